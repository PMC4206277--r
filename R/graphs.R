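# Contact-graph constructions around a candidate contact: the per-residue
# neighbourhood graph N_i, the shared neighbourhood graph SNG(i,j) =
# induced(N_i nodes  intersect  N_j nodes), and the immediate neighbourhood
# graph ING(i,j) on the anchors plus everything in direct contact with them.
# Edges are always the contacts induced among the node set.

#' Neighbourhood seed offsets
#'
#' Sequential seed positions around a residue used to grow its neighbourhood
#' graph: by default the residue and its neighbours up to two positions away;
#' for helical residues the positions facing the same side on the adjacent
#' helix turns (i, i+-3, i+-4, from the 3.6-residue helix period). Offsets
#' falling outside the chain are dropped.
#'
#' @param default_offsets integer offsets for non-helical residues.
#' @param helix_offsets integer offsets for helical residues.
#' @return A `neighborhood_spec` list.
#' @export
neighborhood_spec <- function(default_offsets = c(-2L, -1L, 0L, 1L, 2L),
                              helix_offsets = c(-4L, -3L, 0L, 3L, 4L)) {
  structure(list(default_offsets = as.integer(default_offsets),
                 helix_offsets = as.integer(helix_offsets)),
            class = "neighborhood_spec")
}

.is_helix_state <- function(ss) ss %in% c("H", "G", "I")

.seed_set <- function(i, L, helix, nspec) {
  off <- if (helix) nspec$helix_offsets else nspec$default_offsets
  s <- i + off
  sort(unique(s[s >= 1L & s <= L]))
}

# node set of N_i (seeds plus everything in contact with a seed)
.nbhd_nodes <- function(adj, L, ss, i, nspec) {
  seeds <- .seed_set(i, L, .is_helix_state(ss[i]), nspec)
  sort(unique(c(seeds, unlist(adj[seeds], use.names = FALSE))))
}

# induced edge set among `nodes` (sorted), from an adjacency list
.induced_edges <- function(adj, nodes) {
  inset <- logical(length(adj))
  inset[nodes] <- TRUE
  out <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    v <- nodes[k]
    nb <- adj[[v]]
    nb <- nb[nb > v & inset[nb]]
    if (length(nb)) out[[k]] <- cbind(v, nb)
  }
  e <- do.call(rbind, out)
  if (is.null(e)) e <- matrix(integer(0), 0L, 2L)
  dimnames(e) <- NULL
  e
}

.new_contact_graph <- function(nodes, edges, anchor = NULL) {
  structure(list(nodes = nodes, edges = edges, anchor = anchor),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (!is.null(x$anchor))
                sprintf(", anchor (%d,%d)", x$anchor[1L], x$anchor[2L])
              else ""))
  invisible(x)
}

#' Residue neighbourhood graph
#'
#' The neighbourhood of residue i consists of a sequential seed set (see
#' [neighborhood_spec()]) together with every residue in contact with a seed;
#' edges are the contacts induced among those nodes.
#'
#' @param cm a `contact_map`.
#' @param ss per-residue secondary-structure states (3- or 7-state; helix
#'   states select the helix seed offsets).
#' @param i residue index.
#' @param nspec a [neighborhood_spec()].
#' @param adj optional precomputed adjacency list of `cm` (performance).
#' @return A `contact_graph` (no anchor).
#' @export
residue_neighborhood <- function(cm, ss, i, nspec = neighborhood_spec(),
                                 adj = NULL) {
  stopifnot(i >= 1L, i <= cm$L)
  if (is.null(adj)) adj <- cm_adjacency(cm)
  nodes <- .nbhd_nodes(adj, cm$L, ss, i, nspec)
  .new_contact_graph(nodes, .induced_edges(adj, nodes))
}

#' Shared neighbourhood graph of a contact
#'
#' Intersection of the node sets of the two residue neighbourhoods, with
#' induced edges; captures the joint structural context of the contacting
#' residues. For a contact (i,j) both anchors are always members, since each
#' residue lies in the other's neighbourhood.
#'
#' @inheritParams residue_neighborhood
#' @param j second anchor residue.
#' @return A `contact_graph` with `anchor = c(i, j)`.
#' @export
shared_neighborhood_graph <- function(cm, ss, i, j,
                                      nspec = neighborhood_spec(),
                                      adj = NULL) {
  stopifnot(i >= 1L, j >= 1L, i <= cm$L, j <= cm$L, i != j)
  if (is.null(adj)) adj <- cm_adjacency(cm)
  ni <- .nbhd_nodes(adj, cm$L, ss, i, nspec)
  nj <- .nbhd_nodes(adj, cm$L, ss, j, nspec)
  nodes <- intersect(ni, nj)
  .new_contact_graph(nodes, .induced_edges(adj, nodes),
                     anchor = c(min(i, j), max(i, j)))
}

#' Immediate neighbourhood graph of a contact
#'
#' The two anchor residues plus every residue in direct contact with either,
#' with induced edges.
#'
#' @inheritParams shared_neighborhood_graph
#' @return A `contact_graph` with `anchor = c(i, j)`.
#' @export
immediate_neighborhood_graph <- function(cm, i, j, adj = NULL) {
  stopifnot(i >= 1L, j >= 1L, i <= cm$L, j <= cm$L, i != j)
  if (is.null(adj)) adj <- cm_adjacency(cm)
  nodes <- sort(unique(c(i, j, adj[[i]], adj[[j]])))
  .new_contact_graph(nodes, .induced_edges(adj, nodes),
                     anchor = c(min(i, j), max(i, j)))
}
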