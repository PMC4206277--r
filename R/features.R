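# The fixed-schema 238-input encoding of a candidate contact:
#   49 pairwise + 29 whole-protein inputs, plus 80 graph inputs evaluated
#   once on the shared neighbourhood graph and once on the immediate
#   neighbourhood graph (10 topology + 5 spectrum + 10 single-node +
#   43 node-label statistics + 12 edge-label statistics).

.FEATURE_GROUP_LENGTHS <- c(pairwise = 49L, topology = 10L, spectrum = 5L,
                            single_node = 10L, node_stats = 43L,
                            edge_stats = 12L, whole_protein = 29L)

# ---- graph descriptors ------------------------------------------------

.graph_igraph <- function(g) {
  n <- length(g$nodes)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$edges)) {
    e <- cbind(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes))
    ig <- igraph::add_edges(ig, t(e))
  }
  ig
}

# per-node degree and (n-1)-normalised centralities, computed per
# connected component so that disconnected graphs stay finite
.graph_centralities <- function(g) {
  n <- length(g$nodes)
  ig <- .graph_igraph(g)
  deg <- igraph::degree(ig)
  degc <- clo <- btw <- numeric(n)
  comp <- igraph::components(ig)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    nc <- length(members)
    if (nc == 1L) next
    sub <- igraph::induced_subgraph(ig, members)
    dmat <- igraph::distances(sub)
    degc[members] <- deg[members] / (nc - 1L)
    clo[members] <- (nc - 1L) / rowSums(dmat)
    btw[members] <- if (nc >= 3L)
      igraph::betweenness(sub, normalized = TRUE) else 0
  }
  list(degree = deg, degree_centrality = degc, closeness = clo,
       betweenness = btw, components = comp, ig = ig)
}

.largest_component_ecc <- function(cent) {
  comp <- cent$components
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  if (length(members) == 1L) return(c(0, 0, 0))
  dmat <- igraph::distances(igraph::induced_subgraph(cent$ig, members))
  ecc <- apply(dmat, 1L, max)
  c(min(ecc), max(ecc), mean(ecc))
}

#' Graph topology descriptors
#'
#' Ten descriptors of a contact graph, in this order: number of nodes,
#' number of edges, average degree centrality, average closeness
#' centrality, average betweenness centrality, graph radius, graph
#' diameter, average eccentricity, number of end points (degree-1 nodes)
#' and average local clustering coefficient. Centralities use standard
#' (n-1) normalisations per connected component; radius, diameter and
#' eccentricity are computed on the largest component.
#'
#' @param g a `contact_graph`.
#' @return Numeric vector of length 10.
#' @export
topology_features <- function(g, .cent = NULL) {
  n <- length(g$nodes)
  stopifnot(n >= 1L)
  cent <- .cent %||% .graph_centralities(g)
  rde <- .largest_component_ecc(cent)
  clust <- igraph::transitivity(cent$ig, type = "localundirected",
                                isolates = "zero")
  clust[is.na(clust)] <- 0
  c(n, nrow(g$edges), mean(cent$degree_centrality), mean(cent$closeness),
    mean(cent$betweenness), rde[1L], rde[2L], rde[3L],
    sum(cent$degree == 1L), mean(clust))
}

#' Graph spectrum descriptors
#'
#' Five descriptors of the adjacency spectrum: largest eigenvalue, second
#' largest eigenvalue, number of distinct eigenvalues (at tolerance
#' `cfg$eigen_tolerance`), sum of eigenvalues (zero for any simple graph)
#' and the graph energy (sum of absolute eigenvalues).
#'
#' @param g a `contact_graph`.
#' @param cfg configuration list.
#' @return Numeric vector of length 5. A single-node graph yields
#'   `c(0, 0, 1, 0, 0)`.
#' @export
spectrum_features <- function(g, cfg = dm_config()) {
  n <- length(g$nodes)
  stopifnot(n >= 1L)
  if (n == 1L) return(c(0, 0, 1, 0, 0))
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    e <- cbind(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes))
    A[e] <- 1
    A[e[, 2:1, drop = FALSE]] <- 1
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  distinct <- sum(abs(diff(sort(ev))) > cfg$eigen_tolerance) + 1L
  c(ev[1L], ev[2L], distinct, sum(ev), sum(abs(ev)))
}

#' Single-node descriptors of the anchor residues
#'
#' Degree, closeness centrality, betweenness centrality, sequence
#' conservation and neighbourhood conservation for residue i followed by
#' the same five values for residue j, all evaluated within graph `g`.
#'
#' @param i,j anchor residue indices; both must be nodes of `g`.
#' @param g a `contact_graph`.
#' @param labels a `contact_labels` object.
#' @return Numeric vector of length 10.
#' @export
single_node_features <- function(i, j, g, labels, .cent = NULL) {
  ri <- match(i, g$nodes)
  rj <- match(j, g$nodes)
  if (is.na(ri) || is.na(rj))
    stop("anchor residues must be members of the graph")
  cent <- .cent %||% .graph_centralities(g)
  nd <- labels$nodes
  one <- function(r, res) c(cent$degree[r], cent$closeness[r],
                            cent$betweenness[r],
                            nd$conservation[res], nd$neigh_conservation[res])
  c(one(ri, i), one(rj, j))
}

# ---- label statistics -------------------------------------------------

.distribution <- function(x, levels) {
  if (!length(x)) return(rep(0, length(levels)))
  as.numeric(table(factor(x, levels = levels))) / length(x)
}

.bin_distribution <- function(x, edges) {
  nb <- length(edges) + 1L
  if (!length(x)) return(rep(0, nb))
  b <- findInterval(x, edges) + 1L
  as.numeric(tabulate(b, nbins = nb)) / length(x)
}

.dist_entropy <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

#' Node-label statistics of a contact graph
#'
#' Forty-three aggregate descriptors of the residue labels over the graph's
#' nodes, in fixed order: chemical-class distribution (7), seven-state
#' secondary-structure distribution (7), mean RSA and 3-bin RSA
#' distribution (4), fraction of hydrogen-bonded residues and mean
#' hydrogen-bond count (2), mean solvation energy (1) and its 4-bin
#' distribution (4), entropies of the chemical, secondary-structure and
#' RSA-bin distributions (3), neighbourhood impurity degree (mean number of
#' graph neighbours with a different chemical class, 1), mean and standard
#' deviation of node distances from the node centroid (2), conservation
#' mean/min/max and 4-bin distribution (7), neighbourhood-conservation
#' mean/min/max (3), fraction of nodes sequence-local to the anchors
#' (|k - i| <= 2 or |k - j| <= 2, 1) and fraction of
#' hydrophobic-and-buried nodes (1).
#'
#' @param g a `contact_graph`.
#' @param labels a `contact_labels` object.
#' @param cfg configuration list (bin edges).
#' @return Numeric vector of length 43.
#' @export
node_label_statistics <- function(g, labels, cfg = dm_config()) {
  nd <- labels$nodes[g$nodes, , drop = FALSE]
  chem_d <- .distribution(nd$chem, CHEM_CLASSES)
  ss7_d <- .distribution(nd$ss7, SS7_STATES)
  rsa_d <- .bin_distribution(nd$rsa, cfg$rsa_bins)
  solv_d <- .bin_distribution(nd$solvation, cfg$solvation_bins)
  cons_d <- .bin_distribution(nd$conservation, cfg$conservation_bins)

  # neighbourhood impurity: per node, how many neighbours differ in class
  imp <- 0
  if (nrow(g$edges)) {
    chem_of <- stats::setNames(nd$chem, as.character(g$nodes))
    diffs <- chem_of[as.character(g$edges[, 1L])] !=
      chem_of[as.character(g$edges[, 2L])]
    per_node <- tabulate(match(c(g$edges[diffs, 1L], g$edges[diffs, 2L]),
                               g$nodes), nbins = length(g$nodes))
    imp <- mean(per_node)
  }

  xyz <- as.matrix(nd[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  cd <- sqrt(colSums((t(xyz) - centroid)^2))
  sd_cd <- if (length(cd) > 1L) stats::sd(cd) else 0

  loc <- 0
  if (!is.null(g$anchor)) {
    loc <- mean(abs(g$nodes - g$anchor[1L]) <= 2L |
                  abs(g$nodes - g$anchor[2L]) <= 2L)
  }

  out <- c(chem_d, ss7_d,
           mean(nd$rsa), rsa_d,
           mean(nd$hbond_count > 0L), mean(nd$hbond_count),
           mean(nd$solvation), solv_d,
           .dist_entropy(chem_d), .dist_entropy(ss7_d), .dist_entropy(rsa_d),
           imp,
           mean(cd), sd_cd,
           mean(nd$conservation), min(nd$conservation), max(nd$conservation),
           cons_d,
           mean(nd$neigh_conservation), min(nd$neigh_conservation),
           max(nd$neigh_conservation),
           loc,
           mean(nd$chem == "hydrophobic" & nd$buried))
  stopifnot(length(out) == 43L)
  out
}

#' Edge-label statistics of a contact graph
#'
#' Twelve aggregate descriptors over the graph's edges, in fixed order:
#' link impurity (fraction of edges joining nodes of different chemical
#' class, 1), 5-bin distribution of APC-corrected mutual information (5),
#' cumulative (summed) mutual information (1), 3-bin contact-potential
#' distribution (3), mean contact potential (1) and mean mutual
#' information (1). A graph without edges yields all zeros.
#'
#' @inheritParams node_label_statistics
#' @return Numeric vector of length 12.
#' @export
edge_label_statistics <- function(g, labels, cfg = dm_config()) {
  m <- nrow(g$edges)
  if (m == 0L) return(rep(0, 12L))
  rows <- labels$edge_index[pair_keys(g$edges)]
  if (anyNA(rows)) stop("graph edge missing from edge labels")
  ed <- labels$edges[rows, , drop = FALSE]
  chem <- labels$nodes$chem
  impurity <- mean(chem[g$edges[, 1L]] != chem[g$edges[, 2L]])
  mi_edges <- cfg$mi_bins[2:(length(cfg$mi_bins) - 1L)]
  mi_d <- .bin_distribution(ed$apc, mi_edges)
  pot_d <- .bin_distribution(ed$potential, cfg$potential_bins)
  out <- c(impurity, mi_d, sum(ed$mi), pot_d, mean(ed$potential),
           mean(ed$mi))
  stopifnot(length(out) == 12L)
  out
}

# ---- pairwise and whole-protein blocks --------------------------------

#' Pairwise descriptors of a candidate contact
#'
#' Forty-nine inputs describing the two residues and their relation, in
#' fixed order: chemical-class one-hots for i and j (14), three-state
#' secondary-structure one-hots (6), RSA values (2), buried flags (2),
#' solvation energies (2), Kyte-Doolittle hydrophobicities (2), i-j
#' hydrogen-bond flag (1), hydrogen-bond counts (2), raw sequence
#' separation (1) and its 4-bin one-hot (<12, 12-23, 24-50, >50) (4),
#' distances of i and j from the N- and C-terminus (4), contact potential
#' (1) and its 3-bin one-hot (3), contact-atom distance in the decoy (1),
#' ensemble mean and standard deviation of that distance (2), mutual
#' information (1) and APC-corrected mutual information (1).
#'
#' @param i,j residue indices of the candidate contact (a contact of the
#'   decoy's map).
#' @param labels a `contact_labels` object for the decoy.
#' @param ens an `ensemble_context`, or `NULL` (decoy distance, sd 0).
#' @param cfg configuration list.
#' @return Numeric vector of length 49.
#' @export
pairwise_features <- function(i, j, labels, ens = NULL, cfg = dm_config()) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  nd <- labels$nodes
  L <- nrow(nd)
  onehot <- function(x, levels) as.numeric(levels == x)
  key <- pair_keys(i, j)
  row <- labels$edge_index[key]
  if (!is.na(row)) {
    ed <- labels$edges[row, ]
    dist_ij <- ed$distance; mi <- ed$mi; apc <- ed$apc; pot <- ed$potential
  } else {
    dist_ij <- sqrt(sum((as.numeric(nd[i, c("x", "y", "z")]) -
                           as.numeric(nd[j, c("x", "y", "z")]))^2))
    mi <- 0; apc <- 0
    pot <- .potential_of(nd$aa[i], nd$aa[j])
  }
  sep <- j - i
  sep_bin <- .bin_distribution(sep, cfg$separation_bins)
  pot_bin <- .bin_distribution(pot, cfg$potential_bins)
  mean_d <- if (!is.null(ens)) ens$mean_dist[i, j] else dist_ij
  sd_d <- if (!is.null(ens)) ens$sd_dist[i, j] else 0

  out <- c(onehot(nd$chem[i], CHEM_CLASSES), onehot(nd$chem[j], CHEM_CLASSES),
           onehot(nd$ss3[i], SS3_STATES), onehot(nd$ss3[j], SS3_STATES),
           nd$rsa[i], nd$rsa[j],
           as.numeric(nd$buried[i]), as.numeric(nd$buried[j]),
           nd$solvation[i], nd$solvation[j],
           .kd_of(nd$aa[i]), .kd_of(nd$aa[j]),
           as.numeric(key %in% labels$hbond_keys),
           nd$hbond_count[i], nd$hbond_count[j],
           sep, sep_bin,
           i - 1L, L - i, j - 1L, L - j,
           pot, pot_bin,
           dist_ij, mean_d, sd_d,
           mi, apc)
  stopifnot(length(out) == 49L)
  out
}

#' Whole-protein descriptors
#'
#' Twenty-nine inputs: amino-acid composition over the 20 standard residues
#' (20), three-state secondary-structure composition (3) and a 6-bin
#' protein-length one-hot (<=50, 51-100, 101-150, 151-250, 251-400,
#' >400) (6).
#'
#' @param s a `protein_structure`.
#' @param ss3 per-residue three-state secondary structure.
#' @param cfg configuration list.
#' @return Numeric vector of length 29.
#' @export
whole_protein_features <- function(s, ss3, cfg = dm_config()) {
  aa <- s$seq[s$seq %in% AA_ALPHABET]
  aa_comp <- .distribution(aa, AA_ALPHABET)
  ss_comp <- .distribution(ss3, SS3_STATES)
  len_bin <- .bin_distribution(s$L, cfg$length_bins + 0.5)
  out <- c(aa_comp, ss_comp, len_bin)
  stopifnot(length(out) == 29L)
  out
}

# one 80-input graph block (topology, spectrum, single-node, node stats,
# edge stats), sharing one centrality computation
.graph_block <- function(g, labels, i, j, cfg) {
  cent <- .graph_centralities(g)
  c(topology_features(g, .cent = cent),
    spectrum_features(g, cfg),
    single_node_features(i, j, g, labels, .cent = cent),
    node_label_statistics(g, labels, cfg),
    edge_label_statistics(g, labels, cfg))
}

#' Assemble the full feature vector of a candidate contact
#'
#' Builds the shared and immediate neighbourhood graphs of the contact and
#' concatenates all feature groups in the fixed order: pairwise (49) |
#' SNG topology, spectrum, single-node, node statistics, edge statistics
#' (80) | the same five groups on the ING (80) | whole protein (29), for a
#' total of 238 inputs. Any group-length mismatch is a schema violation and
#' fatal.
#'
#' @param i,j candidate contact (must be a contact of `cm`).
#' @param cm the decoy's `contact_map`.
#' @param ss per-residue secondary-structure states.
#' @param labels a `contact_labels` object.
#' @param ens an `ensemble_context` or `NULL`.
#' @param whole precomputed [whole_protein_features()] (recomputed if
#'   `NULL`).
#' @param nspec a [neighborhood_spec()].
#' @param adj optional precomputed adjacency list of `cm`.
#' @param cfg configuration list.
#' @return Numeric vector of length 238 with attribute `groups`.
#' @export
assemble_feature_vector <- function(i, j, cm, ss, labels, ens = NULL,
                                    whole = NULL, nspec = neighborhood_spec(),
                                    adj = NULL, cfg = dm_config()) {
  if (is.null(adj)) adj <- cm_adjacency(cm)
  sng <- shared_neighborhood_graph(cm, ss, i, j, nspec, adj)
  ing <- immediate_neighborhood_graph(cm, i, j, adj)
  if (is.null(whole)) {
    ss3 <- ifelse(ss %in% c("H", "G", "I"), "H",
                  ifelse(ss %in% c("E", "B"), "E", "C"))
    whole <- .whole_from_labels(labels, ss3, cfg)
  }
  pw <- pairwise_features(min(i, j), max(i, j), labels, ens, cfg)
  fv <- c(pw, .graph_block(sng, labels, min(i, j), max(i, j), cfg),
          .graph_block(ing, labels, min(i, j), max(i, j), cfg), whole)
  if (length(fv) != 238L)
    stop("feature schema violation: vector length ", length(fv))
  attr(fv, "groups") <- .FEATURE_GROUP_LENGTHS
  fv
}

# whole-protein block from a labels object (avoids needing the structure)
.whole_from_labels <- function(labels, ss3, cfg) {
  aa <- labels$nodes$aa
  aa <- aa[aa %in% AA_ALPHABET]
  c(.distribution(aa, AA_ALPHABET), .distribution(ss3, SS3_STATES),
    .bin_distribution(nrow(labels$nodes), cfg$length_bins + 0.5))
}

#' Feature schema
#'
#' Names all 238 inputs of the feature vector in order, with their group.
#'
#' @param cfg configuration list.
#' @return Data frame with columns `index`, `group`, `name` and attribute
#'   `schema_version`.
#' @export
feature_schema <- function(cfg = dm_config()) {
  pw <- c(paste0("chem_i_", CHEM_CLASSES), paste0("chem_j_", CHEM_CLASSES),
          paste0("ss3_i_", SS3_STATES), paste0("ss3_j_", SS3_STATES),
          "rsa_i", "rsa_j", "buried_i", "buried_j",
          "solvation_i", "solvation_j", "kd_i", "kd_j",
          "hbond_ij", "hbond_count_i", "hbond_count_j",
          "separation", paste0("sep_bin_", 1:4),
          "nterm_i", "cterm_i", "nterm_j", "cterm_j",
          "potential", paste0("potential_bin_", 1:3),
          "decoy_distance", "ensemble_mean_distance", "ensemble_sd_distance",
          "mi", "apc_mi")
  topo <- c("n_nodes", "n_edges", "avg_degree_centrality",
            "avg_closeness", "avg_betweenness", "radius", "diameter",
            "avg_eccentricity", "n_end_points", "avg_clustering")
  spec <- c("lambda1", "lambda2", "n_distinct_eigenvalues",
            "eigenvalue_sum", "graph_energy")
  single <- as.vector(outer(c("degree", "closeness", "betweenness",
                              "conservation", "neigh_conservation"),
                            c("_i", "_j"), function(a, b) paste0(a, b)))
  single <- c(single[1:5], single[6:10])
  nstat <- c(paste0("chem_dist_", CHEM_CLASSES),
             paste0("ss7_dist_", SS7_STATES),
             "mean_rsa", paste0("rsa_bin_", 1:3),
             "frac_hbonded", "mean_hbond_count",
             "mean_solvation", paste0("solvation_bin_", 1:4),
             "chem_entropy", "ss7_entropy", "rsa_entropy",
             "impurity_degree", "mean_centroid_dist", "sd_centroid_dist",
             "cons_mean", "cons_min", "cons_max", paste0("cons_bin_", 1:4),
             "ncons_mean", "ncons_min", "ncons_max",
             "frac_anchor_local", "frac_hydrophobic_buried")
  estat <- c("link_impurity", paste0("apc_bin_", 1:5), "cumulative_mi",
             paste0("edge_potential_bin_", 1:3), "mean_potential", "mean_mi")
  whole <- c(paste0("aa_comp_", AA_ALPHABET), paste0("ss3_comp_", SS3_STATES),
             paste0("length_bin_", 1:6))
  groups <- c(rep("pairwise", 49L),
              rep(c("topology_SNG", "spectrum_SNG", "single_node_SNG",
                    "node_stats_SNG", "edge_stats_SNG"),
                  times = c(10L, 5L, 10L, 43L, 12L)),
              rep(c("topology_ING", "spectrum_ING", "single_node_ING",
                    "node_stats_ING", "edge_stats_ING"),
                  times = c(10L, 5L, 10L, 43L, 12L)),
              rep("whole_protein", 29L))
  names <- c(pw,
             paste0("sng_", c(topo, spec, single, nstat, estat)),
             paste0("ing_", c(topo, spec, single, nstat, estat)),
             whole)
  stopifnot(length(names) == 238L, length(groups) == 238L)
  out <- data.frame(index = seq_len(238L), group = groups, name = names,
                    stringsAsFactors = FALSE)
  attr(out, "schema_version") <- "dm-238-v1"
  out
}
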