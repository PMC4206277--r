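# Node and edge labels: every residue (node) of a decoy carries chemical,
# structural and evolutionary annotations; every contact (edge) carries
# co-evolution and contact-potential labels.

#' Chemical class of residues
#'
#' @param aa character vector of one-letter residue codes.
#' @return Character vector over the seven classes (see `CHEM_CLASSES`).
#' @export
chem_class <- function(aa) .chem_class_of(aa)

#' Ensemble distance statistics
#'
#' Per-pair contact-atom distance mean and standard deviation across the
#' selected decoys, plus per-pair occurrence counts under the contact
#' definition. These summarise how persistently and at what distance a pair
#' is realised across the low-energy ensemble.
#'
#' @param decoys list of `protein_structure` decoys (the selected subset).
#' @param cfg configuration list.
#' @return An `ensemble_context`: list with matrices `mean_dist`, `sd_dist`
#'   (L x L), integer matrix `n` (occurrence counts) and scalar `N`.
#' @export
ensemble_context <- function(decoys, cfg = dm_config()) {
  stopifnot(length(decoys) >= 1L)
  L <- decoys[[1L]]$L
  s1 <- matrix(0, L, L)
  s2 <- matrix(0, L, L)
  n <- matrix(0L, L, L)
  for (d in decoys) {
    stopifnot(d$L == L)
    dm <- as.matrix(stats::dist(contact_atoms(d)))
    s1 <- s1 + dm
    s2 <- s2 + dm^2
    n <- n + (dm <= cfg$contact_threshold &
                abs(col(dm) - row(dm)) >= cfg$graph_min_separation)
  }
  N <- length(decoys)
  mean_d <- s1 / N
  var_d <- pmax(s2 / N - mean_d^2, 0)
  structure(list(mean_dist = mean_d, sd_dist = sqrt(var_d), n = n, N = N),
            class = "ensemble_context")
}

#' Build node and edge labels for one decoy
#'
#' Combines the structural annotations of a decoy with the alignment-derived
#' conservation and mutual-information statistics into the label sets the
#' feature encoders consume: one complete label row per residue, one per
#' contact of the decoy's contact map.
#'
#' @param s the decoy `protein_structure`.
#' @param ann annotations from [annotate_structure()].
#' @param msa_stats list with `conservation`, `neigh_conservation` (from
#'   [conservation_profile()]) and `mi`, `apc` (from
#'   [mutual_information_matrix()]).
#' @param cm the decoy's `contact_map`.
#' @param cfg configuration list.
#' @return A `contact_labels` object: list with data frames `nodes`
#'   (aa, chem, ss3, ss7, rsa, buried, hbond_count, solvation,
#'   conservation, neigh_conservation, x, y, z) and `edges`
#'   (i, j, mi, apc, potential, distance), plus the set of hydrogen-bonded
#'   pair keys.
#' @export
build_labels <- function(s, ann, msa_stats, cm, cfg = dm_config()) {
  L <- s$L
  if (length(ann$rsa) != L || length(ann$ss7) != L)
    stop("annotations do not match structure length")
  if (ncol(msa_stats$mi) != L)
    stop("alignment statistics do not match structure length")
  xyz <- contact_atoms(s)
  nodes <- data.frame(
    res = seq_len(L),
    aa = s$seq,
    chem = .chem_class_of(s$seq),
    ss3 = ann$ss3,
    ss7 = ann$ss7,
    rsa = ann$rsa,
    buried = ann$rsa < cfg$buried_rsa,
    hbond_count = ann$hbond_count,
    solvation = ann$solvation,
    conservation = msa_stats$conservation,
    neigh_conservation = msa_stats$neigh_conservation,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)

  p <- cm$pairs
  if (nrow(p)) {
    dvec <- sqrt(rowSums((xyz[p[, 1L], , drop = FALSE] -
                            xyz[p[, 2L], , drop = FALSE])^2))
    edges <- data.frame(
      i = p[, 1L], j = p[, 2L],
      mi = msa_stats$mi[p],
      apc = msa_stats$apc[p],
      potential = .potential_of(s$seq[p[, 1L]], s$seq[p[, 2L]]),
      distance = dvec)
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), mi = numeric(0),
                        apc = numeric(0), potential = numeric(0),
                        distance = numeric(0))
  }
  hb <- ann$hbonds
  hkeys <- unique(pair_keys(pmin(hb$donor, hb$acceptor),
                            pmax(hb$donor, hb$acceptor)))
  structure(list(nodes = nodes, edges = edges,
                 edge_index = stats::setNames(seq_len(nrow(edges)),
                                              pair_keys(edges$i, edges$j)),
                 hbond_keys = hkeys),
            class = "contact_labels")
}
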