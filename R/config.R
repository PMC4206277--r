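#' Pipeline configuration
#'
#' All tunable constants of the pipeline live in one configuration list so
#' that bin edges, thresholds and neighbourhood definitions are stable across
#' runs and can be overridden in one place.
#'
#' Key entries (units):
#' \describe{
#'   \item{contact_threshold}{contact-atom distance cutoff in Angstrom (8).}
#'   \item{graph_min_separation}{minimum |j-i| for edges of the structural
#'     contact graph (1; chain neighbours count if within the cutoff).}
#'   \item{candidate_min_separation}{minimum |j-i| for contacts that are
#'     scored/predicted (12; short-range contacts are trivially present).}
#'   \item{medium_range, long_min}{sequence-separation windows for
#'     medium-range (12..23) and long-range (>= 24) evaluation.}
#'   \item{buried_rsa}{relative solvent accessibility below which a residue
#'     counts as buried (0.25).}
#'   \item{hbond_cutoff, hbond_min_sep}{backbone N...O hydrogen-bond distance
#'     cutoff (3.5 A) and minimum sequence separation (2).}
#'   \item{probe_radius, sasa_points}{solvent probe radius (1.4 A) and number
#'     of sphere sample points (92) for surface-area integration.}
#'   \item{mi_pseudocount}{pseudocount per joint-frequency cell for mutual
#'     information (0.05).}
#'   \item{mi_bins, solvation_bins, rsa_bins, conservation_bins,
#'     potential_bins, separation_bins, length_bins}{fixed bin edges for the
#'     distribution-type feature blocks.}
#'   \item{svm_cost, svm_gamma}{default soft-margin cost (10) and Gaussian
#'     kernel width (1/238) used when tuning is skipped.}
#'   \item{undersample}{per-protein undersampling counts, 50 native and
#'     150 non-native training contacts.}
#'   \item{train_fraction, predict_fraction}{low-energy decoy fractions kept
#'     for training (0.03) and prediction (0.02).}
#'   \item{depth_factor}{alignment-depth threshold factor: alignments with
#'     more than \code{depth_factor * L} rows count as deep (5).}
#' }
#'
#' @param ... named overrides of individual entries.
#' @return A named list of configuration values.
#' @examples
#' cfg <- dm_config(contact_threshold = 7.5)
#' cfg$contact_threshold
#' @export
dm_config <- function(...) {
  cfg <- list(
    contact_threshold        = 8.0,
    graph_min_separation     = 1L,
    candidate_min_separation = 12L,
    medium_range             = c(12L, 23L),
    long_min                 = 24L,
    default_offsets          = c(-2L, -1L, 0L, 1L, 2L),
    helix_offsets            = c(-4L, -3L, 0L, 3L, 4L),
    chain_break_gap          = 4.2,
    buried_rsa               = 0.25,
    rsa_clamp                = 1.2,
    hbond_cutoff             = 3.5,
    hbond_min_sep            = 2L,
    probe_radius             = 1.4,
    sasa_points              = 92L,
    mi_pseudocount           = 0.05,
    conservation_pseudocount = 1,
    conservation_window      = 2L,
    mi_bins                  = c(0, 0.05, 0.1, 0.2, 0.4, Inf),
    solvation_bins           = c(-0.5, 0, 0.5),
    rsa_bins                 = c(0.25, 0.6),
    conservation_bins        = c(0.25, 0.5, 0.75),
    potential_bins           = c(-2.2, -1.1),
    separation_bins          = c(12L, 24L, 51L),
    length_bins              = c(50L, 100L, 150L, 250L, 400L),
    svm_cost                 = 10,
    svm_gamma                = 1 / 238,
    ensemble_members         = 5L,
    calibration_bins         = 10L,
    calibration_percentiles  = c(0.05, 0.95),
    calibration_folds        = 5L,
    undersample              = c(native = 50L, nonnative = 150L),
    train_fraction           = 0.03,
    predict_fraction         = 0.02,
    depth_factor             = 5,
    eigen_tolerance          = 1e-8
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown configuration entries: ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}
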