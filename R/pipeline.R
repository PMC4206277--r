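# Orchestration: preparing a protein (decoy selection + annotation),
# batch feature extraction, end-to-end prediction and the seeded
# corpus-level benchmark.

#' Prepare a protein for feature extraction
#'
#' Selects the low-energy decoy fraction, computes the alignment statistics
#' (conservation, mutual information), the ensemble distance context and
#' the per-decoy annotations, contact maps, labels and neighbourhood
#' caches.
#'
#' @param ctx protein context: list with `id`, `ensemble`
#'   (a `decoy_ensemble`), `msa`, `L` and optionally `sequence`,
#'   `native_cm`, `evo`, `depth` (see [make_corpus()]).
#' @param fraction low-energy fraction to select (e.g. 0.02 for
#'   prediction, 0.03 for training).
#' @param cfg configuration list.
#' @return A `prepared_protein`: list with `id`, `L`, `N`, `msa_stats`,
#'   `ens` (ensemble context) and `decoys` (per-decoy bundles: structure,
#'   cm, adj, ss, labels, whole, candidates).
#' @export
prepare_protein <- function(ctx, fraction, cfg = dm_config()) {
  ens <- select_low_energy(ctx$ensemble, fraction)
  sel <- selected_decoys(ens)
  cons <- conservation_profile(ctx$msa, cfg$conservation_pseudocount,
                               cfg$conservation_window)
  mim <- mutual_information_matrix(ctx$msa, cfg$mi_pseudocount)
  msa_stats <- list(conservation = cons$conservation,
                    neigh_conservation = cons$neigh_conservation,
                    mi = mim$mi, apc = mim$apc)
  ectx <- ensemble_context(sel, cfg)
  decoys <- lapply(sel, function(s) {
    ann <- annotate_structure(s, cfg)
    cm <- compute_contact_map(s, cfg$contact_threshold,
                              cfg$graph_min_separation)
    labels <- build_labels(s, ann, msa_stats, cm, cfg)
    cand <- cm$pairs[cm$pairs[, 2L] - cm$pairs[, 1L] >=
                       cfg$candidate_min_separation, , drop = FALSE]
    list(structure = s, cm = cm, adj = cm_adjacency(cm), ss = ann$ss7,
         labels = labels, whole = whole_protein_features(s, ann$ss3, cfg),
         candidates = cand)
  })
  structure(list(id = ctx$id, L = ctx$L %||% sel[[1L]]$L, N = length(sel),
                 msa_stats = msa_stats, ens = ectx, decoys = decoys),
            class = "prepared_protein")
}

# feature matrix for a set of pairs within one prepared decoy
.decoy_feature_matrix <- function(prep, d, pairs, cfg) {
  nspec <- neighborhood_spec(cfg$default_offsets, cfg$helix_offsets)
  n <- nrow(pairs)
  X <- matrix(NA_real_, n, 238L)
  for (r in seq_len(n)) {
    X[r, ] <- assemble_feature_vector(pairs[r, 1L], pairs[r, 2L], d$cm,
                                      d$ss, d$labels, prep$ens, d$whole,
                                      nspec, d$adj, cfg)
  }
  X
}

# enumerate candidate (pair, decoy) instances of a prepared protein
.enumerate_instances <- function(prep, cfg) {
  rows <- list()
  for (di in seq_along(prep$decoys)) {
    p <- prep$decoys[[di]]$candidates
    if (!nrow(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      decoy = di, i = p[, 1L], j = p[, 2L], key = pair_keys(p),
      stringsAsFactors = FALSE)
  }
  meta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(decoy = integer(0), i = integer(0), j = integer(0),
               key = character(0))
  list(meta = meta)
}

# features for a metadata subset (rows of .enumerate_instances()$meta)
.instance_features <- function(prep, meta, cfg) {
  X <- matrix(NA_real_, nrow(meta), 238L)
  for (di in unique(meta$decoy)) {
    rows <- which(meta$decoy == di)
    X[rows, ] <- .decoy_feature_matrix(
      prep, prep$decoys[[di]],
      cbind(meta$i[rows], meta$j[rows]), cfg)
  }
  X
}

#' End-to-end contact prediction for one protein
#'
#' Runs the full prediction pipeline: select the low-energy decoys, score
#' every candidate contact in every selected decoy with the SVM ensemble,
#' aggregate to per-pair scores, combine with occurrence frequency and
#' evolutionary couplings, and rank.
#'
#' @param model an `svm_ensemble_model`.
#' @param ctx protein context (see [prepare_protein()]).
#' @param weights a [combination_weights()].
#' @param fraction low-energy decoy fraction (default
#'   `cfg$predict_fraction` = 0.02).
#' @param range separation range of the returned ranking.
#' @param cfg configuration list.
#' @return A ranked `contact_score_table`.
#' @export
predict_contacts <- function(model, ctx, weights = combination_weights(),
                             fraction = NULL, range = "long",
                             cfg = dm_config()) {
  fraction <- fraction %||% cfg$predict_fraction
  prep <- prepare_protein(ctx, fraction, cfg)
  tab <- score_contacts_over_decoys(model, prep, cfg)
  comb <- combine_scores(tab, ctx$evo, weights,
                         depth = ctx$depth %||% ctx$msa$depth,
                         L = prep$L, cfg = cfg)
  rank_contacts(comb, range, cfg)
}

#' Seeded corpus benchmark
#'
#' Trains the ensemble on the corpus' training proteins, scores every
#' protein's candidate contacts, tunes the combination weights on the
#' training proteins and evaluates on the held-out test proteins:
#' the pooled per-pair classification AUC of the SVM score, of the
#' frequency-only baseline and of a label-permuted control, and the mean
#' long-range top-L/5 accuracy of the combined ranking versus the Counting
#' baseline.
#'
#' @param corpus a `synthetic_corpus` (or compatible list).
#' @param cost,gamma SVM hyper-parameters (defaults from `cfg`).
#' @param alpha_grid,beta_grid combination-weight grids.
#' @param seed integer seed for training-set sampling, calibration folds
#'   and the permutation control.
#' @param cfg configuration list.
#' @return List with `model`, `weights`, `auc` (svm, frequency, permuted),
#'   `accuracy` (per-protein and mean combined/counting long-range L/5),
#'   `tables` (per-protein score tables) and `n_pairs`.
#' @export
run_contact_benchmark <- function(corpus, cost = NULL, gamma = NULL,
                                  alpha_grid = c(0, 0.5, 1, 2),
                                  beta_grid = c(0, 0.5, 1, 2),
                                  seed = 1L, cfg = dm_config()) {
  subsets <- make_training_set(corpus, seed = seed, cfg = cfg)
  model <- train_ensemble(subsets, cost, gamma, seed = seed, cfg = cfg)

  score_one <- function(ctx) {
    prep <- prepare_protein(ctx, cfg$predict_fraction, cfg)
    score_contacts_over_decoys(model, prep, cfg)
  }
  tables <- lapply(corpus$proteins, score_one)

  entries <- lapply(names(corpus$proteins), function(id) {
    ctx <- corpus$proteins[[id]]
    list(table = tables[[id]], evo = ctx$evo, depth = ctx$depth,
         L = ctx$L, native_cm = ctx$native_cm)
  })
  names(entries) <- names(corpus$proteins)
  weights <- tune_combination_weights(entries[corpus$train_ids],
                                      alpha_grid, beta_grid,
                                      seed = seed, cfg = cfg)

  # held-out per-pair classification
  pooled <- do.call(rbind, lapply(corpus$test_ids, function(id) {
    tab <- as.data.frame(tables[[id]])
    if (!nrow(tab)) return(NULL)
    tab$label <- pair_keys(tab$i, tab$j) %in%
      cm_keys(corpus$proteins[[id]]$native_cm)
    tab
  }))
  set.seed(seed + 7L)
  auc <- list(svm = contact_auc(pooled$label, pooled$s_svm),
              frequency = contact_auc(pooled$label, pooled$f),
              permuted = contact_auc(sample(pooled$label), pooled$s_svm))

  # held-out ranking accuracy: combined vs Counting
  acc <- do.call(rbind, lapply(corpus$test_ids, function(id) {
    e <- entries[[id]]
    comb <- combine_scores(e$table, e$evo, weights, e$depth, e$L, cfg)
    ranked <- rank_contacts(comb, "long", cfg)
    counting <- counting_baseline(as.data.frame(e$table))
    counting <- counting[.in_range(counting$j - counting$i, "long", cfg), ,
                         drop = FALSE]
    data.frame(
      protein = id,
      stratum = depth_stratum(e$depth, e$L, cfg$depth_factor),
      acc_combined = evaluate_predictions(ranked, e$native_cm, e$L, 5,
                                          "long", cfg)$acc,
      acc_counting = evaluate_predictions(counting, e$native_cm, e$L, 5,
                                          "long", cfg)$acc)
  }))
  list(model = model, weights = weights, auc = auc,
       accuracy = list(per_protein = acc,
                       combined = mean(acc$acc_combined, na.rm = TRUE),
                       counting = mean(acc$acc_counting, na.rm = TRUE)),
       tables = tables, n_pairs = nrow(pooled))
}
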