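# Undersampled five-member SVM ensemble with z-normalisation and
# percentile-bin probability calibration.

# ---- calibration ------------------------------------------------------

#' Percentile-bin probability calibration
#'
#' Maps raw SVM decision values to native-contact probabilities: the scores
#' between the 5th and 95th percentile are split into ten equal-width bins
#' and each bin's probability is the fraction of native contacts falling in
#' it. Scores below/above the percentile range clamp to the first/last bin;
#' empty bins inherit the probability of the nearest non-empty bin.
#'
#' @param raw_scores numeric raw classifier outputs.
#' @param labels logical (or coercible) vector, `TRUE` = native contact.
#' @param n_bins number of bins (default 10).
#' @param percentiles lower/upper percentile bounds (default 0.05, 0.95).
#' @return A `bin_calibrator`: list with `edges` (length `n_bins + 1`),
#'   `prob` and `counts` per bin.
#' @export
calibrate_bins <- function(raw_scores, labels, n_bins = 10L,
                           percentiles = c(0.05, 0.95)) {
  labels <- as.logical(labels)
  if (length(raw_scores) < 20L)
    stop("calibration needs at least 20 scores")
  if (length(unique(labels)) < 2L)
    stop("calibration needs both classes")
  p <- stats::quantile(raw_scores, percentiles, names = FALSE)
  if (p[2L] <= p[1L]) p[2L] <- p[1L] + 1e-8
  edges <- seq(p[1L], p[2L], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(raw_scores, edges,
                                rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  prob <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins))
    if (counts[b] > 0L) prob[b] <- mean(labels[bin == b])
  empty <- which(is.na(prob))
  filled <- which(!is.na(prob))
  for (b in empty) {
    nearest <- filled[which.min(abs(filled - b))]
    prob[b] <- prob[nearest]
  }
  structure(list(edges = edges, prob = prob, counts = counts),
            class = "bin_calibrator")
}

#' Apply a bin calibrator
#'
#' @param cal a `bin_calibrator`.
#' @param raw numeric raw scores.
#' @return Calibrated probabilities in `[0, 1]`.
#' @export
apply_calibration <- function(cal, raw) {
  n_bins <- length(cal$prob)
  bin <- pmin(pmax(findInterval(raw, cal$edges, rightmost.closed = TRUE),
                   1L), n_bins)
  cal$prob[bin]
}

# ---- training-set construction ---------------------------------------

#' Build the undersampled training set
#'
#' For each protein, candidate contact instances are all (pair, decoy)
#' occurrences among its low-energy training decoys with sequence
#' separation at least `cfg$candidate_min_separation`; the label is whether
#' the pair is a contact of the native structure. Per protein, 50 native
#' and 150 non-native instances are sampled uniformly without replacement
#' (all available, if fewer), and proteins are split at random into five
#' non-overlapping subsets — one per future ensemble member.
#'
#' @param corpus a `synthetic_corpus`, or a list with `proteins` (contexts
#'   as documented in [make_corpus()]) and optionally `train_ids`.
#' @param seed integer seed driving the split and the undersampling.
#' @param fraction low-energy decoy fraction used for training (default
#'   `cfg$train_fraction` = 0.03).
#' @param cfg configuration list.
#' @return List of `cfg$ensemble_members` subsets, each a list with `X`
#'   (instance-by-238 feature matrix), `y` (factor native/nonnative) and
#'   `meta` (protein, L, i, j, decoy).
#' @export
make_training_set <- function(corpus, seed = 1L, fraction = NULL,
                              cfg = dm_config()) {
  fraction <- fraction %||% cfg$train_fraction
  proteins <- corpus$proteins
  if (!is.null(corpus$train_ids))
    proteins <- proteins[corpus$train_ids]
  if (length(proteins) < cfg$ensemble_members)
    stop("need at least ", cfg$ensemble_members, " proteins for the ensemble")
  set.seed(seed)
  members <- sample(rep_len(seq_len(cfg$ensemble_members), length(proteins)))

  per_protein <- vector("list", length(proteins))
  for (p in seq_along(proteins)) {
    ctx <- proteins[[p]]
    prep <- prepare_protein(ctx, fraction = fraction, cfg = cfg)
    native_keys <- cm_keys(ctx$native_cm)
    inst <- .enumerate_instances(prep, cfg)
    if (!nrow(inst$meta)) {
      warning("protein ", ctx$id, " has no candidate contacts; skipped")
      next
    }
    lab <- inst$meta$key %in% native_keys
    if (!any(lab)) {
      warning("protein ", ctx$id, " has no native decoy contacts; skipped")
      next
    }
    take <- c(.sample_at_most(which(lab), cfg$undersample[["native"]]),
              .sample_at_most(which(!lab), cfg$undersample[["nonnative"]]))
    meta <- inst$meta[take, , drop = FALSE]
    X <- .instance_features(prep, meta, cfg)
    per_protein[[p]] <- list(
      X = X,
      y = factor(ifelse(lab[take], "native", "nonnative"),
                 levels = c("native", "nonnative")),
      meta = cbind(protein = ctx$id, L = ctx$L, meta),
      member = members[p])
  }
  per_protein <- Filter(Negate(is.null), per_protein)
  if (!length(per_protein)) stop("no usable training proteins")
  subsets <- vector("list", cfg$ensemble_members)
  for (m in seq_len(cfg$ensemble_members)) {
    parts <- Filter(function(x) x$member == m, per_protein)
    if (!length(parts)) {
      subsets[[m]] <- list(X = NULL, y = factor(character(0)), meta = NULL)
      next
    }
    subsets[[m]] <- list(X = do.call(rbind, lapply(parts, `[[`, "X")),
                         y = factor(unlist(lapply(parts, function(x)
                           as.character(x$y))),
                           levels = c("native", "nonnative")),
                         meta = do.call(rbind, lapply(parts, `[[`, "meta")))
  }
  subsets
}

.sample_at_most <- function(idx, k) {
  if (length(idx) <= k) idx else sample(idx, k)
}

# ---- ensemble training ------------------------------------------------

.fit_member_svm <- function(X, y, cost, gamma) {
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")[, 1L]
  sign <- if (mean(dv[y == "native"]) >= mean(dv[y == "nonnative"])) 1 else -1
  list(fit = fit, sign = sign)
}

.member_raw <- function(member, X) {
  dv <- attr(stats::predict(member$fit, X, decision.values = TRUE),
             "decision.values")[, 1L]
  member$sign * dv
}

#' Train the calibrated SVM ensemble
#'
#' Fits the z-score normaliser on the union of all subsets, then one
#' soft-margin Gaussian-kernel SVM per subset. Each member is calibrated by
#' percentile binning ([calibrate_bins()]) of out-of-fold decision values
#' from an internal 5-fold cross-validation of its own subset, so the bin
#' probabilities reflect scores the member has not memorised.
#'
#' @param subsets output of [make_training_set()].
#' @param cost soft-margin cost parameter C.
#' @param gamma Gaussian kernel width.
#' @param seed integer seed for the calibration folds.
#' @param cfg configuration list.
#' @return An `svm_ensemble_model`: list with `normalizer` (per-input mean
#'   and sd, sd floored at 1e-8), `members` (five fitted SVMs with sign and
#'   `bin_calibrator`), `cost`, `gamma`, `seed`, `schema_version`.
#' @export
train_ensemble <- function(subsets, cost = NULL, gamma = NULL, seed = 1L,
                           cfg = dm_config()) {
  cost <- cost %||% cfg$svm_cost
  gamma <- gamma %||% cfg$svm_gamma
  subsets <- Filter(function(s) !is.null(s$X) && nrow(s$X) > 0L, subsets)
  if (length(subsets) != cfg$ensemble_members)
    stop("expected ", cfg$ensemble_members, " non-empty subsets, got ",
         length(subsets))
  all_X <- do.call(rbind, lapply(subsets, `[[`, "X"))
  mu <- colMeans(all_X)
  sd <- pmax(apply(all_X, 2L, stats::sd), 1e-8)
  set.seed(seed)
  members <- vector("list", length(subsets))
  for (m in seq_along(subsets)) {
    X <- sweep(sweep(subsets[[m]]$X, 2L, mu), 2L, sd, "/")
    y <- subsets[[m]]$y
    if (length(unique(y)) < 2L)
      stop("subset ", m, " contains a single class; cannot train")
    folds <- sample(rep_len(seq_len(cfg$calibration_folds), nrow(X)))
    raw <- numeric(nrow(X))
    for (f in seq_len(cfg$calibration_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L)
        stop("calibration fold of subset ", m, " lost a class; ",
             "use more training instances")
      fold_fit <- .fit_member_svm(X[tr, , drop = FALSE], y[tr], cost, gamma)
      raw[!tr] <- .member_raw(fold_fit, X[!tr, , drop = FALSE])
    }
    cal <- calibrate_bins(raw, y == "native", cfg$calibration_bins,
                          cfg$calibration_percentiles)
    fit <- .fit_member_svm(X, y, cost, gamma)
    members[[m]] <- list(fit = fit$fit, sign = fit$sign, calibrator = cal)
  }
  structure(list(normalizer = list(mean = mu, sd = sd), members = members,
                 cost = cost, gamma = gamma, seed = seed,
                 schema_version = "dm-238-v1"),
            class = "svm_ensemble_model")
}

#' @export
print.svm_ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<svm_ensemble_model> %d members, C=%g, gamma=%g, %d inputs\n",
    length(x$members), x$cost, x$gamma, length(x$normalizer$mean)))
  invisible(x)
}

#' Predict the native-contact probability of feature vectors
#'
#' Normalises the input, obtains each member's raw decision value, maps it
#' through the member's bin calibrator and averages the five calibrated
#' probabilities.
#'
#' @param model an `svm_ensemble_model`.
#' @param fv a feature vector (length 238) or a matrix of rows.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @export
predict_contact_probability <- function(model, fv) {
  X <- if (is.matrix(fv)) fv else matrix(fv, nrow = 1L)
  if (ncol(X) != length(model$normalizer$mean))
    stop("feature vector does not match the model schema")
  X <- sweep(sweep(X, 2L, model$normalizer$mean), 2L, model$normalizer$sd,
             "/")
  probs <- vapply(model$members, function(m) {
    apply_calibration(m$calibrator, .member_raw(m, X))
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) mean(probs) else rowMeans(matrix(probs, nrow = nrow(X)))
}

# ---- hyper-parameter tuning ------------------------------------------

#' Tune SVM cost and kernel width by cross-validation
#'
#' Grid search maximising the mean long-range top-L/5 precision over
#' protein-level cross-validation folds: for each grid point and fold, a
#' single SVM is trained on the out-of-fold instances and the held-out
#' proteins' candidate pairs are ranked by their mean decision value; the
#' fold metric is the mean per-protein precision among the top
#' `floor(L/5)` long-range pairs. Ties prefer the smallest cost, then the
#' smallest gamma.
#'
#' @param subsets output of [make_training_set()].
#' @param cost_grid,gamma_grid numeric candidate grids.
#' @param k number of folds (capped at the number of proteins).
#' @param seed integer seed.
#' @param cfg configuration list.
#' @return List with `cost`, `gamma` and the full `results` grid.
#' @export
tune_hyperparameters <- function(subsets, cost_grid, gamma_grid, k = 10L,
                                 seed = 1L, cfg = dm_config()) {
  stopifnot(length(cost_grid) >= 1L, length(gamma_grid) >= 1L)
  X <- do.call(rbind, lapply(subsets, `[[`, "X"))
  y <- factor(unlist(lapply(subsets, function(s) as.character(s$y))),
              levels = c("native", "nonnative"))
  meta <- do.call(rbind, lapply(subsets, `[[`, "meta"))
  prots <- unique(meta$protein)
  k <- min(k, length(prots))
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(prots))),
                             prots)
  mu <- colMeans(X)
  sd <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xn <- sweep(sweep(X, 2L, mu), 2L, sd, "/")

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$score <- NA_real_
  for (g in seq_len(nrow(grid))) {
    fold_scores <- numeric(0)
    for (f in seq_len(k)) {
      te <- fold_of[meta$protein] == f
      if (!any(te) || length(unique(y[!te])) < 2L) next
      fit <- .fit_member_svm(Xn[!te, , drop = FALSE], y[!te],
                             grid$cost[g], grid$gamma[g])
      raw <- .member_raw(fit, Xn[te, , drop = FALSE])
      sub <- cbind(meta[te, , drop = FALSE],
                   raw = raw, lab = y[te] == "native")
      for (pid in unique(sub$protein)) {
        sp <- sub[sub$protein == pid, , drop = FALSE]
        agg <- stats::aggregate(cbind(raw, lab) ~ key, data = sp, FUN = mean)
        ij <- do.call(rbind, strsplit(agg$key, "_"))
        agg$sep <- as.integer(ij[, 2L]) - as.integer(ij[, 1L])
        long <- agg[agg$sep >= cfg$long_min, , drop = FALSE]
        if (!nrow(long)) next
        n_top <- max(1L, min(nrow(long), floor(sp$L[1L] / 5)))
        top <- long[order(-long$raw), , drop = FALSE][seq_len(n_top), ]
        fold_scores <- c(fold_scores, mean(top$lab > 0.5))
      }
    }
    grid$score[g] <- if (length(fold_scores)) mean(fold_scores) else 0
  }
  best <- grid[order(-grid$score, grid$cost, grid$gamma), ][1L, ]
  list(cost = best$cost, gamma = best$gamma, results = grid)
}
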