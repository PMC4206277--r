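# CASP-style evaluation: accuracy and coverage of the top-ranked fraction,
# stratified by sequence-separation range and alignment depth.

.in_range <- function(sep, range, cfg = dm_config()) {
  switch(range,
         medium = sep >= cfg$medium_range[1L] & sep <= cfg$medium_range[2L],
         long = sep >= cfg$long_min,
         all = rep(TRUE, length(sep)),
         stop("unknown range: ", range))
}

#' Filter contact pairs by sequence-separation range
#'
#' Medium-range keeps separations 12..23, long-range keeps >= 24 (CASP
#' convention), `"all"` keeps everything.
#'
#' @param pairs data frame (columns `i`, `j`) or two-column matrix.
#' @param range `"medium"`, `"long"` or `"all"`.
#' @param cfg configuration list.
#' @return The filtered pairs, same type as the input.
#' @export
range_filter <- function(pairs, range = c("long", "medium", "all"),
                         cfg = dm_config()) {
  range <- match.arg(range)
  if (is.matrix(pairs)) {
    pairs[.in_range(pairs[, 2L] - pairs[, 1L], range, cfg), , drop = FALSE]
  } else {
    pairs[.in_range(pairs$j - pairs$i, range, cfg), , drop = FALSE]
  }
}

#' Evaluate ranked predictions against a native contact map
#'
#' Takes the top `max(1, floor(L / divisor))` in-range predictions and
#' scores them against the native map: accuracy Acc = TP / (TP + FP) and
#' coverage Cov = TP_frac / TP_total, where TP_total is the number of
#' in-range native contacts. With no in-range native contacts the coverage
#' is undefined and reported as NA.
#'
#' @param ranked ranked predictions (data frame with `i`, `j`, best first).
#' @param native_cm the native `contact_map`.
#' @param L protein length.
#' @param fraction evaluated fraction: divisor 10, 5 or 2 (or strings
#'   "L/10", "L/5", "L/2").
#' @param range `"long"`, `"medium"` or `"all"`.
#' @param cfg configuration list.
#' @return One-row data frame: `range`, `fraction`, `n_eval`, `tp`, `fp`,
#'   `tp_total`, `acc`, `cov`.
#' @export
evaluate_predictions <- function(ranked, native_cm, L,
                                 fraction = 5, range = "long",
                                 cfg = dm_config()) {
  divisor <- if (is.character(fraction))
    as.numeric(sub("^L/", "", fraction)) else as.numeric(fraction)
  stopifnot(divisor >= 1)
  preds <- as.data.frame(ranked)
  preds <- preds[.in_range(preds$j - preds$i, range, cfg), , drop = FALSE]
  n_top <- max(1L, floor(L / divisor))
  n_eval <- min(n_top, nrow(preds))
  native_keys <- cm_keys(native_cm)
  nat_pairs <- native_cm$pairs
  tp_total <- sum(.in_range(nat_pairs[, 2L] - nat_pairs[, 1L], range, cfg))
  if (n_eval == 0L) {
    return(data.frame(range = range, fraction = paste0("L/", divisor),
                      n_eval = 0L, tp = 0L, fp = 0L, tp_total = tp_total,
                      acc = NA_real_,
                      cov = if (tp_total > 0L) 0 else NA_real_))
  }
  top <- preds[seq_len(n_eval), , drop = FALSE]
  tp <- sum(pair_keys(top$i, top$j) %in% native_keys)
  fp <- n_eval - tp
  data.frame(range = range, fraction = paste0("L/", divisor),
             n_eval = n_eval, tp = tp, fp = fp, tp_total = tp_total,
             acc = tp / (tp + fp),
             cov = if (tp_total > 0L) tp / tp_total else NA_real_)
}

#' Alignment-depth stratum of a protein
#'
#' @param depth number of sequences in the alignment.
#' @param L protein length.
#' @param factor depth threshold factor (default 5).
#' @return One of `"(1,1L]"`, `"(1L,5L]"`, `">5L"`.
#' @export
depth_stratum <- function(depth, L, factor = 5) {
  stopifnot(depth >= 1)
  if (depth <= L) "(1,1L]"
  else if (depth <= factor * L) "(1L,5L]"
  else ">5L"
}

#' Area under the ROC curve
#'
#' @param labels logical (or coercible) class labels, `TRUE` = positive.
#' @param scores numeric predictor, larger = more positive.
#' @return AUC in `[0, 1]`.
#' @export
contact_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("AUC needs both classes")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(r$auc)
}
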