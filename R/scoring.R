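# Per-pair score aggregation over the decoy ensemble, the occurrence-
# frequency (Counting) baseline, combination with evolutionary couplings
# and final ranking.

#' Combination weights
#'
#' Weights of the linear combination
#' `combined = S_svm + alpha * f + beta * g`, where `S_svm` is the ensemble
#' SVM probability, `f` the occurrence frequency across the selected decoys
#' and `g` the (per-protein min-max rescaled) evolutionary coupling score.
#' `beta_high` applies to proteins whose alignment depth exceeds
#' `depth_factor * L` sequences, `beta_low` otherwise; shallow alignments
#' carry weak coupling signal, so the two regimes are weighted separately.
#'
#' @param alpha frequency weight (>= 0).
#' @param beta_low,beta_high evolutionary weights for the shallow and deep
#'   alignment regimes.
#' @param depth_factor alignment-depth threshold factor (default 5).
#' @return A `combination_weights` list.
#' @export
combination_weights <- function(alpha = 1, beta_low = 0.5, beta_high = 2,
                                depth_factor = 5) {
  stopifnot(alpha >= 0, beta_low >= 0, beta_high >= 0)
  structure(list(alpha = alpha, beta_low = beta_low, beta_high = beta_high,
                 depth_factor = depth_factor),
            class = "combination_weights")
}

#' Occurrence frequencies over the selected decoys
#'
#' For every candidate pair (sequence separation at least
#' `cfg$candidate_min_separation`) observed in at least one selected decoy:
#' the number of decoys containing the contact and its frequency f = n/N.
#'
#' @param prep a prepared protein from [prepare_protein()].
#' @param cfg configuration list.
#' @return Data frame `i`, `j`, `n`, `f`, ordered by (i, j).
#' @export
occurrence_frequencies <- function(prep, cfg = dm_config()) {
  counts <- list()
  for (d in prep$decoys) {
    p <- d$candidates
    if (!nrow(p)) next
    k <- pair_keys(p)
    counts[[length(counts) + 1L]] <- k
  }
  keys <- unlist(counts)
  if (!length(keys)) {
    return(data.frame(i = integer(0), j = integer(0), n = integer(0),
                      f = numeric(0)))
  }
  tab <- table(keys)
  ij <- do.call(rbind, strsplit(names(tab), "_"))
  out <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                    n = as.integer(tab), f = as.integer(tab) / prep$N)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidate contacts over the decoy ensemble
#'
#' Every candidate contact present in every selected decoy is scored by the
#' SVM ensemble; the per-pair score `s_svm` is the mean probability over
#' the decoys that contain the pair, and `f = n/N` its occurrence
#' frequency. Pairs never observed in a selected decoy are absent.
#'
#' @param model an `svm_ensemble_model`.
#' @param prep a prepared protein from [prepare_protein()].
#' @param cfg configuration list.
#' @return A `contact_score_table`: data frame `i`, `j`, `s_svm`, `n`, `f`
#'   with attributes `L`, `N` and `protein`.
#' @export
score_contacts_over_decoys <- function(model, prep, cfg = dm_config()) {
  sums <- new.env(parent = emptyenv())
  for (d in prep$decoys) {
    p <- d$candidates
    if (!nrow(p)) next
    X <- .decoy_feature_matrix(prep, d, p, cfg)
    pr <- predict_contact_probability(model, X)
    ks <- pair_keys(p)
    for (r in seq_along(ks)) {
      prev <- sums[[ks[r]]] %||% c(0, 0)
      sums[[ks[r]]] <- prev + c(pr[r], 1)
    }
  }
  keys <- ls(sums)
  if (!length(keys)) {
    out <- data.frame(i = integer(0), j = integer(0), s_svm = numeric(0),
                      n = integer(0), f = numeric(0))
  } else {
    ij <- do.call(rbind, strsplit(keys, "_"))
    acc <- t(vapply(keys, function(k) sums[[k]], numeric(2L)))
    out <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                      s_svm = acc[, 1L] / acc[, 2L],
                      n = as.integer(acc[, 2L]),
                      f = acc[, 2L] / prep$N)
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("contact_score_table", "data.frame"),
            L = prep$L, N = prep$N, protein = prep$id)
}

#' Counting baseline: rank contacts by occurrence frequency
#'
#' The classical decoy-based predictor: candidate pairs ranked by how often
#' they occur in the selected low-energy decoys, ties broken by ascending
#' (i, j). Independent of the SVM and of evolutionary information.
#'
#' @param table a `contact_score_table` or any data frame with `i`, `j`,
#'   `f`.
#' @return The table ordered by descending `f` with a `rank` column.
#' @export
counting_baseline <- function(table) {
  ord <- order(-table$f, table$i, table$j)
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Combine SVM, frequency and evolutionary scores
#'
#' `combined = s_svm + alpha * f + beta * g`, with `beta` chosen by the
#' protein's alignment depth (deep regime when depth exceeds
#' `depth_factor * L`). Evolutionary scores are min-max rescaled to
#' `[0, 1]` per protein before weighting, since coupling methods scale
#' differently with alignment depth. Pairs carrying an evolutionary score
#' but never observed in a decoy enter with `s_svm = 0`, `f = 0`, so deep
#' alignments are not capped by decoy coverage.
#'
#' @param table a `contact_score_table`.
#' @param evo an `evolutionary_scores` table, or `NULL`.
#' @param weights a [combination_weights()].
#' @param depth alignment depth (number of sequences).
#' @param L protein length (default from the table attribute).
#' @param cfg configuration list.
#' @return The table with columns `g` and `combined` added.
#' @export
combine_scores <- function(table, evo, weights = combination_weights(),
                           depth = 1, L = NULL, cfg = dm_config()) {
  L <- L %||% attr(table, "L")
  tab <- as.data.frame(table)
  tab$g <- 0
  if (!is.null(evo) && nrow(evo)) {
    ev <- as.data.frame(evo)
    ev <- ev[ev$j - ev$i >= cfg$candidate_min_separation, , drop = FALSE]
    if (nrow(ev)) {
      rng <- range(ev$score)
      ev$g01 <- if (rng[2L] > rng[1L])
        (ev$score - rng[1L]) / (rng[2L] - rng[1L]) else 1
      m <- match(pair_keys(tab$i, tab$j), pair_keys(ev$i, ev$j))
      tab$g <- ifelse(is.na(m), 0, ev$g01[m])
      extra <- ev[!pair_keys(ev$i, ev$j) %in% pair_keys(tab$i, tab$j), ,
                  drop = FALSE]
      if (nrow(extra)) {
        add <- data.frame(i = extra$i, j = extra$j, s_svm = 0,
                          n = 0L, f = 0, g = extra$g01)
        for (nm in setdiff(names(tab), names(add))) add[[nm]] <- NA
        tab <- rbind(tab, add[names(tab)])
      }
    }
  }
  beta <- if (depth > weights$depth_factor * L) weights$beta_high
          else weights$beta_low
  tab$combined <- tab$s_svm + weights$alpha * tab$f + beta * tab$g
  tab <- tab[order(tab$i, tab$j), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("contact_score_table", "data.frame"),
            L = L, N = attr(table, "N"), protein = attr(table, "protein"))
}

#' Rank contacts by combined score
#'
#' Descending combined score; ties broken by descending frequency, then
#' ascending (i, j). Optionally filtered to a sequence-separation range.
#'
#' @param table a `contact_score_table` with a `combined` column.
#' @param range `"long"` (j - i >= 24), `"medium"` (12..23) or `"all"`.
#' @param cfg configuration list.
#' @return The filtered, ordered table with a `rank` column.
#' @export
rank_contacts <- function(table, range = c("long", "medium", "all"),
                          cfg = dm_config()) {
  range <- match.arg(range)
  tab <- as.data.frame(table)
  tab <- tab[.in_range(tab$j - tab$i, range, cfg), , drop = FALSE]
  ord <- order(-tab$combined, -tab$f, tab$i, tab$j)
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("contact_score_table", "data.frame"),
            L = attr(table, "L"), N = attr(table, "N"),
            protein = attr(table, "protein"))
}

#' Tune the combination weights
#'
#' Grid search over (alpha, beta) maximising the mean long-range top-L/5
#' accuracy under protein-level cross-validation, tuned separately for the
#' shallow (depth <= depth_factor * L) and deep (depth > depth_factor * L)
#' alignment strata. If a stratum is empty its beta inherits the other
#' stratum's value with a warning. Ties prefer smaller beta, then smaller
#' alpha; the final alpha is the one maximising the pooled accuracy given
#' each stratum's best beta.
#'
#' @param tables list of per-protein lists with elements `table`
#'   (scored `contact_score_table`), `evo`, `depth`, `L`, `native_cm`.
#' @param alpha_grid,beta_grid candidate weights.
#' @param k number of cross-validation folds (capped at stratum size).
#' @param seed integer seed.
#' @param cfg configuration list.
#' @return A [combination_weights()] with attribute `results`.
#' @export
tune_combination_weights <- function(tables, alpha_grid, beta_grid, k = 5L,
                                     seed = 1L, cfg = dm_config()) {
  stopifnot(length(alpha_grid) >= 1L, length(beta_grid) >= 1L)
  set.seed(seed)
  deep <- vapply(tables, function(x) x$depth > cfg$depth_factor * x$L,
                 logical(1L))
  acc_one <- function(entry, alpha, beta) {
    w <- combination_weights(alpha, beta, beta, cfg$depth_factor)
    comb <- combine_scores(entry$table, entry$evo, w, entry$depth, entry$L,
                           cfg)
    ranked <- rank_contacts(comb, "long", cfg)
    row <- evaluate_predictions(ranked, entry$native_cm, entry$L, 5,
                                range = "long", cfg = cfg)
    row$acc
  }
  stratum_best <- function(entries) {
    grid <- expand.grid(alpha = alpha_grid, beta = beta_grid)
    folds <- sample(rep_len(seq_len(min(k, length(entries))),
                            length(entries)))
    grid$score <- vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(entries, acc_one, numeric(1L),
                     alpha = grid$alpha[g], beta = grid$beta[g])
      mean(vapply(unique(folds), function(f) mean(accs[folds == f]),
                  numeric(1L)))
    }, numeric(1L))
    grid[order(-grid$score, grid$beta, grid$alpha), ]
  }
  res_low <- if (any(!deep)) stratum_best(tables[!deep]) else NULL
  res_high <- if (any(deep)) stratum_best(tables[deep]) else NULL
  if (is.null(res_low) && is.null(res_high))
    stop("no proteins to tune on")
  if (is.null(res_low)) {
    warning("shallow-alignment stratum empty; beta_low inherits beta_high")
    res_low <- res_high
  }
  if (is.null(res_high)) {
    warning("deep-alignment stratum empty; beta_high inherits beta_low")
    res_high <- res_low
  }
  out <- combination_weights(alpha = res_high$alpha[1L],
                             beta_low = res_low$beta[1L],
                             beta_high = res_high$beta[1L],
                             depth_factor = cfg$depth_factor)
  attr(out, "results") <- list(low = res_low, high = res_high)
  out
}
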