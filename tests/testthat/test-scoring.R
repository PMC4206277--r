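fake_table <- function(df, L = 60, N = 4) {
  structure(df, class = c("contact_score_table", "data.frame"),
            L = L, N = N, protein = "p")
}

test_that("per-pair aggregation averages over the decoys containing a pair", {
  bench <- get_mini_benchmark()
  corpus <- get_mini_corpus()
  id <- corpus$test_ids[1]
  tab <- bench$tables[[id]]
  prep <- prepare_protein(corpus$proteins[[id]], dm_config()$predict_fraction)
  expect_equal(attr(tab, "N"), prep$N)
  expect_true(all(tab$f >= 1 / prep$N & tab$f <= 1))
  expect_equal(tab$f, tab$n / prep$N)
  expect_true(all(tab$s_svm >= 0 & tab$s_svm <= 1))
  # pairs come only from observed decoy contacts, candidate separations only
  expect_true(all(tab$j - tab$i >= 12))
  freq <- occurrence_frequencies(prep)
  expect_equal(as.data.frame(tab)[c("i", "j", "n", "f")],
               freq[c("i", "j", "n", "f")])

  # manual recount of one pair across decoys
  k <- which.max(tab$n)
  key <- decoymap:::pair_keys(tab$i[k], tab$j[k])
  in_decoys <- sum(vapply(prep$decoys, function(d)
    key %in% decoymap:::pair_keys(d$candidates), logical(1)))
  expect_equal(tab$n[k], in_decoys)
})

test_that("the Counting baseline ranks by frequency with index tie-breaks", {
  tab <- fake_table(data.frame(i = c(1L, 5L, 2L, 9L),
                               j = c(30L, 40L, 30L, 44L),
                               s_svm = c(0.1, 0.9, 0.4, 0.2),
                               n = c(9L, 5L, 5L, 1L),
                               f = c(0.9, 0.5, 0.5, 0.1)))
  rk <- counting_baseline(tab)
  expect_equal(rk$rank, 1:4)
  expect_equal(rk$f, c(0.9, 0.5, 0.5, 0.1))
  # tie between (5,40) and (2,30): ascending index wins
  expect_equal(rk$i[2:3], c(2L, 5L))
  # invariant to the SVM column
  tab2 <- tab
  tab2$s_svm <- rev(tab2$s_svm)
  expect_equal(counting_baseline(tab2)[c("i", "j", "rank")],
               rk[c("i", "j", "rank")])
})

test_that("score combination is the documented weighted linear sum", {
  tab <- fake_table(data.frame(i = 1L, j = 30L, s_svm = 0.5, n = 2L,
                               f = 0.2))
  evo <- structure(data.frame(i = c(1L, 2L), j = c(30L, 40L),
                              score = c(1, 0)),
                   class = c("evolutionary_scores", "data.frame"))
  w <- combination_weights(alpha = 0.1, beta_low = 0.3, beta_high = 9)
  comb <- combine_scores(tab, evo, w, depth = 10, L = 60)
  row <- comb[comb$i == 1 & comb$j == 30, ]
  expect_equal(row$combined, 0.5 + 0.1 * 0.2 + 0.3 * 1.0)  # = 0.82

  # evolutionary-only pairs enter with S = 0, f = 0
  extra <- comb[comb$i == 2 & comb$j == 40, ]
  expect_equal(extra$s_svm, 0)
  expect_equal(extra$f, 0)

  # deep alignments switch to beta_high at depth > 5L
  deep <- combine_scores(tab, evo, w, depth = 5 * 60 + 1, L = 60)
  expect_equal(deep$combined[deep$i == 1], 0.5 + 0.1 * 0.2 + 9 * 1.0)
  shallow <- combine_scores(tab, evo, w, depth = 5 * 60, L = 60)
  expect_equal(shallow$combined[shallow$i == 1], 0.82)

  # without evolutionary scores the ranking reduces to S + alpha f
  comb0 <- combine_scores(tab, NULL, w, depth = 10, L = 60)
  expect_equal(comb0$combined, 0.5 + 0.1 * 0.2)

  # monotone in each input
  base <- combine_scores(fake_table(data.frame(i = 1L, j = 30L, s_svm = 0.5,
                                               n = 2L, f = 0.2)),
                         evo, w, 10, 60)$combined[1]
  up_s <- combine_scores(fake_table(data.frame(i = 1L, j = 30L, s_svm = 0.6,
                                               n = 2L, f = 0.2)),
                         evo, w, 10, 60)$combined[1]
  expect_gt(up_s, base)
})

test_that("ranking filters separations and breaks ties by f then index", {
  tab <- fake_table(data.frame(
    i = c(1L, 1L, 2L, 3L), j = c(30L, 15L, 40L, 27L),
    s_svm = c(0.2, 0.9, 0.2, 0.2), n = 1L,
    f = c(0.5, 0.5, 0.9, 0.5), g = 0,
    combined = c(0.7, 1.4, 0.7, 0.7)))
  long <- rank_contacts(tab, "long")
  expect_true(all(long$j - long$i >= 24))        # (1,15) removed
  expect_equal(long$rank, seq_len(nrow(long)))
  # ties on combined: higher f first, then ascending (i, j)
  expect_equal(long$i, c(2L, 1L, 3L))
  med <- rank_contacts(tab, "medium")
  expect_equal(nrow(med), 1L)
  expect_identical(rank_contacts(tab, "long"), long)  # stable rerun
})

test_that("with zero weights the combined ranking follows the SVM score", {
  bench <- get_mini_benchmark()
  corpus <- get_mini_corpus()
  id <- corpus$test_ids[2]
  tab <- bench$tables[[id]]
  w0 <- combination_weights(0, 0, 0)
  comb <- combine_scores(tab, corpus$proteins[[id]]$evo, w0,
                         corpus$proteins[[id]]$depth, attr(tab, "L"))
  observed <- comb[comb$n > 0, ]
  expect_equal(order(-observed$combined), order(-observed$s_svm))
})

test_that("combination-weight tuning prefers informative couplings", {
  corpus <- get_mini_corpus()
  bench <- get_mini_benchmark()
  # construct per-protein entries whose evolutionary scores are exact
  # native indicators: the largest beta must win in the deep stratum
  entries <- lapply(corpus$test_ids[1:3], function(id) {
    ctx <- corpus$proteins[[id]]
    nat <- ctx$native_cm$pairs
    nat <- nat[nat[, 2] - nat[, 1] >= 12, , drop = FALSE]
    oracle <- structure(data.frame(i = nat[, 1], j = nat[, 2], score = 1),
                        class = c("evolutionary_scores", "data.frame"))
    list(table = bench$tables[[id]], evo = oracle,
         depth = 6 * ctx$L, L = ctx$L, native_cm = ctx$native_cm)
  })
  w <- suppressWarnings(
    tune_combination_weights(entries, alpha_grid = 0, beta_grid = c(0, 5),
                             seed = 1))
  expect_equal(w$beta_high, 5)
  # degenerate all-zero grid
  w0 <- suppressWarnings(
    tune_combination_weights(entries, alpha_grid = 0, beta_grid = 0,
                             seed = 1))
  expect_equal(c(w0$alpha, w0$beta_low, w0$beta_high), c(0, 0, 0))
})
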