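blob_subsets <- function(n_per = 60, d = 6, sep = 6, seed = 21) {
  set.seed(seed)
  lapply(1:5, function(m) {
    Xp <- matrix(stats::rnorm(n_per * d), n_per) + sep / 2
    Xn <- matrix(stats::rnorm(3 * n_per * d), 3 * n_per) - sep / 2
    list(X = rbind(Xp, Xn),
         y = factor(rep(c("native", "nonnative"), c(n_per, 3 * n_per)),
                    levels = c("native", "nonnative")),
         meta = NULL)
  })
}

test_that("bin calibration spans the percentiles and conserves mass", {
  set.seed(31)
  raw <- stats::runif(500)
  lab <- raw > 0.5
  cal <- calibrate_bins(raw, lab)
  expect_length(cal$edges, 11)
  expect_equal(cal$edges[1], unname(stats::quantile(raw, 0.05)))
  expect_equal(cal$edges[11], unname(stats::quantile(raw, 0.95)))
  # bins below the decision point are ~0, above ~1
  expect_lt(mean(cal$prob[1:4]), 0.05)
  expect_gt(mean(cal$prob[7:10]), 0.95)
  # clamping: far outside scores inherit the extreme bins
  expect_equal(apply_calibration(cal, -10), cal$prob[1])
  expect_equal(apply_calibration(cal, 10), cal$prob[10])

  # count-weighted mean of bin probabilities equals the native fraction
  noisy_lab <- stats::runif(500) < 0.3
  cal2 <- calibrate_bins(raw, noisy_lab)
  expect_equal(sum(cal2$prob * cal2$counts) / sum(cal2$counts),
               mean(noisy_lab), tolerance = 1e-12)

  expect_error(calibrate_bins(raw[1:10], lab[1:10]), "20")
  expect_error(calibrate_bins(raw, rep(TRUE, 500)), "classes")
})

test_that("separable data trains a perfect, unit-normalised ensemble", {
  subsets <- blob_subsets()
  model <- train_ensemble(subsets, cost = 10, gamma = 0.1, seed = 3)
  expect_length(model$members, 5)

  # the normaliser gives zero mean and unit sd on the pooled training data
  allX <- do.call(rbind, lapply(subsets, `[[`, "X"))
  Xn <- sweep(sweep(allX, 2, model$normalizer$mean), 2,
              model$normalizer$sd, "/")
  expect_equal(colMeans(Xn), rep(0, ncol(allX)), tolerance = 1e-10)
  expect_equal(apply(Xn, 2, stats::sd), rep(1, ncol(allX)),
               tolerance = 1e-10)

  # training points are classified perfectly by the calibrated ensemble
  p_pos <- predict_contact_probability(model, subsets[[1]]$X[1:60, ])
  p_neg <- predict_contact_probability(model, subsets[[1]]$X[61:240, ])
  expect_gt(min(p_pos), 0.5)
  expect_lt(max(p_neg), 0.5)
  expect_true(all(c(p_pos, p_neg) >= 0 & c(p_pos, p_neg) <= 1))

  # schema mismatch is fatal
  expect_error(predict_contact_probability(model, stats::rnorm(3)), "schema")

  # single-class subsets cannot be trained
  bad <- subsets
  bad[[2]]$y <- factor(rep("native", length(bad[[2]]$y)),
                       levels = c("native", "nonnative"))
  expect_error(train_ensemble(bad, cost = 10, gamma = 0.1), "class")
})

test_that("ensemble averaging is the mean of member probabilities", {
  subsets <- blob_subsets(seed = 22)
  model <- train_ensemble(subsets, cost = 10, gamma = 0.1, seed = 3)
  X <- rbind(subsets[[2]]$X, subsets[[3]]$X)
  Xn <- sweep(sweep(X, 2, model$normalizer$mean), 2, model$normalizer$sd,
              "/")
  member_p <- vapply(model$members, function(m) {
    apply_calibration(m$calibrator, decoymap:::.member_raw(m, Xn))
  }, numeric(nrow(X)))
  expect_equal(rowMeans(member_p), predict_contact_probability(model, X),
               tolerance = 1e-12)
  # averaging reduces variance relative to the members
  expect_lte(stats::var(rowMeans(member_p)),
             mean(apply(member_p, 2, stats::var)) + 1e-12)
})

test_that("training-set construction undersamples 50/150 deterministically", {
  corpus <- get_mini_corpus()
  subsets <- make_training_set(list(proteins = corpus$proteins[1:6]),
                               seed = 5)
  expect_length(subsets, 5)
  meta <- do.call(rbind, lapply(subsets, `[[`, "meta"))
  y <- unlist(lapply(subsets, function(s) as.character(s$y)))
  # per-protein caps: never more than 50 native / 150 non-native
  for (pid in unique(meta$protein)) {
    sel <- meta$protein == pid
    expect_lte(sum(y[sel] == "native"), 50)
    expect_lte(sum(y[sel] == "nonnative"), 150)
  }
  # each protein lands in exactly one subset
  prot_member <- lapply(subsets, function(s) unique(s$meta$protein))
  expect_equal(anyDuplicated(unlist(prot_member)), 0L)

  # a protein with surplus instances is clamped to exactly 50 + 150
  ctx <- corpus$proteins[[1]]
  prep <- prepare_protein(ctx, dm_config()$train_fraction)
  inst <- decoymap:::.enumerate_instances(prep, dm_config())
  nat <- inst$meta$key %in% decoymap:::cm_keys(ctx$native_cm)
  sel <- meta$protein == ctx$id
  expect_equal(sum(y[sel] == "native"), min(50L, sum(nat)))
  expect_equal(sum(y[sel] == "nonnative"), min(150L, sum(!nat)))

  # same seed reproduces the identical instance lists
  subsets2 <- make_training_set(list(proteins = corpus$proteins[1:6]),
                                seed = 5)
  expect_identical(lapply(subsets, `[[`, "meta"),
                   lapply(subsets2, `[[`, "meta"))
  expect_equal(subsets[[1]]$X, subsets2[[1]]$X)
})

test_that("hyper-parameter tuning returns grid optima deterministically", {
  corpus <- get_mini_corpus()
  subsets <- cache_get("tune_subsets", function()
    make_training_set(list(proteins = corpus$proteins[1:6]), seed = 5))

  # single-point grid: that point
  one <- tune_hyperparameters(subsets, 10, 1 / 238, k = 3, seed = 2)
  expect_equal(one$cost, 10)
  expect_equal(one$gamma, 1 / 238)

  # a pathologically narrow kernel cannot generalise: the planted optimum
  # (moderate gamma) wins
  two <- tune_hyperparameters(subsets, 10, c(1 / 238, 1e6), k = 3, seed = 2)
  expect_equal(two$gamma, 1 / 238)

  rerun <- tune_hyperparameters(subsets, 10, c(1 / 238, 1e6), k = 3,
                                seed = 2)
  expect_identical(two$results, rerun$results)
})
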