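test_that("synthetic natives are stereochemically sane, compact globules", {
  spec <- synthetic_protein_spec(L = 60, seed = 42)
  nat <- make_native(spec)
  s <- nat$structure
  expect_equal(s$L, 60L)
  ca <- s$bb$CA
  d <- sqrt(rowSums((ca[-1, ] - ca[-60, ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  expect_length(s$chain_breaks, 0)
  # contains medium/long-range contacts to learn from
  sep <- nat$cm$pairs[, 2] - nat$cm$pairs[, 1]
  expect_gt(sum(sep >= 12), 30)
  expect_gt(sum(sep >= 24), 5)

  # an all-helix chain shows the (i, i+4) helical contact ladder
  helix <- make_native(synthetic_protein_spec(
    L = 30, topology = data.frame(type = "H", len = 30), seed = 1))
  keys <- decoymap:::cm_keys(helix$cm)
  ladder <- decoymap:::pair_keys(1:26, 5:30)
  expect_gt(sum(ladder %in% keys), 20)

  # same seed, same coordinates; different seed, different fold
  nat2 <- make_native(spec)
  expect_identical(s$atoms, nat2$structure$atoms)
  nat3 <- make_native(synthetic_protein_spec(L = 60, seed = 43))
  expect_false(isTRUE(all.equal(s$atoms$x, nat3$structure$atoms$x)))

  expect_error(make_native(synthetic_protein_spec(
    L = 60, topology = data.frame(type = "H", len = 30), seed = 1)), "sum")
})

test_that("decoy tiers degrade contact maps gradually and energies track RMSD", {
  spec <- synthetic_protein_spec(L = 60, n_decoys = 24, seed = 11)
  nat <- make_native(spec)
  natk <- decoymap:::cm_keys(nat$cm)
  jac <- function(ens, idx) {
    mean(vapply(ens$decoys[idx], function(d) {
      k <- decoymap:::cm_keys(compute_contact_map(d))
      length(intersect(k, natk)) / length(union(k, natk))
    }, numeric(1)))
  }
  # near-zero noise tier: nearly the native map
  tight <- spec; tight$sigma_ladder <- 0.2
  expect_gt(jac(make_decoys(nat, tight), 1:8), 0.9)
  # far tier: mostly non-native
  wide <- spec; wide$sigma_ladder <- 4
  expect_lt(jac(make_decoys(nat, wide), 1:8), 0.5)

  # energies rank-correlate with nativeness across the mixed ensemble
  ens <- make_decoys(nat, spec)
  expect_gt(stats::cor(ens$meta$rmsd, unname(ens$energies),
                       method = "spearman"), 0.5)
  # determinism
  ens2 <- make_decoys(nat, spec)
  expect_identical(ens$energies, ens2$energies)
  expect_identical(ens$decoys[[5]]$atoms, ens2$decoys[[5]]$atoms)
})

test_that("planted co-evolution dominates the coupling scores", {
  spec <- synthetic_protein_spec(L = 60, msa_depth = 500, seed = 13)
  nat <- make_native(spec)
  al <- make_msa(nat$sequence, nat$cm, spec)
  expect_equal(al$msa$depth, 500L)
  expect_identical(al$msa$mat[1, ], nat$sequence)
  expect_gt(nrow(al$planted), 5)

  sc <- as.data.frame(al$scores)
  keys <- decoymap:::pair_keys(sc$i, sc$j)
  pk <- decoymap:::pair_keys(al$planted)
  planted_scores <- sc$score[keys %in% pk]
  background <- sc$score[!keys %in% pk]
  expect_true(all(planted_scores >
                    stats::quantile(background, 0.95)))

  # depth 1: no coupling signal at all
  flat <- spec; flat$msa_depth <- 1L
  al1 <- make_msa(nat$sequence, nat$cm, flat)
  expect_true(all(al1$scores$score == 0))

  # seeded regeneration is identical
  al2 <- make_msa(nat$sequence, nat$cm, spec)
  expect_identical(al$msa$mat, al2$msa$mat)
})

test_that("corpora are split disjointly and support the core premise", {
  corpus <- get_mini_corpus()
  expect_length(corpus$proteins, 10)
  expect_length(intersect(corpus$train_ids, corpus$test_ids), 0)
  expect_setequal(c(corpus$train_ids, corpus$test_ids),
                  names(corpus$proteins))

  # native contacts occur more frequently in low-energy decoys than
  # non-native ones
  ctx <- corpus$proteins[[2]]
  prep <- prepare_protein(ctx, 0.05)
  freq <- occurrence_frequencies(prep)
  nat <- decoymap:::pair_keys(freq$i, freq$j) %in%
    decoymap:::cm_keys(ctx$native_cm)
  expect_gt(mean(freq$f[nat]), mean(freq$f[!nat]))
})

test_that("written systems are read back by the package's own readers", {
  dir <- withr::local_tempdir()
  corpus <- make_corpus(6, synthetic_protein_spec(L = 30, n_decoys = 6,
                                                  msa_depth = 20), seed = 2)
  ctx <- corpus$proteins[[1]]
  write_protein_system(ctx, dir)
  s <- read_structure(file.path(dir, "native.pdb"))
  expect_equal(s$L, ctx$native$L)
  expect_equal(s$seq, ctx$native$seq)
  expect_equal(unname(s$bb$CA), unname(ctx$native$bb$CA),
               tolerance = 1e-3)
  e <- read_energy_table(file.path(dir, "energies.tsv"))
  expect_equal(length(e), 6L)
  m <- read_msa(file.path(dir, "alignment.fasta"))
  expect_equal(m$depth, 20L)
  expect_equal(paste(m$mat[1, ], collapse = ""),
               paste(ctx$sequence, collapse = ""))
  ev <- read_evolutionary_scores(file.path(dir, "evo_scores.tsv"),
                                 L = ctx$L)
  expect_equal(nrow(ev), nrow(ctx$evo))
})
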