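test_that("PDB parsing resolves residues, altLocs and the glycine rule", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(path)
  s <- read_structure(path)
  expect_equal(s$L, 3L)
  expect_equal(s$seq, c("A", "G", "L"))

  # highest-occupancy altLoc retained for the ALA CB
  r1 <- residue(s, 1)
  expect_equal(unname(r1$atoms["CB", ]), c(2.0, -1.0, 1.0))
  expect_equal(contact_atom(r1), c(2.0, -1.0, 1.0))

  # glycine contact atom falls back to CA, silently
  r2 <- residue(s, 2)
  expect_equal(contact_atom(r2), unname(r2$atoms["CA", ]))

  # non-glycine residue without CB warns and falls back to CA
  r3 <- residue(s, 3)
  r3$atoms <- r3$atoms[rownames(r3$atoms) != "CB", , drop = FALSE]
  expect_warning(out <- contact_atom(r3), "CA")
  expect_equal(out, unname(r3$atoms["CA", ]))

  expect_error(read_structure(path, chain = "Z"), "chain")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")))
})

test_that("contact maps respect the threshold, separation and symmetry", {
  # two contact atoms at a controlled distance
  two_res <- function(d) {
    atoms <- data.frame(
      res = c(1L, 1L, 2L, 2L),
      atom = c("CA", "CB", "CA", "CB"),
      elem = "C",
      x = c(0, 0, 0, d), y = 0, z = 0)
    decoymap:::.new_protein_structure("t", "A", c("A", "A"), atoms)
  }
  expect_equal(nrow(compute_contact_map(two_res(7.9))$pairs), 1L)
  expect_equal(nrow(compute_contact_map(two_res(8.1))$pairs), 0L)

  nat <- make_native(synthetic_protein_spec(L = 30, seed = 4))
  cm <- compute_contact_map(nat$structure)
  # i < j everywhere and no self-pairs: symmetric by construction
  expect_true(all(cm$pairs[, 1] < cm$pairs[, 2]))
  # idempotent: re-reading the same coordinates gives the same map
  cm2 <- compute_contact_map(nat$structure)
  expect_identical(cm$pairs, cm2$pairs)
  # min_separation filters chain neighbours
  cm12 <- compute_contact_map(nat$structure, min_separation = 12)
  expect_true(all(cm12$pairs[, 2] - cm12$pairs[, 1] >= 12))
})

test_that("energy tables parse, reject duplicates and gate selection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\t-3.2", "d2\t-1.0", "d3\t-5.5"), path)
  e <- read_energy_table(path)
  expect_equal(unname(e["d3"]), -5.5)
  expect_equal(length(e), 3L)

  writeLines(c("decoy_id\tenergy", "d1\t-3.2", "d1\t-1.0"), path)
  expect_error(read_energy_table(path), "duplicate")

  expect_error(decoy_ensemble(list(list(id = "a")), c(b = 1)),
               "without energy")
})

test_that("low-energy selection uses the ceiling and is nested", {
  expect_equal(length(select_low_energy(fake_ensemble(1000), 0.02)$selected),
               20L)
  expect_equal(length(select_low_energy(fake_ensemble(200), 0.03)$selected),
               6L)
  # equal energies: first ceil(f*N) by id
  ens <- fake_ensemble(10, energies = rep(1, 10))
  expect_equal(select_low_energy(ens, 0.3)$selected,
               sprintf("d%04d", 1:3))
  # full fraction returns everything; selections are nested in fraction
  ens <- fake_ensemble(50, energies = stats::rnorm(50))
  all50 <- select_low_energy(ens, 1)$selected
  expect_setequal(all50, names(ens$decoys))
  prev <- character(0)
  for (f in c(0.1, 0.25, 0.5, 1)) {
    cur <- select_low_energy(ens, f)$selected
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(select_low_energy(ens, 0), "fraction")
})

test_that("MSA reader handles FASTA and A3M insertion states", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACDEF"), path)
  m <- read_msa(path)
  expect_equal(m$depth, 1L)
  expect_equal(m$L, 5L)
  # depth-1 conservation defaults to 1 per column
  expect_equal(conservation_profile(m)$conservation, rep(1, 5))

  writeLines(c(">q", "ACDEF", ">h1", "AaaCDEF", ">h2", "GCDEggF"), path)
  m <- read_msa(path)
  expect_equal(m$depth, 3L)
  expect_equal(m$L, 5L)
  expect_equal(paste(m$mat[2, ], collapse = ""), "ACDEF")

  writeLines(c(">q", "ACDEF", ">bad", "ACD"), path)
  expect_error(read_msa(path), "ragged")
})

test_that("evolutionary score files normalise, deduplicate and default to 0", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("3\t10\t1.25"), path)
  es <- read_evolutionary_scores(path)
  expect_equal(evo_score(es, 3, 10), 1.25)
  expect_equal(evo_score(es, 10, 3), 1.25)
  expect_equal(evo_score(es, 1, 2), 0)

  writeLines(c("10\t3\t1.0", "3\t10\t2.0"), path)
  expect_warning(es <- read_evolutionary_scores(path), "duplicate")
  expect_equal(evo_score(es, 3, 10), 2.0)

  writeLines(c("3\t99\t1.0"), path)
  expect_error(read_evolutionary_scores(path, L = 50), "outside")
})

test_that("RR files round-trip ranked contacts to six decimals", {
  scores <- data.frame(i = c(3L, 1L, 7L), j = c(30L, 25L, 40L),
                       score = c(0.123456, 0.9, 0.5))
  path <- withr::local_tempfile(fileext = ".rr")
  write_rr(scores, path, sequence = strrep("A", 60))
  back <- read_rr(path)
  expect_equal(nchar(back$sequence), 60L)
  expect_equal(back$scores$d1, rep(0, 3))
  expect_equal(back$scores$d2, rep(8, 3))
  # rows in descending score order
  expect_true(all(diff(back$scores$score) <= 0))
  # round trip preserves (i, j, score)
  m <- back$scores[order(back$scores$i), ]
  o <- scores[order(scores$i), ]
  expect_equal(m$i, o$i)
  expect_equal(m$j, o$j)
  expect_equal(m$score, o$score, tolerance = 1e-9)
})
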