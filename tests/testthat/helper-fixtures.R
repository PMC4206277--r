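# shared fixtures; expensive objects are built once per test run and cached

.test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- builder()
  .test_cache[[key]]
}

# a bare contact map object for graph-construction tests
make_cm <- function(L, pairs) {
  p <- matrix(as.integer(pairs), ncol = 2L, byrow = TRUE)
  p <- cbind(pmin(p[, 1L], p[, 2L]), pmax(p[, 1L], p[, 2L]))
  p <- p[order(p[, 1L], p[, 2L]), , drop = FALSE]
  structure(list(L = as.integer(L), pairs = p, threshold = 8,
                 min_separation = 1L),
            class = "contact_map")
}

# hand-written fixed-width PDB ATOM line
pdb_line <- function(serial, name, alt, res, chain, resno, x, y, z,
                     occ = 1, elem = substr(name, 1, 1), record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, res, chain, resno,
          x, y, z, occ, 0, elem)
}

# three-residue fixture: ALA (with CB, altLoc A/B on CB), GLY (no CB), LEU
write_test_pdb <- function(path) {
  lines <- c(
    pdb_line(1, "N",  " ", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_line(2, "CA", " ", "ALA", "A", 1, 1.458, 0.0, 0.0),
    pdb_line(3, "C",  " ", "ALA", "A", 1, 2.0, 1.4, 0.0),
    pdb_line(4, "O",  " ", "ALA", "A", 1, 1.5, 2.5, 0.0),
    pdb_line(5, "CB", "A", "ALA", "A", 1, 2.0, -1.0, 1.0, occ = 0.6),
    pdb_line(6, "CB", "B", "ALA", "A", 1, 9.0, 9.0, 9.0, occ = 0.4),
    pdb_line(7, "N",  " ", "GLY", "A", 2, 3.3, 1.5, 0.0),
    pdb_line(8, "CA", " ", "GLY", "A", 2, 4.2, 2.6, 0.2),
    pdb_line(9, "C",  " ", "GLY", "A", 2, 5.6, 2.1, 0.4),
    pdb_line(10, "O", " ", "GLY", "A", 2, 5.9, 0.9, 0.4),
    pdb_line(11, "N", " ", "LEU", "A", 3, 6.5, 3.1, 0.6),
    pdb_line(12, "CA", " ", "LEU", "A", 3, 7.9, 2.8, 0.9),
    pdb_line(13, "C", " ", "LEU", "A", 3, 8.7, 4.1, 1.1),
    pdb_line(14, "O", " ", "LEU", "A", 3, 8.2, 5.2, 1.0),
    pdb_line(15, "CB", " ", "LEU", "A", 3, 8.5, 2.0, -0.3),
    "TER",
    "END")
  writeLines(lines, path)
  path
}

# the worked contact-map fixture used across graph tests
fixture_cm12 <- function() {
  make_cm(12, c(3, 10, 2, 10, 4, 9, 1, 11, 5, 8))
}

# light-weight fake decoys: enough structure for energy-based selection
fake_ensemble <- function(n, energies = NULL) {
  ids <- sprintf("d%04d", seq_len(n))
  decoys <- lapply(ids, function(id) list(id = id))
  if (is.null(energies)) energies <- stats::setNames(seq_len(n), ids)
  else energies <- stats::setNames(energies, ids)
  decoy_ensemble(decoys, energies)
}

# reduced-size corpus shared by the ml / scoring / pipeline tests
get_mini_corpus <- function() {
  cache_get("mini_corpus", function() {
    make_corpus(10, synthetic_protein_spec(L = 50, n_decoys = 100,
                                           msa_depth = 150), seed = 7)
  })
}

get_mini_benchmark <- function() {
  cache_get("mini_benchmark", function() {
    suppressWarnings(run_contact_benchmark(get_mini_corpus(), seed = 7))
  })
}

# one prepared protein + labels from the mini corpus (feature-level tests)
get_mini_prep <- function() {
  cache_get("mini_prep", function() {
    prepare_protein(get_mini_corpus()$proteins[[1]], fraction = 0.04)
  })
}

# full-size study corpus and benchmark (acceptance suite)
get_full_benchmark <- function() {
  cache_get("full_benchmark", function() {
    corpus <- make_corpus(12, synthetic_protein_spec(), seed = 1)
    res <- suppressWarnings(run_contact_benchmark(corpus, seed = 1))
    res$corpus <- corpus
    res
  })
}
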