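# Seeded generator of toy study systems: compact single-chain natives built
# from ideal secondary-structure geometry, decoy ensembles with an
# RMSD-linked energy, alignments with planted co-evolving column pairs and
# the matching coupling-score files. All randomness flows from one seed per
# protein, so every artefact regenerates identically.

#' Specification of one synthetic protein system
#'
#' @param L chain length in residues.
#' @param topology segment recipe: data frame with columns `type`
#'   ("H", "E" or "C") and `len`, summing to `L`; `NULL` draws a seeded
#'   mixed helix/strand recipe.
#' @param n_decoys number of decoys to generate.
#' @param sigma_ladder per-coordinate perturbation scales (Angstrom) of the
#'   three nativeness tiers (very close, relatively close, far).
#' @param rho along-chain correlation of the perturbation (Ornstein-
#'   Uhlenbeck autocorrelation per residue step).
#' @param energy_a,energy_s energy model: energy = `energy_a` * RMSD +
#'   Gaussian noise with sd `energy_s` (arbitrary energy units).
#' @param msa_depth number of alignment rows.
#' @param plant_fraction fraction of medium/long-range native contacts
#'   planted as co-evolving column pairs.
#' @param cons_level probability that a non-planted alignment position
#'   keeps the query residue.
#' @param mut_rate per-position noise rate on planted columns.
#' @param seed integer seed.
#' @return A `synthetic_protein_spec` list.
#' @export
synthetic_protein_spec <- function(L = 60L, topology = NULL, n_decoys = 200L,
                                   sigma_ladder = c(1.5, 2.5, 4.0),
                                   rho = 0.9, energy_a = 1, energy_s = 0.5,
                                   msa_depth = 500L, plant_fraction = 0.5,
                                   cons_level = 0.7, mut_rate = 0.05,
                                   seed = 1L) {
  stopifnot(L >= 10L, all(sigma_ladder > 0), msa_depth >= 1L)
  structure(list(L = as.integer(L), topology = topology,
                 n_decoys = as.integer(n_decoys),
                 sigma_ladder = sigma_ladder, rho = rho,
                 energy_a = energy_a, energy_s = energy_s,
                 msa_depth = as.integer(msa_depth),
                 plant_fraction = plant_fraction, cons_level = cons_level,
                 mut_rate = mut_rate, seed = as.integer(seed)),
            class = "synthetic_protein_spec")
}

# seeded mixed alpha/beta segment recipe filling exactly L residues
.random_recipe <- function(L) {
  segs <- list()
  remaining <- L
  types <- c("H", "E")
  k <- 0L
  while (remaining > 0L) {
    k <- k + 1L
    type <- sample(types, 1L)
    len <- if (type == "H") sample(8:13, 1L) else sample(5:8, 1L)
    coil <- sample(3:5, 1L)
    if (remaining < len + coil + 5L) {
      segs[[k]] <- data.frame(type = "C", len = remaining)
      remaining <- 0L
    } else {
      segs[[k]] <- data.frame(type = c(type, "C"), len = c(len, coil))
      remaining <- remaining - len - coil
    }
  }
  do.call(rbind, segs)
}

# per-residue (phi, psi) targets; coil entries NA (chosen during compaction)
.recipe_dihedrals <- function(recipe) {
  type <- rep(recipe$type, recipe$len)
  phi <- ifelse(type == "H", -57, ifelse(type == "E", -120, NA_real_))
  psi <- ifelse(type == "H", -47, ifelse(type == "E", 130, NA_real_))
  list(type = type, phi = phi, psi = psi)
}

# candidate (phi, psi) pairs for coil residues: turn- and extended-like
.COIL_CANDIDATES <- matrix(c(-60, -30,
                             -90, 0,
                             -70, 140,
                             -135, 160,
                             60, 40,
                             80, -100), ncol = 2L, byrow = TRUE)

# hydrophobic-patterned sequence matching the segment recipe
.design_sequence <- function(recipe) {
  pools <- list(hydrophobic = c("A", "V", "L", "I", "M", "F"),
                polar = c("S", "T", "N", "Q", "D", "E", "K", "R"))
  out <- character(0)
  for (r in seq_len(nrow(recipe))) {
    type <- recipe$type[r]
    len <- recipe$len[r]
    aa <- character(len)
    for (p in seq_len(len)) {
      hydro <- switch(type,
                      H = (p %% 7L) %in% c(0L, 3L, 4L),
                      E = (p %% 2L) == 0L,
                      sample(c(TRUE, FALSE), 1L, prob = c(0.2, 0.8)))
      pool <- if (hydro) pools$hydrophobic else pools$polar
      aa[p] <- sample(pool, 1L)
      if (type == "C" && stats::runif(1) < 0.2)
        aa[p] <- sample(c("G", "P"), 1L)
    }
    out <- c(out, aa)
  }
  out
}

# build a full backbone with NeRF; coil dihedrals are chosen greedily from a
# candidate library to minimise the radius of gyration while avoiding
# C-alpha clashes (the compaction heuristic)
.build_backbone <- function(dihedrals) {
  L <- length(dihedrals$phi)
  bN <- 1.458; bCA <- 1.525; bC <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  N <- CA <- CC <- O <- matrix(NA_real_, L, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(bN, 0, 0)
  phi <- dihedrals$phi
  psi <- dihedrals$psi

  place_c <- function(i, phi_i) {
    if (i == 1L) {
      ang <- aNCAC * pi / 180
      CA[1L, ] + bCA * c(-cos(ang), sin(ang), 0)
    } else {
      .nerf_place(CC[i - 1L, ], N[i, ], CA[i, ], bCA, aNCAC, phi_i)
    }
  }
  # projected next C-alpha for a (phi, psi) choice at residue i
  project_next_ca <- function(i, phi_i, psi_i) {
    c_i <- place_c(i, phi_i)
    n2 <- .nerf_place(N[i, ], CA[i, ], c_i, bC, aCACN, psi_i)
    list(c_i = c_i,
         n2 = n2,
         ca2 = .nerf_place(CA[i, ], c_i, n2, bN, aCNCA, 180))
  }

  for (i in seq_len(L)) {
    if (is.na(phi[i])) {
      # compaction heuristic: pick the coil torsions whose projected next
      # C-alpha hugs the current centroid without clashing
      jit <- stats::runif(2L, -8, 8)
      best <- .COIL_CANDIDATES[1L, ]
      best_score <- Inf
      prev <- CA[seq_len(i), , drop = FALSE]
      centroid <- colMeans(prev)
      for (k in seq_len(nrow(.COIL_CANDIDATES))) {
        cand <- .COIL_CANDIDATES[k, ] + jit
        if (i == L) { best <- cand; break }
        proj <- project_next_ca(i, cand[1L], cand[2L])
        score <- sqrt(sum((proj$ca2 - centroid)^2))
        if (i > 2L) {
          dmin <- min(.cross_dist(matrix(proj$ca2, 1L),
                                  prev[seq_len(i - 2L), , drop = FALSE]))
          if (dmin < 4.0) score <- score + 1000 * (4.0 - dmin)
        }
        if (score < best_score) { best_score <- score; best <- cand }
      }
      phi[i] <- best[1L]
      psi[i] <- best[2L]
    }
    CC[i, ] <- place_c(i, phi[i])
    psi_i <- if (is.na(psi[i])) 180 else psi[i]
    # carbonyl oxygen: anti-periplanar to the next amide nitrogen
    O[i, ] <- .nerf_place(N[i, ], CA[i, ], CC[i, ], 1.231, 120.8,
                          psi_i + 180)
    if (i < L) {
      N[i + 1L, ] <- .nerf_place(N[i, ], CA[i, ], CC[i, ], bC, aCACN, psi_i)
      CA[i + 1L, ] <- .nerf_place(CA[i, ], CC[i, ], N[i + 1L, ], bN, aCNCA,
                                  180)
    }
  }
  list(N = N, CA = CA, C = CC, O = O, phi = phi, psi = psi)
}

# assemble a protein_structure from backbone matrices and a sequence
.structure_from_backbone <- function(id, seq, bb, cfg = dm_config()) {
  L <- length(seq)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    atoms <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (seq[i] != "G") {
      atoms <- c(atoms, "CB")
      xyz <- rbind(xyz, .ideal_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ]))
    }
    rows[[i]] <- data.frame(res = i, atom = atoms,
                            elem = substr(atoms, 1L, 1L),
                            x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                            stringsAsFactors = FALSE)
  }
  .new_protein_structure(id, "A", seq, do.call(rbind, rows), cfg)
}

#' Generate a synthetic native structure
#'
#' Builds a full backbone (N, CA, C, O, CB) from ideal secondary-structure
#' dihedrals with the natural-extension (NeRF) chain rule; coil dihedrals
#' are selected by a seeded compaction heuristic that folds the chain back
#' on itself, producing a compact globule with helix rise 1.5 A/residue,
#' strand rise ~3.3 A/residue and consecutive C-alpha distances of 3.8 A.
#'
#' @param spec a [synthetic_protein_spec()].
#' @param id structure identifier.
#' @return List with `structure` (a `protein_structure`), `cm` (native
#'   `contact_map` at the 8 A contact rule), `sequence` (character vector)
#'   and `recipe`.
#' @export
make_native <- function(spec, id = "native") {
  set.seed(spec$seed)
  recipe <- spec$topology %||% .random_recipe(spec$L)
  if (sum(recipe$len) != spec$L)
    stop("topology recipe lengths must sum to L")
  seq <- .design_sequence(recipe)
  dih <- .recipe_dihedrals(recipe)
  bb <- .build_backbone(dih)
  s <- .structure_from_backbone(id, seq, bb)
  list(structure = s, cm = compute_contact_map(s), sequence = seq,
       recipe = recipe)
}

# Ornstein-Uhlenbeck displacement field along the chain, one 3D shift per
# residue with stationary per-coordinate sd sigma
.ou_field <- function(L, sigma, rho) {
  e <- matrix(0, L, 3L)
  e[1L, ] <- stats::rnorm(3L, 0, sigma)
  if (L > 1L) {
    step <- sqrt(1 - rho^2)
    for (k in 2L:L) e[k, ] <- rho * e[k - 1L, ] + step * stats::rnorm(3L, 0, sigma)
  }
  e
}

# shift all atoms of each residue rigidly by a per-residue displacement
.shift_structure <- function(s, delta, id) {
  atoms <- s$atoms
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
    delta[atoms$res, , drop = FALSE]
  .new_protein_structure(id, s$chain, s$seq, atoms)
}

#' Generate a decoy ensemble for a synthetic native
#'
#' Each decoy is the native with a chain-correlated Gaussian displacement
#' field applied per residue; the perturbation scale cycles through the
#' three tiers of `spec$sigma_ladder` (very close, relatively close, far
#' from the native). Decoy energies follow
#' energy = `energy_a` * CA-RMSD + N(0, `energy_s`), so that low energy
#' correlates with nativeness, mirroring the premise that native contacts
#' are energetically favourable.
#'
#' @param native output of [make_native()].
#' @param spec a [synthetic_protein_spec()].
#' @return A `decoy_ensemble` with extra element `meta` (data frame
#'   id/sigma/rmsd).
#' @export
make_decoys <- function(native, spec) {
  set.seed(spec$seed + 1L)
  s0 <- native$structure
  ca0 <- s0$bb$CA
  n <- spec$n_decoys
  decoys <- vector("list", n)
  sigma <- spec$sigma_ladder[((seq_len(n) - 1L) %% length(spec$sigma_ladder)) + 1L]
  rmsd <- numeric(n)
  ids <- sprintf("decoy_%04d", seq_len(n))
  for (k in seq_len(n)) {
    delta <- .ou_field(s0$L, sigma[k], spec$rho)
    decoys[[k]] <- .shift_structure(s0, delta, ids[k])
    rmsd[k] <- sqrt(mean(rowSums((decoys[[k]]$bb$CA - ca0)^2)))
  }
  energies <- stats::setNames(spec$energy_a * rmsd +
                                stats::rnorm(n, 0, spec$energy_s), ids)
  ens <- decoy_ensemble(decoys, energies)
  ens$meta <- data.frame(id = ids, sigma = sigma, rmsd = rmsd)
  ens
}

#' Generate an alignment with planted co-evolution
#'
#' Rows are sampled from per-column profiles centred on the query sequence;
#' for a seeded subset of the native medium/long-range contacts the two
#' columns mutate jointly between two coupled states, so their mutual
#' information rises far above the background. The returned coupling scores
#' are the APC-corrected mutual information of the generated alignment,
#' standing in for an external co-evolution method's output.
#'
#' @param sequence query sequence (character vector).
#' @param native_cm the native `contact_map`.
#' @param spec a [synthetic_protein_spec()].
#' @param cfg configuration list.
#' @return List with `msa` (an `msa`), `scores` (an `evolutionary_scores`
#'   table over all pairs) and `planted` (two-column matrix of planted
#'   pairs).
#' @export
make_msa <- function(sequence, native_cm, spec, cfg = dm_config()) {
  set.seed(spec$seed + 2L)
  L <- length(sequence)
  depth <- spec$msa_depth
  mat <- matrix("", depth, L)
  mat[1L, ] <- sequence

  cand <- native_cm$pairs
  cand <- cand[cand[, 2L] - cand[, 1L] >= cfg$candidate_min_separation, ,
               drop = FALSE]
  planted <- matrix(integer(0), 0L, 2L)
  if (nrow(cand) && spec$plant_fraction > 0 && depth > 1L) {
    want <- round(spec$plant_fraction * nrow(cand))
    ord <- sample(nrow(cand))
    used <- logical(L)
    keep <- integer(0)
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used[i] && !used[j]) {
        keep <- c(keep, k)
        used[c(i, j)] <- TRUE
        if (length(keep) >= want) break
      }
    }
    planted <- cand[keep, , drop = FALSE]
  }

  alt <- vapply(seq_len(L), function(c) {
    sample(setdiff(AA_ALPHABET, sequence[c]), 2L)
  }, character(2L))
  if (depth > 1L) {
    for (c in seq_len(L)) {
      r <- stats::runif(depth - 1L)
      col <- ifelse(r < spec$cons_level, sequence[c],
                    ifelse(r < spec$cons_level + (1 - spec$cons_level) / 2,
                           alt[1L, c], alt[2L, c]))
      mat[2:depth, c] <- col
    }
    if (nrow(planted)) {
      for (k in seq_len(nrow(planted))) {
        i <- planted[k, 1L]; j <- planted[k, 2L]
        z <- stats::runif(depth - 1L) < 0.5
        mat[2:depth, i] <- ifelse(z, sequence[i], alt[1L, i])
        mat[2:depth, j] <- ifelse(z, sequence[j], alt[1L, j])
        flip <- stats::runif(depth - 1L) < spec$mut_rate
        if (any(flip))
          mat[1L + which(flip), i] <- sample(AA_ALPHABET, sum(flip),
                                             replace = TRUE)
      }
    }
  }
  msa <- .new_msa(c("query", sprintf("hom%04d", seq_len(depth - 1L))), mat)

  mim <- mutual_information_matrix(msa, cfg$mi_pseudocount)
  ij <- which(upper.tri(mim$apc), arr.ind = TRUE)
  df <- data.frame(i = ij[, 1L], j = ij[, 2L], score = mim$apc[ij])
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  scores <- structure(df, class = c("evolutionary_scores", "data.frame"),
                      provenance = "synthetic apc-mi")
  list(msa = msa, scores = scores, planted = planted)
}

#' Generate a full synthetic corpus
#'
#' Independent synthetic proteins (native, decoy ensemble with energies,
#' alignment, coupling scores), split into training and test halves.
#'
#' @param n_proteins number of proteins (>= 6).
#' @param spec template [synthetic_protein_spec()]; each protein gets its
#'   own seed and seeded topology recipe.
#' @param seed corpus-level seed.
#' @param cfg configuration list.
#' @return A `synthetic_corpus`: list with `proteins` (named list of
#'   contexts: id, spec, native, native_cm, sequence, ensemble, msa, evo,
#'   depth, L), `train_ids`, `test_ids` and `seed`.
#' @export
make_corpus <- function(n_proteins, spec = synthetic_protein_spec(),
                        seed = 1L, cfg = dm_config()) {
  stopifnot(n_proteins >= 6L)
  set.seed(seed)
  pseeds <- sample.int(10^7, n_proteins)
  ids <- sprintf("prot%02d", seq_len(n_proteins))
  proteins <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    sp <- spec
    sp$seed <- pseeds[p]
    sp$topology <- NULL
    nat <- make_native(sp, id = paste0(ids[p], "_native"))
    ens <- make_decoys(nat, sp)
    al <- make_msa(nat$sequence, nat$cm, sp, cfg)
    proteins[[p]] <- list(id = ids[p], spec = sp, native = nat$structure,
                          native_cm = nat$cm, sequence = nat$sequence,
                          ensemble = ens, msa = al$msa, evo = al$scores,
                          planted = al$planted, depth = al$msa$depth,
                          L = sp$L)
  }
  names(proteins) <- ids
  train <- sort(sample(ids, ceiling(n_proteins / 2)))
  structure(list(proteins = proteins, train_ids = train,
                 test_ids = setdiff(ids, train), seed = seed),
            class = "synthetic_corpus")
}

#' Write a synthetic protein system to disk
#'
#' Writes the native and decoy PDB files, the energy table, the alignment
#' (FASTA) and the coupling-score file of one corpus protein, in the plain
#' formats the readers of this package consume.
#'
#' @param ctx one element of `make_corpus()$proteins`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_protein_system <- function(ctx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_pdb(ctx$native, file.path(dir, "native.pdb"))
  ddir <- file.path(dir, "decoys")
  dir.create(ddir, showWarnings = FALSE)
  for (d in ctx$ensemble$decoys)
    .write_pdb(d, file.path(ddir, paste0(d$id, ".pdb")))
  utils::write.table(
    data.frame(decoy_id = names(ctx$ensemble$energies),
               energy = unname(ctx$ensemble$energies)),
    file.path(dir, "energies.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  rows <- apply(ctx$msa$mat, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", ctx$msa$ids), rows)),
             file.path(dir, "alignment.fasta"))
  utils::write.table(as.data.frame(ctx$evo), file.path(dir, "evo_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

# minimal fixed-width PDB ATOM writer via bio3d
.write_pdb <- function(s, path) {
  aa123 <- stats::setNames(
    c("ALA","CYS","ASP","GLU","PHE","GLY","HIS","ILE","LYS","LEU","MET",
      "ASN","PRO","GLN","ARG","SER","THR","VAL","TRP","TYR"),
    AA_ALPHABET)
  resid <- aa123[s$seq[s$atoms$res]]
  resid[is.na(resid)] <- "UNK"
  n <- nrow(s$atoms)
  xyz <- as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = s$atoms$res, resid = resid,
                   eleno = seq_len(n), elety = s$atoms$atom,
                   chain = rep(s$chain %||% "A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
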