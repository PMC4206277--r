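# Reading/writing external formats and the basic contact relation.

.new_protein_structure <- function(id, chain, seq, atoms, cfg = dm_config()) {
  L <- length(seq)
  stopifnot(L >= 1L)
  bb <- list()
  for (nm in c("N", "CA", "C", "O", "CB")) {
    m <- matrix(NA_real_, L, 3L)
    rows <- atoms[atoms$atom == nm, , drop = FALSE]
    if (nrow(rows)) m[rows$res, ] <- as.matrix(rows[, c("x", "y", "z")])
    bb[[nm]] <- m
  }
  ca <- bb$CA
  gaps <- integer(0)
  if (L > 1L) {
    d <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-L, , drop = FALSE])^2))
    gaps <- which(!is.na(d) & d > cfg$chain_break_gap)
  }
  structure(list(id = id, chain = chain, L = L, seq = seq,
                 atoms = atoms, bb = bb, chain_breaks = gaps),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure %s> chain %s, %d residues, %d atoms\n",
              x$id, x$chain %||% "-", x$L, nrow(x$atoms)))
  if (length(x$chain_breaks))
    cat("  chain breaks after residues:",
        paste(x$chain_breaks, collapse = ", "), "\n")
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of one chain into a light-weight per-residue
#' structure. Alternate locations are resolved to the highest occupancy
#' (ties broken by altLoc letter), HETATM records are ignored except
#' selenomethionine (MSE, read as MET), and residues without a C-alpha atom
#' are skipped with a warning. Residues are renumbered contiguously from 1
#' in file order (insertion codes are flattened into serial order). Chain
#' breaks, defined as consecutive C-alpha atoms more than 4.2 A apart, are
#' recorded in `$chain_breaks`.
#'
#' @param path PDB file.
#' @param chain chain identifier; default: first chain in the file.
#' @param id structure identifier; default: file name without extension.
#' @param cfg configuration list, see [dm_config()].
#' @return A `protein_structure`: list with `id`, `chain`, `L`, `seq`
#'   (one-letter residues), `atoms` (data frame res/atom/elem/x/y/z),
#'   `bb` (N, CA, C, O, CB coordinate matrices) and `chain_breaks`.
#' @export
read_structure <- function(path, chain = NULL, id = NULL, cfg = dm_config()) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, ATOM.only = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  at$resid[at$resid == "MSE"] <- "MET"
  at$chain[is.na(at$chain)] <- " "
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains) stop("chain '", chain, "' not present in ", path)
  at <- at[at$chain == chain, , drop = FALSE]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(at$resno, ins, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  # highest occupancy wins within (residue, atom name); ties by altLoc letter
  ord <- order(match(rkey, unique(rkey)), at$elety, -occ, alt)
  at <- at[ord, , drop = FALSE]
  rkey <- rkey[ord]
  dup <- duplicated(paste(rkey, at$elety, sep = "|"))
  at <- at[!dup, , drop = FALSE]
  rkey <- rkey[!dup]

  res_ids <- unique(rkey)
  seq <- character(0)
  rows <- list()
  skipped <- 0L
  idx <- 0L
  for (rk in res_ids) {
    sub <- at[rkey == rk, , drop = FALSE]
    if (!"CA" %in% sub$elety) {
      skipped <- skipped + 1L
      next
    }
    idx <- idx + 1L
    aa <- suppressWarnings(bio3d::aa321(sub$resid[1L]))
    if (is.na(aa) || !aa %in% AA_ALPHABET) aa <- "X"
    seq[idx] <- aa
    rows[[idx]] <- data.frame(
      res = idx, atom = sub$elety,
      elem = substr(gsub("[^A-Za-z]", "", sub$elety), 1L, 1L),
      x = sub$x, y = sub$y, z = sub$z, stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " residue(s) without CA skipped in ", basename(path))
  if (idx == 0L) stop("no parseable residues in ", path)
  atoms <- do.call(rbind, rows)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  .new_protein_structure(id, chain, seq, atoms, cfg)
}

#' Extract one residue record
#'
#' @param s a `protein_structure`.
#' @param i residue index (1-based).
#' @return List with `aa`, `seq_index` and an `atoms` matrix (rows named by
#'   atom name).
#' @export
residue <- function(s, i) {
  stopifnot(inherits(s, "protein_structure"), i >= 1L, i <= s$L)
  sub <- s$atoms[s$atoms$res == i, , drop = FALSE]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$atom
  list(aa = s$seq[i], seq_index = i, atoms = m)
}

#' Contact atom of a residue
#'
#' The contact relation is defined on C-beta atoms, with C-alpha standing in
#' for glycine. A missing C-beta on a non-glycine residue also falls back to
#' C-alpha, with a warning.
#'
#' @param res a residue record from [residue()].
#' @return xyz coordinate (numeric length 3).
#' @export
contact_atom <- function(res) {
  atoms <- res$atoms
  if (!"CA" %in% rownames(atoms)) stop("residue ", res$seq_index, " has no CA")
  if (res$aa != "G" && "CB" %in% rownames(atoms))
    return(unname(atoms["CB", ]))
  if (res$aa != "G")
    warning("residue ", res$seq_index, " (", res$aa,
            ") has no CB; using CA")
  unname(atoms["CA", ])
}

#' Contact-atom coordinates of all residues
#'
#' @param s a `protein_structure`.
#' @return L x 3 matrix of C-beta (C-alpha for glycine or when C-beta is
#'   absent) coordinates.
#' @export
contact_atoms <- function(s) {
  cb <- s$bb$CB
  ca <- s$bb$CA
  use_ca <- s$seq == "G" | is.na(cb[, 1L])
  out <- cb
  out[use_ca, ] <- ca[use_ca, ]
  if (anyNA(out[, 1L])) stop("structure ", s$id, " has residues without CA")
  out
}

#' Compute the contact map of a structure
#'
#' Two residues are in contact when their contact atoms (C-beta, C-alpha for
#' glycine) are within `threshold` Angstrom and they are at least
#' `min_separation` positions apart in sequence.
#'
#' @param s a `protein_structure`.
#' @param threshold distance cutoff in Angstrom (default 8).
#' @param min_separation minimum sequence separation j - i (default 1).
#' @return A `contact_map`: list with `L`, `pairs` (two-column integer
#'   matrix, i < j, ordered), `threshold` and `min_separation`.
#' @export
compute_contact_map <- function(s, threshold = 8, min_separation = 1L) {
  stopifnot(s$L >= 2L)
  xyz <- contact_atoms(s)
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d <= threshold &
                 (col(d) - row(d)) >= min_separation, arr.ind = TRUE)
  pairs <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
  dimnames(pairs) <- NULL
  structure(list(L = s$L, pairs = pairs, threshold = threshold,
                 min_separation = as.integer(min_separation)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> L=%d, %d pairs (<= %g A, sep >= %d)\n",
              x$L, nrow(x$pairs), x$threshold, x$min_separation))
  invisible(x)
}

# canonical "i_j" keys for pair sets
pair_keys <- function(i, j = NULL) {
  if (is.null(j)) { j <- i[, 2L]; i <- i[, 1L] }
  paste(i, j, sep = "_")
}

cm_keys <- function(cm) pair_keys(cm$pairs)

# adjacency list of a contact map
cm_adjacency <- function(cm) {
  adj <- rep(list(integer(0)), cm$L)
  p <- cm$pairs
  if (nrow(p)) {
    for (k in seq_len(nrow(p))) {
      adj[[p[k, 1L]]] <- c(adj[[p[k, 1L]]], p[k, 2L])
      adj[[p[k, 2L]]] <- c(adj[[p[k, 2L]]], p[k, 1L])
    }
  }
  adj
}

#' Read a multiple-sequence alignment (FASTA or A3M)
#'
#' Lowercase characters and '.' columns (A3M insertion states) are removed;
#' all remaining rows must match the query length. The first sequence is the
#' query.
#'
#' @param path FASTA/A3M file.
#' @return An `msa`: list with `ids`, `mat` (depth x L character matrix),
#'   `depth` and `L`.
#' @export
read_msa <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("unreadable alignment '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) < 1L) stop("alignment ", path, " contains no sequences")
  seqs <- gsub("[a-z.]", "", as.character(set))
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L)
    stop("ragged alignment after removing insertion columns in ", path)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  .new_msa(names(set) %||% paste0("seq", seq_along(seqs)), mat)
}

.new_msa <- function(ids, mat) {
  structure(list(ids = ids, mat = mat, depth = nrow(mat), L = ncol(mat)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> depth %d, %d columns (query: %s)\n",
              x$depth, x$L, x$ids[1L]))
  invisible(x)
}

#' Read evolutionary coupling scores
#'
#' Tab- or space-separated rows `i j score` with 1-based residue indices,
#' e.g. coupling scores from a pseudo-likelihood co-evolution method.
#' Pairs are normalised to i < j; duplicated pairs keep the last value with
#' a warning. Pairs absent from the file score 0 when queried.
#'
#' @param path score file.
#' @param L protein length for index validation (optional).
#' @return An `evolutionary_scores` data frame with columns `i`, `j`,
#'   `score` and attribute `provenance`.
#' @export
read_evolutionary_scores <- function(path, L = NULL) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("i", "j", "score"))
  if (!nrow(df)) stop("empty score file: ", path)
  swap <- df$i > df$j
  tmp <- df$i[swap]; df$i[swap] <- df$j[swap]; df$j[swap] <- tmp
  self <- df$i == df$j
  if (any(self)) {
    warning(sum(self), " self-pairs dropped from ", basename(path))
    df <- df[!self, , drop = FALSE]
  }
  if (!is.null(L) && nrow(df) && (min(df$i) < 1L || max(df$j) > L))
    stop("pair indices outside [1, ", L, "] in ", path)
  key <- pair_keys(df$i, df$j)
  if (anyDuplicated(key)) {
    warning("duplicate pairs in ", basename(path), "; last value wins")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("evolutionary_scores", "data.frame"),
            provenance = path)
}

#' Look up an evolutionary score
#'
#' @param es an `evolutionary_scores` table.
#' @param i,j residue indices (any order).
#' @return The stored score, or 0 for absent pairs.
#' @export
evo_score <- function(es, i, j) {
  ii <- pmin(i, j); jj <- pmax(i, j)
  m <- match(pair_keys(ii, jj), pair_keys(es$i, es$j))
  out <- es$score[m]
  out[is.na(out)] <- 0
  out
}

#' Read a decoy energy table
#'
#' Two-column table `decoy_id energy` (tab- or space-separated, optional
#' header). Duplicate decoy identifiers are fatal.
#'
#' @param path energy file.
#' @return Named numeric vector of energies.
#' @export
read_energy_table <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1L]]
  has_header <- length(toks) >= 2L && is.na(suppressWarnings(as.numeric(toks[2L])))
  df <- utils::read.table(path, header = has_header)
  if (ncol(df) < 2L) stop("energy table must have two columns: ", path)
  names(df)[1:2] <- c("decoy_id", "energy")
  if (anyDuplicated(df$decoy_id))
    stop("duplicate decoy ids in energy table: ", path)
  stats::setNames(as.numeric(df$energy), as.character(df$decoy_id))
}

#' Bundle decoys with their energies
#'
#' @param decoys list of `protein_structure` decoys.
#' @param energies named numeric vector; every decoy id must be present.
#' @return A `decoy_ensemble`: list with `decoys` (named list), `energies`
#'   and `selected` (character vector of currently selected decoy ids,
#'   empty until [select_low_energy()] is applied).
#' @export
decoy_ensemble <- function(decoys, energies) {
  if (!length(decoys)) stop("empty decoy ensemble")
  ids <- vapply(decoys, function(d) d$id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate decoy ids")
  missing <- setdiff(ids, names(energies))
  if (length(missing))
    stop("decoys without energy: ", paste(missing, collapse = ", "))
  names(decoys) <- ids
  structure(list(decoys = decoys, energies = energies[ids],
                 selected = character(0)),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat(sprintf("<decoy_ensemble> %d decoys, %d selected\n",
              length(x$decoys), length(x$selected)))
  invisible(x)
}

#' Select the low-energy fraction of a decoy ensemble
#'
#' Keeps the `ceiling(fraction * N)` decoys with lowest energy; ties are
#' broken by decoy id (lexicographic), which makes the selection
#' deterministic and nested across fractions.
#'
#' @param ens a `decoy_ensemble`.
#' @param fraction fraction in (0, 1]; e.g. 0.02 for prediction decoys,
#'   0.03 for training decoys.
#' @return The ensemble with `selected` filled in.
#' @export
select_low_energy <- function(ens, fraction) {
  stopifnot(inherits(ens, "decoy_ensemble"))
  if (!length(ens$decoys)) stop("empty decoy ensemble")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n <- length(ens$decoys)
  k <- ceiling(fraction * n)
  ord <- order(ens$energies, names(ens$energies))
  ens$selected <- names(ens$energies)[ord][seq_len(k)]
  ens
}

#' @rdname select_low_energy
#' @export
selected_decoys <- function(ens) {
  if (!length(ens$selected)) stop("no decoys selected; run select_low_energy()")
  ens$decoys[ens$selected]
}

#' Write ranked contacts in the CASP RR dialect
#'
#' Emits a `PFRMAT RR` header, the sequence in 50-residue lines, then one
#' `i j 0 <threshold> score` row per contact in descending score order, and
#' a terminating `END`.
#'
#' @param scores data frame with columns `i`, `j` and a score column (the
#'   first of `combined`, `score`, `s_svm` found).
#' @param path output file.
#' @param sequence optional query sequence (single string).
#' @param threshold upper distance bound written per row (default 8).
#' @return Invisibly, the path.
#' @export
write_rr <- function(scores, path, sequence = NULL, threshold = 8) {
  sc_col <- intersect(c("combined", "score", "s_svm"), names(scores))[1L]
  if (is.na(sc_col)) stop("no score column found")
  sc <- scores[[sc_col]]
  ord <- order(-sc, scores$i, scores$j)
  lines <- "PFRMAT RR"
  if (!is.null(sequence)) {
    seq1 <- paste(sequence, collapse = "")
    starts <- seq(1L, nchar(seq1), by = 50L)
    lines <- c(lines, substring(seq1, starts, pmin(starts + 49L, nchar(seq1))))
  }
  lines <- c(lines,
             sprintf("%d %d 0 %g %.6f", scores$i[ord], scores$j[ord],
                     threshold, sc[ord]),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP RR contact file
#'
#' @param path RR file written by [write_rr()] or a compatible tool.
#' @return List with `sequence` (possibly `NULL`) and `scores` (data frame
#'   `i`, `j`, `d1`, `d2`, `score`).
#' @export
read_rr <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)",
                        lines)]
  is_row <- grepl("^\\d+\\s+\\d+\\s", lines)
  seq <- if (any(!is_row)) paste(lines[!is_row], collapse = "") else NULL
  rows <- lines[is_row]
  if (!length(rows)) return(list(sequence = seq, scores = NULL))
  df <- utils::read.table(text = rows,
                          col.names = c("i", "j", "d1", "d2", "score"))
  list(sequence = seq, scores = df)
}
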