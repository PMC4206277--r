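# Evolutionary sequence features: Henikoff-weighted per-column conservation
# and pairwise mutual information with average product correction (APC).

.MSA_SYMBOLS <- c(AA_ALPHABET, "-")

# map an msa character matrix to integer symbols 1..21 (21 = gap/other)
.msa_index <- function(mat) {
  idx <- match(toupper(mat), .MSA_SYMBOLS)
  idx[is.na(idx)] <- 21L
  dim(idx) <- dim(mat)
  idx
}

# Henikoff position-based sequence weights, normalised to sum = depth
.henikoff_weights <- function(idx) {
  depth <- nrow(idx)
  if (depth == 1L) return(1)
  w <- numeric(depth)
  for (c in seq_len(ncol(idx))) {
    col <- idx[, c]
    counts <- tabulate(col, nbins = 21L)
    r <- sum(counts > 0L)
    w <- w + 1 / (r * counts[col])
  }
  w * depth / sum(w)
}

#' Per-column conservation profile
#'
#' Conservation of column c is 1 - H_c / log(20), where H_c is the Shannon
#' entropy of the Henikoff-weighted residue frequencies (gaps excluded, a
#' pseudocount added to each observed residue's weighted count). A
#' perfectly conserved column and every column of a single-sequence
#' alignment score exactly 1; a uniformly variable column tends to 0 with
#' depth. The neighbourhood conservation is the mean over a +-2 column
#' window, clipped at the alignment ends.
#'
#' @param m an `msa`.
#' @param pseudocount count added to each observed residue (default 1).
#' @param window half-width of the neighbourhood window (default 2).
#' @return List with numeric vectors `conservation`,
#'   `neigh_conservation` (both length L, in `[0, 1]`) and the sequence
#'   `weights`.
#' @export
conservation_profile <- function(m, pseudocount = 1, window = 2L) {
  idx <- .msa_index(m$mat)
  w <- .henikoff_weights(idx)
  L <- ncol(idx)
  cons <- numeric(L)
  for (c in seq_len(L)) {
    col <- idx[, c]
    keep <- col <= 20L
    if (!any(keep)) { cons[c] <- 0; next }
    wc <- as.numeric(rowsum(w[keep], col[keep]))
    wc <- wc + pseudocount
    p <- wc / sum(wc)
    h <- -sum(p * log(p))
    cons[c] <- max(0, min(1, 1 - h / log(20)))
  }
  neigh <- vapply(seq_len(L), function(c) {
    mean(cons[max(1L, c - window):min(L, c + window)])
  }, numeric(1L))
  list(conservation = cons, neigh_conservation = neigh, weights = w)
}

#' Mutual information between alignment columns
#'
#' MI over 21 symbols (20 residues + gap) with a pseudocount per joint cell,
#' plus the average-product-corrected matrix
#' APC(a,b) = MI(a,b) - mean_a(MI) * mean_b(MI) / mean(MI), which removes
#' background covariation due to phylogeny and column entropy. Natural
#' logarithms; two perfectly coupled binary columns approach MI = log 2.
#'
#' @param m an `msa`.
#' @param pseudocount pseudocount per joint frequency cell (default 0.05).
#' @return List of two symmetric L x L matrices, `mi` and `apc` (zero
#'   diagonal; all zeros when depth < 2).
#' @export
mutual_information_matrix <- function(m, pseudocount = 0.05) {
  L <- m$L
  mi <- matrix(0, L, L)
  if (m$depth >= 2L) {
    idx <- .msa_index(m$mat)
    for (a in seq_len(L - 1L)) {
      ia <- idx[, a]
      for (b in (a + 1L):L) {
        joint <- tabulate(ia + 21L * (idx[, b] - 1L), nbins = 441L) +
          pseudocount
        p <- joint / sum(joint)
        dim(p) <- c(21L, 21L)
        pa <- rowSums(p)
        pb <- colSums(p)
        v <- sum(p * log(p / outer(pa, pb)))
        mi[a, b] <- mi[b, a] <- max(v, 0)
      }
    }
  }
  apc <- matrix(0, L, L)
  if (L > 1L && any(mi > 0)) {
    rowmean <- rowSums(mi) / (L - 1L)
    overall <- sum(mi) / (L * (L - 1L))
    if (overall > 0) apc <- mi - outer(rowmean, rowmean) / overall
    diag(apc) <- 0
  }
  list(mi = mi, apc = apc)
}
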