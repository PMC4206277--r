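# residue-level lookup tables; the TSV files live in inst/extdata so they can
# be inspected and swapped, and are parsed once per session

.dm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "decoymap")
  if (!nzchar(path)) stop("missing data file: ", file)
  path
}

.dm_table <- function(key, loader) {
  if (is.null(.dm_cache[[key]])) .dm_cache[[key]] <- loader()
  .dm_cache[[key]]
}

#' Residue chemical classes
#'
#' Seven-way classification of the 20 standard amino acids used for the
#' categorical node labels: hydrophobic (A,V,L,I,M,C), aromatic (F,W,Y),
#' polar (S,T,N,Q), positive (K,R,H), negative (D,E), glycine and proline.
#'
#' @return Named character vector mapping one-letter codes to class names.
#' @export
chem_class_table <- function() {
  .dm_table("chem", function() {
    df <- utils::read.delim(.dm_extdata("chem_classes.tsv"),
                            stringsAsFactors = FALSE)
    stats::setNames(df$class, df$aa)
  })
}

#' Theoretical maximum solvent accessibilities
#'
#' Per-residue maximum accessible surface areas (A^2) used to normalise raw
#' SASA into relative solvent accessibility (Tien et al. 2013 theoretical
#' values).
#'
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
max_sasa_table <- function() {
  .dm_table("maxsasa", function() {
    df <- utils::read.delim(.dm_extdata("max_sasa.tsv"),
                            stringsAsFactors = FALSE)
    stats::setNames(df$max_sasa, df$aa)
  })
}

#' Atomic solvation parameters
#'
#' Surface-tension-style coefficients sigma (kcal mol^-1 A^-2) per atom type;
#' the free solvation energy of a residue is the sum over its atoms of
#' sigma * SASA. This is a synthetic stand-in table with
#' Eisenberg--McLachlan-style magnitudes (apolar carbon positive, polar and
#' charged nitrogen/oxygen negative); see the package vignette.
#'
#' @return Named numeric vector keyed by atom type.
#' @export
solvation_sigma_table <- function() {
  .dm_table("sigma", function() {
    df <- utils::read.delim(.dm_extdata("solvation_sigma_synthetic.tsv"),
                            stringsAsFactors = FALSE)
    stats::setNames(df$sigma, df$atom_type)
  })
}

#' Residue-residue contact potential
#'
#' A 20x20 symmetric quasi-chemical-style contact potential (arbitrary energy
#' units, attractive = negative). The shipped table is a synthetic stand-in
#' generated from a documented hydrophobicity/charge formula (see the
#' vignette); any 20x20 table with the same layout can be swapped in.
#'
#' @return Numeric 20x20 matrix with residue one-letter dimnames.
#' @export
contact_potential_table <- function() {
  .dm_table("potential", function() {
    m <- as.matrix(utils::read.delim(.dm_extdata("contact_potential_synthetic.tsv"),
                                     row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    m
  })
}

#' Kyte-Doolittle hydrophobicity scale
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kd_hydrophobicity <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

# class of a residue vector; unknown letters fall back to "polar"
.chem_class_of <- function(aa) {
  tab <- chem_class_table()
  out <- unname(tab[aa])
  out[is.na(out)] <- "polar"
  out
}

.kd_of <- function(aa) {
  kd <- kd_hydrophobicity()
  out <- unname(kd[aa])
  out[is.na(out)] <- 0
  out
}

.max_sasa_of <- function(aa) {
  tab <- max_sasa_table()
  out <- unname(tab[aa])
  out[is.na(out)] <- mean(tab)
  out
}

.potential_of <- function(aa_i, aa_j) {
  pot <- contact_potential_table()
  ii <- match(aa_i, rownames(pot))
  jj <- match(aa_j, colnames(pot))
  out <- rep(0, length(aa_i))
  ok <- !is.na(ii) & !is.na(jj)
  out[ok] <- pot[cbind(ii[ok], jj[ok])]
  out
}
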