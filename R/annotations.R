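# Structure-level annotations: backbone hydrogen bonds, secondary structure
# from dihedrals + H-bond patterns, Shrake-Rupley solvent accessibility and
# atomic-solvation free energies.

#' Detect backbone hydrogen bonds
#'
#' Geometric criterion on backbone amide nitrogen and carbonyl oxygen:
#' residues i (donor N) and j (acceptor O) are hydrogen bonded when
#' N(i)...O(j) <= `cutoff` Angstrom and |i - j| >= `min_sep`.
#'
#' @param s a `protein_structure`.
#' @param cutoff N...O distance cutoff in Angstrom (default 3.5).
#' @param min_sep minimum sequence separation (default 2).
#' @return Data frame with columns `donor`, `acceptor` (residue indices).
#' @export
detect_hbonds <- function(s, cutoff = 3.5, min_sep = 2L) {
  N <- s$bb$N
  O <- s$bb$O
  okN <- which(!is.na(N[, 1L]))
  okO <- which(!is.na(O[, 1L]))
  if (!length(okN) || !length(okO))
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  d <- .cross_dist(N[okN, , drop = FALSE], O[okO, , drop = FALSE])
  sep <- abs(outer(okN, okO, "-"))
  hit <- which(d <= cutoff & sep >= min_sep, arr.ind = TRUE)
  out <- data.frame(donor = okN[hit[, 1L]], acceptor = okO[hit[, 2L]])
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

# per-residue count of hydrogen bonds (either role)
.hbond_counts <- function(hb, L) {
  tabulate(c(hb$donor, hb$acceptor), nbins = L)
}

#' Assign secondary structure from backbone geometry
#'
#' Dihedral-plus-hydrogen-bond heuristic: alpha helix (H) for runs of at
#' least four residues with phi in [-90, -30] and psi in [-77, -17] degrees;
#' extended strand (E) for runs of at least three residues with phi in
#' [-170, -70] and psi in [90, 180] or [-180, -170]; shorter strand-like
#' stretches become isolated bridges (B). Outside those, residues engaged in
#' (i, i+3) backbone hydrogen bonds are 3-10 helix (G), (i, i+5) bonds pi
#' helix (I), residues spanned by an (i, i+3) bond are turns (T), and
#' everything else is coil (C). The 3-state collapse maps H,G,I to H and
#' E,B to E.
#'
#' @param s a `protein_structure`.
#' @param hbonds optional precomputed [detect_hbonds()] table.
#' @param cfg configuration list.
#' @return List with `ss7`, `ss3` (character vectors) and the backbone
#'   dihedrals `phi`, `psi` in degrees (NA at chain termini).
#' @export
assign_secondary_structure <- function(s, hbonds = NULL, cfg = dm_config()) {
  L <- s$L
  ss7 <- rep("C", L)
  if (L < 3L) {
    return(list(ss7 = ss7, ss3 = rep("C", L),
                phi = rep(NA_real_, L), psi = rep(NA_real_, L)))
  }
  N <- s$bb$N; CA <- s$bb$CA; CC <- s$bb$C
  phi <- psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1L && !anyNA(c(CC[i - 1L, ], N[i, ], CA[i, ], CC[i, ])))
      phi[i] <- dihedral_angle(CC[i - 1L, ], N[i, ], CA[i, ], CC[i, ])
    if (i < L && !anyNA(c(N[i, ], CA[i, ], CC[i, ], N[i + 1L, ])))
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], CC[i, ], N[i + 1L, ])
  }
  helix_like <- !is.na(phi) & !is.na(psi) &
    phi >= -90 & phi <= -30 & psi >= -77 & psi <= -17
  strand_like <- !is.na(phi) & !is.na(psi) &
    phi >= -170 & phi <= -70 &
    ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -170))

  mark_runs <- function(mask, min_len, label, only_c = FALSE) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= min_len) {
        idx <- starts[k]:ends[k]
        if (only_c) idx <- idx[ss7[idx] == "C"]
        ss7[idx] <<- label
      }
    }
  }
  mark_runs(helix_like, 4L, "H")
  mark_runs(strand_like & ss7 == "C", 3L, "E")
  mark_runs(strand_like & ss7 == "C", 1L, "B", only_c = TRUE)

  if (is.null(hbonds))
    hbonds <- detect_hbonds(s, cfg$hbond_cutoff, cfg$hbond_min_sep)
  sep <- abs(hbonds$donor - hbonds$acceptor)
  g_res <- unique(c(hbonds$donor[sep == 3L], hbonds$acceptor[sep == 3L]))
  i_res <- unique(c(hbonds$donor[sep == 5L], hbonds$acceptor[sep == 5L]))
  t_res <- unique(unlist(lapply(which(sep == 3L), function(k) {
    lo <- min(hbonds$donor[k], hbonds$acceptor[k])
    (lo + 1L):(lo + 2L)
  })))
  ss7[ss7 == "C" & seq_len(L) %in% t_res] <- "T"
  ss7[ss7 %in% c("C", "T") & seq_len(L) %in% i_res] <- "I"
  ss7[ss7 %in% c("C", "T") & seq_len(L) %in% g_res] <- "G"

  ss3 <- rep("C", L)
  ss3[ss7 %in% c("H", "G", "I")] <- "H"
  ss3[ss7 %in% c("E", "B")] <- "E"
  list(ss7 = ss7, ss3 = ss3, phi = phi, psi = psi)
}

#' Solvent-accessible surface area of a set of atoms
#'
#' Shrake-Rupley numerical integration: each atom's solvent-extended sphere
#' (van der Waals radius + probe) is sampled with a deterministic golden
#' spiral point set, and the accessible area is the fraction of points not
#' buried inside any neighbouring atom's extended sphere.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 92).
#' @return Numeric vector of per-atom areas in Angstrom^2.
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 92L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  pts <- .sphere_points(n_points)
  out <- numeric(n)
  rs <- radii + probe
  for (i in seq_len(n)) {
    ri <- rs[i]
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < ri + rs & seq_len(n) != i)
    area_full <- 4 * pi * ri^2
    if (!length(nb)) { out[i] <- area_full; next }
    p <- pts * ri
    p <- sweep(p, 2L, xyz[i, ], "+")
    d2 <- .cross_dist(p, xyz[nb, , drop = FALSE])
    buried <- rowSums(d2 < rep(rs[nb], each = n_points)) > 0L
    out[i] <- mean(!buried) * area_full
  }
  out
}

.atom_radius <- function(elem) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  out <- unname(r[elem])
  out[is.na(out)] <- 1.70
  out
}

#' Per-residue solvent accessibility
#'
#' Sums [sasa_atoms()] areas per residue and normalises by the residue's
#' theoretical maximum ([max_sasa_table()]) to obtain relative solvent
#' accessibility (RSA), clamped at `cfg$rsa_clamp`.
#'
#' @param s a `protein_structure`.
#' @param probe probe radius (Angstrom).
#' @param n_points sphere sample points per atom.
#' @param cfg configuration list.
#' @return List with `atom_sasa` (per atom, in `s$atoms` order),
#'   `residue_sasa` and `rsa` (length-L vectors).
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 92L, cfg = dm_config()) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  radii <- .atom_radius(s$atoms$elem)
  a <- sasa_atoms(xyz, radii, probe, n_points)
  res_sasa <- as.numeric(rowsum(a, s$atoms$res, reorder = TRUE))
  rsa <- pmin(pmax(res_sasa / .max_sasa_of(s$seq), 0), cfg$rsa_clamp)
  list(atom_sasa = a, residue_sasa = res_sasa, rsa = rsa)
}

#' Atomic-solvation free energy per residue
#'
#' @param s a `protein_structure`.
#' @param atom_sasa per-atom areas from [compute_sasa()].
#' @return Length-L numeric vector (kcal/mol): sum over the residue's atoms
#'   of sigma(atom type) * SASA(atom), with sigma from
#'   [solvation_sigma_table()].
#' @export
solvation_energy <- function(s, atom_sasa) {
  sig_tab <- solvation_sigma_table()
  sig <- unname(sig_tab[s$atoms$elem])
  sig[is.na(sig)] <- 0
  as.numeric(rowsum(sig * atom_sasa, s$atoms$res, reorder = TRUE))
}

#' Annotate a structure for feature generation
#'
#' Convenience wrapper computing secondary structure, hydrogen bonds, SASA,
#' RSA and solvation energies in one pass.
#'
#' @param s a `protein_structure`.
#' @param cfg configuration list.
#' @return List with `ss7`, `ss3`, `phi`, `psi`, `hbonds`, `hbond_count`,
#'   `rsa`, `residue_sasa`, `solvation`.
#' @export
annotate_structure <- function(s, cfg = dm_config()) {
  hb <- detect_hbonds(s, cfg$hbond_cutoff, cfg$hbond_min_sep)
  ss <- assign_secondary_structure(s, hbonds = hb, cfg = cfg)
  sa <- compute_sasa(s, cfg$probe_radius, cfg$sasa_points, cfg)
  list(ss7 = ss$ss7, ss3 = ss$ss3, phi = ss$phi, psi = ss$psi,
       hbonds = hb, hbond_count = .hbond_counts(hb, s$L),
       rsa = sa$rsa, residue_sasa = sa$residue_sasa,
       solvation = solvation_energy(s, sa$atom_sasa))
}
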