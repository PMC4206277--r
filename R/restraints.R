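# Bounded-Lorentz distance restraints: a non-penalising energy bonus for
# satisfied predicted contacts, used to bias folding simulations.

#' Restraint parameters
#'
#' @param lb lower distance bound in Angstrom (default 1.5).
#' @param ub upper distance bound in Angstrom (default 8, the contact
#'   definition).
#' @param hw half width in Angstrom: the violation at which half the bonus
#'   is still rewarded (default 1).
#' @param w magnitude of the full energy bonus (> 0, default 1).
#' @param n_contacts number of top-ranked contacts emitted by
#'   [write_restraint_file()]; default (`NULL`) emits the top L.
#' @return A `restraint_params` list.
#' @export
restraint_params <- function(lb = 1.5, ub = 8, hw = 1, w = 1,
                             n_contacts = NULL) {
  stopifnot(lb < ub, hw > 0, w > 0)
  structure(list(lb = lb, ub = ub, hw = hw, w = w,
                 n_contacts = n_contacts),
            class = "restraint_params")
}

#' Bounded-Lorentz restraint energy
#'
#' The full bonus -w is rewarded while the distance lies within the bounds;
#' outside, the bonus decays as a Lorentzian of the violation,
#' `E(d) = -w / (1 + ((d - ub)/hw)^2)` for d > ub (symmetrically for
#' d < lb), reaching -w/2 at one half-width of violation and approaching 0
#' for large violations. The energy is never positive, so a wrongly
#' predicted contact is ignored rather than penalised.
#'
#' @param d distance(s) in Angstrom (>= 0).
#' @param p a [restraint_params()].
#' @return Energy value(s) in `[-w, 0]`.
#' @export
lorentz_energy <- function(d, p = restraint_params()) {
  stopifnot(all(d >= 0))
  out <- rep(-p$w, length(d))
  hi <- d > p$ub
  lo <- d < p$lb
  out[hi] <- -p$w / (1 + ((d[hi] - p$ub) / p$hw)^2)
  out[lo] <- -p$w / (1 + ((p$lb - d[lo]) / p$hw)^2)
  out
}

#' Write a distance-restraint file
#'
#' Emits the top-ranked contacts as a documented TSV with one restraint per
#' row: `i j atom_i atom_j lb ub hw w`. Restraint atoms are C-beta, or
#' C-alpha for glycine partners. If fewer ranked contacts are available
#' than requested, all are written with a warning.
#'
#' @param ranked ranked contact table (data frame with `i`, `j`, best
#'   first).
#' @param p a [restraint_params()].
#' @param path output file.
#' @param sequence the protein sequence (character vector or single
#'   string), used for the glycine rule and the default contact count.
#' @return Invisibly, the number of restraints written.
#' @export
write_restraint_file <- function(ranked, p, path, sequence) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1L]]
  ranked <- as.data.frame(ranked)
  if (!nrow(ranked)) stop("no ranked contacts to write")
  n <- p$n_contacts %||% length(sequence)
  if (n > nrow(ranked)) {
    warning("requested ", n, " restraints but only ", nrow(ranked),
            " ranked contacts are available")
    n <- nrow(ranked)
  }
  top <- ranked[seq_len(n), , drop = FALSE]
  atom_of <- function(idx) ifelse(sequence[idx] == "G", "CA", "CB")
  df <- data.frame(i = top$i, j = top$j,
                   atom_i = atom_of(top$i), atom_j = atom_of(top$j),
                   lb = p$lb, ub = p$ub, hw = p$hw, w = p$w)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(n)
}

#' Read a distance-restraint file
#'
#' @param path file written by [write_restraint_file()].
#' @return Data frame with columns `i`, `j`, `atom_i`, `atom_j`, `lb`,
#'   `ub`, `hw`, `w`.
#' @export
read_restraint_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
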