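#' Standard 10-20 channel set used throughout the package
#'
#' The 19 monopolar electrode labels of the international 10-20 system, in the
#' canonical order used by every recording container in this package.
#'
#' @return Character vector of length 19.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Schematic 2-D electrode positions
#'
#' Approximate planar coordinates (unit head circle, nose up) for the 19
#' electrodes. Used for inverse-distance channel interpolation and for the
#' spatial loading of the synthetic EOG generator; only relative distances
#' matter.
#'
#' @return A matrix with rows named by electrode and columns `x`, `y`.
#' @keywords internal
electrode_positions <- function() {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.45, 0.52), Fz = c(0, 0.5),
    F4  = c(0.45, 0.52),  F8  = c(0.81, 0.59),
    T3  = c(-1.0, 0),     C3  = c(-0.5, 0),     Cz = c(0, 0),
    C4  = c(0.5, 0),      T4  = c(1.0, 0),
    T5  = c(-0.81, -0.59), P3 = c(-0.45, -0.52), Pz = c(0, -0.5),
    P4  = c(0.45, -0.52),  T6 = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95))
  colnames(pos) <- c("x", "y")
  pos[channels_1020(), , drop = FALSE]
}

#' Longitudinal bipolar montage with anterior/posterior scalp groups
#'
#' Defines the 18 longitudinal bipolar derivations (anode minus cathode) and
#' their partition into four scalp groups: anterior-left (AL), anterior-right
#' (AR), posterior-left (PL) and posterior-right (PR). Each group has exactly
#' five members; the midline derivations Fz-Cz and Cz-Pz are shared between the
#' left and right group of their row, reflecting that midline activity is not
#' lateralized.
#'
#' @return A list with elements:
#'   \item{pairs}{tibble with columns `label`, `anode`, `cathode` (18 rows).}
#'   \item{groups}{named list mapping AL/AR/PL/PR to 5 bipolar labels each.}
#' @export
#' @examples
#' m <- bipolar_montage()
#' m$pairs
#' m$groups$AL
bipolar_montage <- function() {
  anode   <- c("Fp1", "F7", "T3", "T5", "Fp1", "F3", "C3", "P3", "Fz",
               "Cz", "Fp2", "F4", "C4", "P4", "Fp2", "F8", "T4", "T6")
  cathode <- c("F7", "T3", "T5", "O1", "F3", "C3", "P3", "O1", "Cz",
               "Pz", "F4", "C4", "P4", "O2", "F8", "T4", "T6", "O2")
  label <- paste(anode, cathode, sep = "-")
  groups <- list(
    AL = c("Fp1-F7", "F7-T3", "Fp1-F3", "F3-C3", "Fz-Cz"),
    AR = c("Fp2-F8", "F8-T4", "Fp2-F4", "F4-C4", "Fz-Cz"),
    PL = c("T3-T5", "T5-O1", "C3-P3", "P3-O1", "Cz-Pz"),
    PR = c("T4-T6", "T6-O2", "C4-P4", "P4-O2", "Cz-Pz"))
  stopifnot(length(label) == 18L, all(unlist(groups) %in% label))
  list(pairs = tibble::tibble(label = label, anode = anode, cathode = cathode),
       groups = groups)
}

#' Monopolar electrode groups used by the synthetic generator
#'
#' Maps the four scalp groups to the monopolar electrodes underlying them, used
#' to restrict planted directed coupling to within-group electrode pairs.
#' Midline electrodes are left out so a planted unilateral effect stays
#' unilateral.
#'
#' @return Named list of electrode label vectors.
#' @keywords internal
electrode_groups <- function() {
  list(AL = c("Fp1", "F7", "F3", "T3", "C3"),
       AR = c("Fp2", "F8", "F4", "T4", "C4"),
       PL = c("T5", "P3", "O1"),
       PR = c("T6", "P4", "O2"))
}

#' Normalize channel names to the 10-20 labels used here
#'
#' Maps common aliases (modified combinatorial nomenclature and case variants)
#' onto the canonical labels, e.g. `"T7" -> "T3"`, `"FP1" -> "Fp1"`.
#'
#' @param x Character vector of channel names.
#' @return Character vector of canonical labels; unknown names are returned
#'   unchanged.
#' @export
normalize_channel_names <- function(x) {
  aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  canon <- channels_1020()
  out <- vapply(x, function(nm) {
    hit <- canon[toupper(canon) == toupper(nm)]
    if (length(hit) == 1L) return(hit)
    hit <- aliases[toupper(names(aliases)) == toupper(nm)]
    if (length(hit) == 1L) return(unname(hit))
    nm
  }, character(1), USE.NAMES = FALSE)
  out
}
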