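#' Frequency band definitions
#'
#' Canonical EEG band edges. Two contexts exist: for band-power features the
#' delta and global bands start at 1 Hz; for spectral connectivity they start
#' at 2 Hz, because 2.5 s epochs require at least five cycles of the lowest
#' frequency for a usable spectral estimate. Band membership of a frequency bin
#' is half-open, `lo <= f < hi`, so shared edges (4, 8, 13 Hz) are never
#' counted twice.
#'
#' @param context `"bandpower"` or `"connectivity"`.
#' @return A tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
#' @examples
#' band_definitions("bandpower")
#' band_definitions("connectivity")
band_definitions <- function(context = c("bandpower", "connectivity")) {
  context <- match.arg(context)
  lo_delta <- if (context == "connectivity") 2 else 1
  tibble::tibble(
    band  = c("delta", "theta", "alpha", "beta", "global"),
    lo_hz = c(lo_delta, 4, 8, 13, lo_delta),
    hi_hz = c(4, 8, 13, 30, 30))
}

# Logical mask of bins belonging to a band (half-open interval).
band_mask <- function(freqs, lo, hi) freqs >= lo & freqs < hi
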