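#' Molar stoichiometry of RNA bands relative to a reference band
#'
#' Stained-gel band intensity scales with the mass of RNA in the band; the
#' molar amount is the intensity divided by the species' nucleotide length.
#' This reports each band's molar ratio relative to a reference band (e.g.
#' the snRNAs of a purified complex relative to its exon RNA), so a value
#' of 1 means one copy per reference molecule.
#'
#' @param bands tibble with columns `band`, `intensity` (>= 0) and
#'   `length` (nt, >= 1).
#' @param reference name of the reference band.
#' @return tibble with an added `molar_ratio` column; the reference's
#'   ratio is exactly 1.
#' @export
rna_stoichiometry <- function(bands, reference) {
  required <- c("band", "intensity", "length")
  if (!all(required %in% names(bands))) {
    abort("`bands` needs columns band, intensity, length")
  }
  if (any(bands$intensity < 0, na.rm = TRUE)) abort("intensities must be >= 0")
  if (any(bands$length < 1, na.rm = TRUE)) abort("lengths must be >= 1 nt")
  ref <- bands[bands$band == reference, , drop = FALSE]
  if (nrow(ref) != 1L) abort(sprintf("reference band '%s' not found exactly once", reference))
  if (ref$intensity <= 0) abort("reference band has zero intensity")
  ref_molar <- ref$intensity / ref$length
  out <- as_tibble(bands)
  out$molar_ratio <- (out$intensity / out$length) / ref_molar
  out
}

#' Ratio of two band intensities
#'
#' E.g. the EDC band over the early exon RNP band on a native gel, tracked
#' over a time course.
#'
#' @param numerator,denominator band intensities (vectors allowed; a
#'   time-series of measurements divides elementwise).
#' @return numeric ratio(s).
#' @export
band_ratio <- function(numerator, denominator) {
  if (any(is.na(denominator)) || any(denominator <= 0)) {
    abort("denominator band intensity must be > 0")
  }
  if (any(numerator < 0, na.rm = TRUE)) abort("band intensities must be >= 0")
  numerator / denominator
}

#' Percent exon inclusion from included/skipped band intensities
#'
#' @param included,skipped intensities of the exon-included and
#'   exon-skipped products (vectors allowed).
#' @return percentage in \[0, 100\]: `100 * included / (included + skipped)`.
#' @export
percent_inclusion <- function(included, skipped) {
  if (any(included < 0, na.rm = TRUE) || any(skipped < 0, na.rm = TRUE)) {
    abort("band intensities must be >= 0")
  }
  total <- included + skipped
  if (any(is.na(total)) || any(total <= 0)) {
    abort("included + skipped must be > 0")
  }
  100 * included / total
}
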