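#' Normalized spectral abundance factors
#'
#' NSAF expresses each protein's share of the identified spectra in a
#' sample after correcting for protein length: longer proteins produce
#' more tryptic peptides and therefore more spectra at equal molar
#' abundance. For protein *i*,
#' \deqn{NSAF_i = (SpC_i / L_i) / \sum_j (SpC_j / L_j)}
#' where SpC is the spectral count and L the length in amino acids. Values
#' lie in \[0, 1\] and sum to 1 over the sample. Proteins with zero counts
#' are retained with NSAF 0 so that NSAF tables from different complexes
#' stay aligned on the same protein universe.
#'
#' @param records tibble/data frame with columns `protein`, `spc`
#'   (nonnegative integer spectral count) and `length` (positive integer,
#'   amino acids).
#' @return the input as a tibble with an added `nsaf` column.
#' @export
nsaf <- function(records) {
  required <- c("protein", "spc", "length")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort(paste0("spectral-count table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) abort("spectral-count table is empty")
  if (any(is.na(records$spc)) || any(records$spc < 0)) {
    abort("spectral counts must be nonnegative")
  }
  if (any(is.na(records$length)) || any(records$length < 1)) {
    abort("protein lengths must be >= 1")
  }
  if (anyDuplicated(records$protein)) {
    abort("duplicate protein identifiers in spectral-count table")
  }
  saf <- records$spc / records$length
  total <- sum(saf)
  if (total <= 0) abort("no spectra: all spectral counts are zero")
  out <- as_tibble(records)
  out$nsaf <- saf / total
  out
}
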