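#' Fold-change heat map across complex comparisons
#'
#' Renders a proteins x comparisons matrix of log2 fold changes, proteins
#' sorted by descending log2 fold change in the first comparison, on the
#' red/yellow/green scale conventional for depletion/no-change/enrichment.
#'
#' @param comparisons named list of `complex_comparison` tibbles (see
#'   [fold_change()]).
#' @param file optional path; when given, the plot is written there (PDF
#'   or PNG by extension).
#' @return invisibly, the plotted log2 fold-change matrix.
#' @export
plot_fold_change_heatmap <- function(comparisons, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    abort("plot_fold_change_heatmap requires the 'pheatmap' package")
  }
  proteins <- sort(unique(unlist(lapply(comparisons, function(x) x$protein))))
  mat <- sapply(comparisons, function(cmp) {
    log2(cmp$fold_change)[match(proteins, cmp$protein)]
  })
  rownames(mat) <- proteins
  mat <- mat[order(mat[, 1], decreasing = TRUE, na.last = TRUE), , drop = FALSE]
  pal <- grDevices::colorRampPalette(c("red", "yellow", "green"))(51)
  lim <- max(abs(mat), na.rm = TRUE)
  pheatmap::pheatmap(
    mat, cluster_rows = FALSE, cluster_cols = FALSE,
    color = pal, breaks = seq(-lim, lim, length.out = 52),
    na_col = "grey90", filename = file %||% NA
  )
  invisible(mat)
}
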