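# Small in-code fixture builders shared across test files.

# peptide table from a named list of per-protein peptide ratios,
# heavy channel fixed at 1000 so light = 1000 * ratio
peptides_from_ratios <- function(ratios, complex_pair = "cmp") {
  rows <- lapply(names(ratios), function(p) {
    r <- ratios[[p]]
    tibble::tibble(
      peptide = sprintf("%s_pep%d", p, seq_along(r)),
      protein = p,
      complex_pair = complex_pair,
      intensity_light = 1000 * r,
      intensity_heavy = 1000
    )
  })
  dplyr::bind_rows(rows)
}

# one exon model on a synthetic plus-strand locus with a uniquely planted
# branch point: the upstream-intron background is A-free (C/T/G) so the
# planted CTCAG is the only adenosine-containing candidate
make_test_exon <- function(ui_len = 300L, ex_len = 100L, di_len = 300L,
                           bps_offset = 30L, exon_id = "ex1",
                           chrom = "gene_t", delta_psi = 40) {
  set.seed(ui_len + bps_offset) # deterministic background
  ui <- sample(c("C", "T", "G"), ui_len, replace = TRUE)
  ui[ui_len - 1L] <- "A"; ui[ui_len] <- "G" # terminal AG (excluded from search)
  i_b <- ui_len - 1L - bps_offset
  ui[(i_b - 3L):(i_b + 1L)] <- c("C", "T", "C", "A", "G")
  py <- seq(i_b + 2L, ui_len - 2L)
  ui[py] <- sample(c("C", "T"), length(py), replace = TRUE)
  tibble::tibble(
    exon_id = exon_id, chrom = chrom, strand = "+",
    exon_start = ui_len, exon_end = ui_len + ex_len,
    up_intron_start = 0L, up_intron_end = ui_len,
    down_intron_start = ui_len + ex_len,
    down_intron_end = ui_len + ex_len + di_len,
    up_intron_seq = paste(ui, collapse = ""),
    delta_psi = delta_psi
  )
}

# odd-width cluster whose midpoint is exactly `midpoint`
make_cluster <- function(exon, midpoint, width = 11L, id = "cl1") {
  stopifnot(width %% 2L == 1L)
  tibble::tibble(
    cluster_id = id, exon_id = exon$exon_id,
    chrom = exon$chrom, strand = exon$strand,
    start = midpoint - (width - 1L) %/% 2L,
    end = midpoint + (width - 1L) %/% 2L + 1L
  )
}

# cluster midpoint placed `d3` nt upstream of the exon's 3'ss AG first base
cluster_at_d3 <- function(exon, d3, width = 11L, id = "cl1") {
  make_cluster(exon, (exon$exon_start - 2L) - d3, width = width, id = id)
}
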