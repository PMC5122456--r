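#!/usr/bin/env Rscript
# Stage 2: SILAC quantification of the exon RNP complexes.
#
# Reads the peptide tables from stage 1 and computes, per protein:
# light/heavy ratios, anchor-normalized ratios (CBP20/CBP80), fold changes
# for the three complex contrasts, and the two-experiment consensus after
# the consistency filter. Writes per-comparison TSVs, a JSON summary and a
# fold-change heat map under results/quant/.

suppressPackageStartupMessages({
  library(exonrnp)
  library(dplyr)
})

ind <- "results/data"
out <- "results/quant"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pep1 <- read_peptide_tsv(file.path(ind, "exp1_peptides.tsv"))
pep2 <- read_peptide_tsv(file.path(ind, "exp2_peptides.tsv"))

## experiment 1: direct mixtures
norm1 <- silac_quantify(pep1)
act1 <- fold_change(norm1, "active_vs_repressed", "active", "repressed",
                    complex_pair = "active_vs_repressed")
edc1 <- fold_change(norm1, "edc_vs_repressed", "edc", "repressed",
                    complex_pair = "edc_vs_repressed")
ea1 <- ratio_of_ratios(edc1, act1)

## experiment 2: spiked reference
ab <- reference_channel_abundance(pep2)
act2 <- abundance_fold_change(ab, "active", "repressed")
ea2 <- abundance_fold_change(ab, "edc", "active")

## two-experiment consensus
act <- consistency_filter(act1, act2)
ea <- consistency_filter(ea1, ea2)

dump_cmp <- function(cmp, name) {
  readr::write_tsv(
    as_tibble(cmp) |> arrange(desc(log2(fold_change))),
    file.path(out, paste0(name, ".tsv"))
  )
}
dump_cmp(act1, "active_vs_repressed_exp1")
dump_cmp(ea1, "edc_vs_active_exp1")
dump_cmp(act2, "active_vs_repressed_exp2")
dump_cmp(ea2, "edc_vs_active_exp2")
readr::write_tsv(act, file.path(out, "active_vs_repressed_consensus.tsv"))
readr::write_tsv(ea, file.path(out, "edc_vs_active_consensus.tsv"))

repressed_enriched <- act |> filter(fold_change < 0.5) |> pull(protein)
hallmarks <- c("DDX17", "TRA2B", "SFRS3", "LUC7L2")
message("Proteins >2-fold enriched in the repressed complex: ",
        paste(repressed_enriched, collapse = ", "))
message("Active/repressed consensus DDX17: ",
        round(act$fold_change[act$protein == "DDX17"], 2))
message("EDC/active consensus  TRA2B: ",
        round(ea$fold_change[ea$protein == "TRA2B"], 2),
        "  SFRS3: ", round(ea$fold_change[ea$protein == "SFRS3"], 2),
        "  LUC7L2: ", round(ea$fold_change[ea$protein == "LUC7L2"], 2))

write_json_summary(list(
  n_proteins_consensus = nrow(act),
  repressed_enriched = repressed_enriched,
  hallmark_fold_changes = list(
    ddx17_active_vs_repressed = act$fold_change[act$protein == "DDX17"],
    tra2b_edc_vs_active = ea$fold_change[ea$protein == "TRA2B"],
    sfrs3_edc_vs_active = ea$fold_change[ea$protein == "SFRS3"],
    luc7l2_edc_vs_active = ea$fold_change[ea$protein == "LUC7L2"]
  ),
  agreement_rate = mean(c(act$agreement, ea$agreement))
), file.path(out, "summary.json"))

if (requireNamespace("pheatmap", quietly = TRUE)) {
  plot_fold_change_heatmap(
    list(active_vs_repressed = act1, edc_vs_active = ea1),
    file = file.path(out, "fold_change_heatmap.pdf")
  )
  message("Wrote heat map to ", file.path(out, "fold_change_heatmap.pdf"))
}
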