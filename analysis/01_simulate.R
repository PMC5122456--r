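#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Produces, under results/data/:
#   exp1_peptides.tsv   direct-mixture SILAC experiment (active/repressed
#                       and EDC/repressed mixed 1:1 against the heavy
#                       repressed complex)
#   exp2_peptides.tsv   spiked-reference experiment (three light complexes
#                       against a common heavy reference)
#   spectral_counts.tsv per-protein spectral counts for NSAF
#   exons.gff3, loci.fa, clusters.bed, delta_psi.tsv
#                       95-exon repressed cohort with planted binding zones
#   truth.json          planted fold changes and zone labels

suppressPackageStartupMessages(library(exonrnp))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating direct-mixture SILAC experiment (seed ", seed, ")")
sim1 <- generate_silac_experiment(silac_sim_config(
  fold_changes = edc_study_fold_changes(),
  mixing_error = 1.15, seed = seed
))
write_peptide_tsv(sim1$peptides, file.path(out, "exp1_peptides.tsv"))

message("Simulating spiked-reference SILAC experiment")
sim2 <- generate_silac_experiment(silac_sim_config(
  fold_changes = spiked_reference_fold_changes(),
  mixing_error = c(repressed = 1.1, active = 0.95, edc = 1.2),
  seed = seed + 1L
))
write_peptide_tsv(sim2$peptides, file.path(out, "exp2_peptides.tsv"))

message("Simulating spectral counts")
write_spectral_tsv(generate_spectral_counts(60, seed = seed),
                   file.path(out, "spectral_counts.tsv"))

message("Simulating 95-exon repressed cohort")
cohort <- generate_exon_cohort(exon_sim_config(seed = seed + 1000L))
write_exon_gff3(cohort$exons, file.path(out, "exons.gff3"))
write_fasta(cohort$sequences, file.path(out, "loci.fa"))
write_bed6(cohort$clusters, file.path(out, "clusters.bed"))
readr::write_tsv(cohort$exons[, c("exon_id", "delta_psi")],
                 file.path(out, "delta_psi.tsv"))

write_json_summary(list(
  seed = seed,
  silac_truth = list(
    exp1 = sim1$truth$fold_changes,
    exp2 = sim2$truth$fold_changes,
    mixing_error_exp1 = as.list(sim1$truth$mixing_error),
    mixing_error_exp2 = as.list(sim2$truth$mixing_error)
  ),
  cohort_truth = cohort$truth
), file.path(out, "truth.json"))

message("Wrote ", out, ": ",
        nrow(sim1$peptides) + nrow(sim2$peptides), " peptides, ",
        nrow(cohort$exons), " exons, ", nrow(cohort$clusters), " clusters")
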