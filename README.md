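# exonrnp

Quantitative analysis of exon ribonucleoprotein (RNP) remodeling and of
repressive RNA-binding-protein positioning, for splicing biologists
working with purified-complex SILAC mass spectrometry and iCLIP binding
maps.

Most vertebrate exons are recognized by *exon definition*: U1 snRNP,
U2AF and the U2 snRNP assemble across the exon into an exon definition
complex (EDC). Repressors such as PTBP1 block this maturation from
*distal* intronic binding sites. `exonrnp` implements the two
computations that quantify this:

1. **Comparative SILAC quantification of purified complexes.** Per
   peptide, the light/heavy ratio r = I_L/I_H; per protein, the
   exponentiated median of log2 peptide ratios; normalization by the
   geometric mean of the cap-binding anchor proteins CBP20/CBP80 (bound
   once per capped RNA, hence equimolar across complexes); fold changes
   between complex states by direct mixture, by ratio of ratios
   ((EDC/repressed)/(active/repressed) = EDC/active), or against a
   spiked heavy reference; a two-experiment consistency filter; two-fold
   enrichment classes; and NSAF spectral abundances
   (NSAF_i = (SpC_i/L_i) / Σ_j SpC_j/L_j).
2. **Positional classification of iCLIP clusters** around repressed
   cassette exons into zones — a (distal upstream intron), b (branch
   point/polypyrimidine region), c (exon), d (downstream intron) — using
   the 100-nt (from the 3'ss AG) and 25-nt (from the predicted branch
   adenosine) rules, with a position-weight-matrix branch-point scanner,
   plus per-exon binding-architecture summaries (distal-only, etc.).

A synthetic-data module generates SILAC experiments, spectral-count
tables and exon/cluster cohorts with known planted truth, so the whole
pipeline is testable without any external data.

## Worked example

The `analysis/` directory is a numbered workflow
(`01_simulate.R` … `05_report.R`) that simulates the full study and
writes its tables under `results/`. Its core, condensed:

```r
library(exonrnp)

## two-experiment SILAC study with planted fold changes
study <- run_edc_study(seed = 1)
ea <- study$edc_vs_active        # consensus EDC/active fold changes
ar <- study$active_vs_repressed  # consensus active/repressed fold changes
ar$protein[ar$fold_change < 0.5] # proteins >2x enriched when repressed
#> [1] "MBNL1" "PTBP1" "RAVER1"
round(ea$fold_change[match(c("TRA2B", "SFRS3", "LUC7L2"), ea$protein)], 2)
#> [1] 3.95 4.04 8.68

## 95-exon repressed cohort: where does the repressor bind?
cohort <- generate_exon_cohort(exon_sim_config(seed = 1001))
kept <- select_derepressed(cohort$exons, cohort$clusters, psi_threshold = 15)
zones <- classify_clusters(cohort$clusters, kept)
summ <- cohort_summary(summarize_exons(zones, exon_ids = kept$exon_id))
summ$distal_only_count; summ$distal_only_pct
#> [1] 56
#> [1] 58.9
```

The three proteins enriched in the repressed complex are the repressor
module (PTBP1 with its corepressors RAVER1 and MBNL1); the EDC/active
fold changes recover the planted SR-protein recruitment (TRA2B and SFRS3
~4-fold, LUC7L2 ~8-fold); and 56 of 95 exons (58.9%) carry clusters only
in the distal intron zones, most on both sides of the exon.

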