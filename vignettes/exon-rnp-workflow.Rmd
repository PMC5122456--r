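---
title: "Quantifying exon RNP remodeling and mapping repressive binding zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exon RNP remodeling and mapping repressive binding zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonrnp)
```

## The problem

Most vertebrate exons are recognized by *exon definition*: the U1 snRNP
binds the 5' splice site, U2AF the polypyrimidine tract and 3' splice
site, and the U2 snRNP the branch point, assembling an exon definition
complex (EDC) across the exon. Splicing repressors such as PTBP1
(polypyrimidine-tract binding protein) can block this maturation from
binding sites in the flanking introns that are *distal* to the splice
sites, so simple steric competition cannot explain the repression. Two
quantitative questions follow:

1. **How does the protein composition of an exon RNP change** between its
   repressed state, its active early state, and the EDC? This is measured
   by comparative SILAC mass spectrometry of purified complexes.
2. **Where do the repressor's binding sites sit** relative to repressed
   exons genome-wide? This is measured by classifying iCLIP clusters into
   positional zones around each exon.

`exonrnp` implements both computations, plus a synthetic-data module that
generates inputs with known ground truth so every stage is testable
end to end without any external download.

## SILAC quantification model

Each peptide is observed as a light (^12^C) and a heavy (^13^C) peak;
the ratio \(r = I_L / I_H\) estimates the relative
abundance of its protein in the two mixed complexes. The pipeline is:

1. **Peptide ratios** (`peptide_ratios()`): \(r = I_L/I_H\). Peptides
   with an absent or zero channel cannot give a finite ratio; they are
   excluded with a reason code (`missing-channel`, `zero-channel`), never
   silently. Proteins seen in only one channel are reported as
   `insufficient-evidence` rather than being assigned an infinite ratio.
2. **Protein aggregation** (`aggregate_protein_ratios()`): the protein
   ratio is \(2^{\mathrm{median}(\log_2 r_i)}\). The median on the log
   scale is robust to a single aberrant peptide; the mean is available as
   an option. The number of contributing peptides is always reported; no
   hard minimum is imposed by default.
3. **Anchor normalization** (`anchor_normalize()`): the cap-binding
   proteins CBP20 and CBP80 bind every capped transcript once and are
   therefore equimolar across all complexes; their averaged ratio
   measures the mixing/processing error of that mixture. All ratios are
   divided by the anchors' geometric mean, which is exactly 1 afterwards.
   "Average" means geometric mean here because ratios are multiplicative;
   an arithmetic option exists for strict literalism.
4. **Fold changes.** For a direct 1:1 mixture of two complexes the
   normalized ratio *is* the fold change between the states
   (`fold_change()`). A third contrast is derived by **ratio of ratios**
   (`ratio_of_ratios()`): \((\mathrm{EDC/repressed}) /
   (\mathrm{active/repressed}) = \mathrm{EDC/active}\) — the shared
   repressed-state terms cancel without the two complexes ever being
   mixed.
5. **Spiked-reference abundances** (`reference_channel_abundance()`):
   when each light complex is mixed with one common heavy reference, a
   protein's abundance in state \(s\) is
   \[(I_L(p,s)/I_H(p)) \; / \; \mathrm{geomean}_{a \in \mathrm{anchors}}
   (I_L(a,s)/I_H(a)),\]
   and state contrasts are ratios of these abundances
   (`abundance_fold_change()`).
6. **Consistency filter** (`consistency_filter()`): proteins quantified
   in only one of the two experimental designs are not considered
   further; for retained proteins both estimates, their directional
   agreement, and their geometric-mean consensus are reported.
7. **Enrichment classes** (`classify_enrichment()`): fold change
   \(> 2\) is `enriched`, \(< 1/2\) `depleted`, otherwise `unchanged`
   (strict comparisons, threshold configurable).

There is no multiple-testing procedure on the MS ratios: none is part of
the analysis being implemented, and adding one would change its meaning.

The wording "dividing a normalized SILAC ratio from the active complex by
the SILAC ratio from repressed complex" is ambiguous between the
direct-mixture reading (one ratio per mixture, the ratio is already the
fold change) and the two-ratio spiked-reference reading. Both are
implemented as distinct operations (`fold_change()` vs
`reference_channel_abundance()` + `abundance_fold_change()`); on
noise-free data they agree exactly, which is one of the package's
acceptance properties.

### NSAF

Spectral counting uses the normalized spectral abundance factor
(`nsaf()`): \(\mathrm{NSAF}_i = (SpC_i/L_i) / \sum_j (SpC_j/L_j)\), where
\(L\) corrects for the fact that longer proteins yield more tryptic
peptides. Zero-count proteins are kept at NSAF 0 so tables from different
complexes stay aligned. Whether the counts are unique or total spectra is
the caller's choice; the formula is agnostic.

## Zone classification of CLIP clusters

For each repressed cassette exon (selected by `select_derepressed()`:
delta-PSI \(\ge 15\) percentage points upon repressor depletion —
inclusive boundary, matching the "\(\ge\)" wording — and at least one
associated cluster), clusters are assigned to zones by
`classify_clusters()`:

* **c** — midpoint inside the exon;
* **d** — midpoint downstream of the 5' splice site;
* **a** — midpoint more than 100 nt upstream of the 3'ss AG;
* otherwise the branch point is predicted, and the cluster is **a** when
  more than 25 nt upstream of the branch adenosine, else **b** (the
  branch point / polypyrimidine-tract region).

Fixed conventions, chosen so the rules are testable:

* The rules operate on the cluster **midpoint**, rounded toward the 3'ss
  for even lengths. An alternative `position = "overlap"` mode labels
  every base and resolves conflicts by the precedence c > b > d > a, for
  sensitivity analysis.
* Distances are counted in nt, exclusive, from the first base of the
  intron-terminal AG and from the branch adenosine respectively. "More
  than" is implemented as strict `>` by default; `strict = FALSE` gives
  the `>=` reading at both thresholds.
* All internal coordinates are 0-based half-open (BED convention); GFF3's
  1-based closed coordinates are converted only inside the I/O layer.
* One branch point is predicted per exon and shared by all of its
  proximal clusters.
* If branch-point prediction fails where it is needed, the cluster is
  conservatively labelled **b** with a `bps_degraded` flag — proximal
  binding is treated as potentially splice-site-associated, so
  distal-only architectures are never overcalled.

Per-exon label multisets map to architecture classes
(`summarize_exons()`): `unbound`, `distal-only` (labels all in
\{a, d\}), `contains-b`, `contains-c`, and `mixed` (both b and c).
`cohort_summary()` reports counts and percentages (to 0.1%) over the full
retained cohort — exons with unclassifiable or no clusters stay in the
denominator.

### Branch point model

The cited branch-point predictor's internals are not reproducible from
the text, so the package ships its own position-weight-matrix scanner
(`predict_bps()`): a 5-position matrix over the mammalian consensus
(pyrimidine-rich with the canonical instance `cucAg`; branch A at
position 4), scored as log2 odds against a uniform background over the
final 100 nt of the upstream intron, excluding the last 3 nt (the AG and
the base before it). Candidates are adenosines only; ties break toward
the 3'ss, where mammalian branch points concentrate. The matrix is data,
not code — pass any 4x5 probability matrix to use a different model.

## What the simulator emulates — and what it does not

`generate_silac_experiment()` draws, per peptide, a base intensity
(log-uniform over one decade around `base_intensity`) and multiplies the
light channel by the protein's planted fold change and the mixture's
global `mixing_error`. Noise is multiplicative and log-normal.
`log2_noise_sd` is defined as the sd of the *ratio* noise and is applied
as independent per-channel noise of sd \(/\sqrt 2\), so the config
parameter is directly the measurement noise on the quantity that matters
downstream. Missing peptides lose one randomly chosen channel and are
emitted with `NA` (not zero), forcing the handling policy downstream to
be explicit.

`generate_exon_cohort()` builds one locus per exon (upstream intron,
exon, downstream intron, plus strand; `flip_exon_cohort()`
reverse-complements whole loci for minus-strand fixtures). Each upstream
intron ends in a planted exact branch consensus (`CTCAG`) at a recorded
offset, followed by an adenosine-free pyrimidine tract and the terminal
AG — so the planted branch point is always the best-scoring candidate
and any random tie upstream loses the toward-3'ss tie-break. Clusters
are placed with midpoints at least 5 nt inside their intended zone,
separating rule testing from boundary testing; boundary behaviour is
tested separately by sliding 1-nt clusters across a locus. Architecture
counts are apportioned deterministically (largest remainder), so planted
fractions are exact by construction rather than binomially noisy.

Defaults are fixed once as the study conditions: a 95-exon cohort with
architecture counts 11 a-only, 9 d-only, 36 a+d, 20 b-containing,
9 c-containing, 10 mixed — 56 distal-only exons (58.9%), most bound on
both sides, and none exon-only; a protein roster whose planted fold
changes encode the repressor module (PTBP1, RAVER1, MBNL1 more than
two-fold enriched in the repressed complex), the hnRNP/helicase gains in
the active complex (DDX17 3-fold), and the SR-protein/U2 snRNP
recruitment into the EDC (TRA2B and SFRS3 4-fold, LUC7L2 8-fold over the
active complex); peptide ratio noise sd 0.2 in log2; 6–18 peptides per
protein, typical of abundant spliceosomal proteins; mixing errors of
1.15 (direct design) and 1.1/0.95/1.2 (spiked design). In the spiked
design the heavy reference is taken to have the active complex's
composition, as a depleted-extract preparation would.

The simulator does **not** model raw spectra, retention times, charge
states, shared peptides, interference between co-eluting peaks,
intensity-dependent missingness, or correlated peptide noise within a
protein, and cluster placement knows nothing of crosslinking biases or
mappability. Passing tests therefore demonstrate that the *computational
rules* are implemented correctly and are recoverable under calibrated
noise — not that the pipeline is robust to every pathology of real MS or
iCLIP data.

## Numerical choices and degenerate inputs

* All ratio averaging is geometric (log-scale); anchor geometric means
  are restored to exactly 1 (tested to 1e-12).
* Normalization with no anchor present is a hard error; a single anchor
  proceeds with a warning.
* All-zero spectral counts, empty cohorts, zero reference bands, and
  `included + skipped = 0` are errors, not NaNs.
* A search window longer than the available intron sequence truncates
  with a warning; a window without any adenosine is an error.
* Seeds are explicit everywhere (`withr::with_seed`, so the caller's RNG
  stream is untouched); equal config and seed give byte-identical
  output.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the study's own scale: two SILAC experiments of ~2,000 peptides over a
36-protein roster, a 95-exon cohort (about 190 clusters), a 200-exon
cohort for exhaustive label recovery, 1,000 randomized property cases,
and 20 replicate simulations of 100 proteins for parameter recovery.
These sizes exercise every code path while keeping a full run in well
under a minute per stage.

## Known limitations

* The branch-point model is a deliberately simple PWM stand-in; on real
  introns a dedicated predictor will differ in the proximal a/b split
  (which is why prediction failure degrades conservatively to b).
* Fold changes for proteins absent from a channel are reported as
  `insufficient-evidence`, not imputed; the package takes no position on
  missing-value imputation for MS data.
* `consistency_filter()` requires exactly two experiments, matching the
  study design it implements.
* Gel-band utilities assume intensities already corrected for background
  and labeling; they are arithmetic helpers, not densitometry.
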