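#' Configuration for a synthetic SILAC experiment
#'
#' Describes one simulated SILAC-MS run in which one or more pairs of exon
#' RNP complexes ("light" vs "heavy") are mixed and peptides are quantified
#' in both isotope channels. The generator plants known per-protein
#' abundance ratios so downstream quantification can be checked against
#' ground truth.
#'
#' @param fold_changes named list: one element per mixed comparison
#'   (`complex_pair` label), each a named numeric vector mapping protein id
#'   to its true light/heavy abundance ratio. Anchor proteins must be
#'   absent or set to 1. Defaults to the built-in exon-complex roster of
#'   [edc_study_fold_changes()].
#' @param n_proteins total number of simulated proteins. Proteins named in
#'   `fold_changes` come first; the remainder are filler proteins with true
#'   ratio 1 in every comparison. `NA` (default) uses exactly the named
#'   roster plus anchors.
#' @param peptides_per_protein integer range `c(min, max)`; each protein's
#'   peptide count in each comparison is drawn uniformly from this range.
#' @param log2_noise_sd standard deviation, in log2 units, of each
#'   peptide's multiplicative measurement noise on the light/heavy ratio.
#'   Noise is applied to the two channels independently with per-channel
#'   sd `log2_noise_sd / sqrt(2)`, so the peptide ratio carries the stated
#'   sd while absolute intensities still fluctuate per channel.
#' @param anchor_ids proteins present at equal true abundance in every
#'   complex (true ratio exactly 1); defaults to the cap-binding proteins
#'   `CBP20` and `CBP80`, which bind every capped RNA once.
#' @param mixing_error global factor (> 0) applied to the light channel of
#'   each comparison, emulating unequal 1:1 mixing; scalar, or a named
#'   vector with one entry per comparison.
#' @param base_intensity location of the per-peptide base intensity
#'   distribution (arbitrary units); base intensities are drawn
#'   log-uniformly over one decade either side of this value.
#' @param missing_rate probability in `[0, 1)` that a peptide is absent
#'   from one (randomly chosen) channel; absent intensities are `NA`.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return an object of class `silac_sim_config` (a validated list).
#' @seealso [generate_silac_experiment()]
#' @export
silac_sim_config <- function(fold_changes = edc_study_fold_changes(),
                             n_proteins = NA,
                             peptides_per_protein = c(6L, 18L),
                             log2_noise_sd = 0.2,
                             anchor_ids = c("CBP20", "CBP80"),
                             mixing_error = 1,
                             base_intensity = 1e6,
                             missing_rate = 0,
                             seed = 1L) {
  if (!is.list(fold_changes) || is.null(names(fold_changes)) ||
      any(names(fold_changes) == "")) {
    abort("configuration error: `fold_changes` must be a named list of named numeric vectors")
  }
  for (cp in names(fold_changes)) {
    fc <- fold_changes[[cp]]
    if (!is.numeric(fc) || is.null(names(fc)) || any(names(fc) == "")) {
      abort(sprintf("configuration error: `fold_changes$%s` must be a named numeric vector", cp))
    }
    if (any(!is.finite(fc)) || any(fc <= 0)) {
      abort(sprintf("configuration error: `fold_changes$%s` must be strictly positive", cp))
    }
    bad_anchor <- intersect(names(fc)[fc != 1], anchor_ids)
    if (length(bad_anchor)) {
      abort(sprintf(
        "configuration error: `fold_changes` assigns non-unit ratio to anchor protein(s) %s",
        paste(bad_anchor, collapse = ", ")
      ))
    }
  }
  check_range2(peptides_per_protein, "peptides_per_protein", lower = 1)
  check_scalar(log2_noise_sd, "log2_noise_sd", lower = 0)
  if (!is.character(anchor_ids) || length(anchor_ids) < 1L) {
    abort("configuration error: `anchor_ids` must name at least one protein")
  }
  pairs <- names(fold_changes)
  if (length(mixing_error) == 1L && is.null(names(mixing_error))) {
    mixing_error <- stats::setNames(rep(mixing_error, length(pairs)), pairs)
  }
  if (!all(pairs %in% names(mixing_error))) {
    abort("configuration error: `mixing_error` must be scalar or named per comparison")
  }
  mixing_error <- mixing_error[pairs]
  for (m in mixing_error) check_scalar(m, "mixing_error", lower = 0, strict_lower = TRUE)
  check_scalar(base_intensity, "base_intensity", lower = 0, strict_lower = TRUE)
  check_scalar(missing_rate, "missing_rate", lower = 0, upper = 1)
  if (missing_rate >= 1) abort("configuration error: `missing_rate` must be < 1")
  check_scalar(seed, "seed", integerish = TRUE)

  roster <- unique(c(anchor_ids, unlist(lapply(fold_changes, names))))
  if (is.na(n_proteins)) n_proteins <- length(roster)
  check_scalar(n_proteins, "n_proteins", lower = 1, integerish = TRUE)
  if (n_proteins < length(roster)) {
    abort(sprintf(
      "configuration error: `n_proteins` (%d) smaller than the %d proteins named in `fold_changes`/`anchor_ids`",
      n_proteins, length(roster)
    ))
  }
  if (n_proteins > length(roster)) {
    filler <- sprintf("SIMP%03d", seq_len(n_proteins - length(roster)))
    roster <- c(roster, filler)
  }

  structure(
    list(
      fold_changes = fold_changes,
      proteins = roster,
      n_proteins = as.integer(n_proteins),
      peptides_per_protein = as.integer(peptides_per_protein),
      log2_noise_sd = log2_noise_sd,
      anchor_ids = anchor_ids,
      mixing_error = mixing_error,
      base_intensity = base_intensity,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "silac_sim_config"
  )
}

#' Planted fold changes for the exon-complex remodeling study
#'
#' The default protein roster used by the simulator: a cast of spliceosomal
#' and hnRNP proteins with true abundance ratios chosen to reproduce the
#' compositional remodeling of a PTBP1-repressed exon RNP. The repressor
#' module (PTBP1 and corepressors RAVER1, MBNL1) is >2-fold enriched in the
#' repressed complex; hnRNPs and the DDX5/DDX17 helicases rise in the
#' active early complex (DDX17 3-fold); and SR/SR-related proteins plus the
#' U2 snRNP are recruited into the exon definition complex (TRA2B and SFRS3
#' 4-fold over the active complex, LUC7L2 8-fold). U1 snRNP proteins and
#' the CBP20/CBP80 anchors are flat throughout.
#'
#' @return a named list with elements `active_vs_repressed` and
#'   `edc_vs_repressed`, each a named vector of true light/heavy ratios,
#'   plus attribute `"edc_vs_active"` holding the implied EDC/active ratios.
#' @export
edc_study_fold_changes <- function() {
  act <- c( # active early complex over repressed complex
    PTBP1 = 0.20, RAVER1 = 0.30, MBNL1 = 0.35, MATR3 = 0.80,
    SNRNP70 = 1.0, SNRPA = 1.0, SNRPC = 1.0,
    U2AF2 = 1.3, U2AF1 = 1.3,
    HNRNPC = 3.0, HNRNPD = 2.5, RBMX = 2.2, HNRNPK = 2.5, HNRNPR = 2.0,
    SYNCRIP = 2.8, HNRNPU = 2.2, HNRNPA1 = 1.1, HNRNPA2B1 = 1.0, HNRNPH1 = 1.0,
    DDX17 = 3.0, DDX5 = 1.5, DHX15 = 2.0,
    TRA2B = 3.0, SFRS3 = 1.6, LUC7L2 = 1.2,
    SRSF6 = 1.0, SRSF7 = 1.0, SRSF11 = 1.0, RBM39 = 1.2,
    SF3B1 = 1.0, SF3A1 = 1.0, SNRPB2 = 1.0, DDX46 = 1.0, DDX39B = 1.0
  )
  eda <- c( # EDC over active early complex
    PTBP1 = 0.5, RAVER1 = 0.6, MBNL1 = 0.6, MATR3 = 0.8,
    SNRNP70 = 1.0, SNRPA = 1.0, SNRPC = 1.0,
    U2AF2 = 1.2, U2AF1 = 1.2,
    HNRNPC = 0.3, HNRNPD = 0.5, RBMX = 0.5, HNRNPK = 0.3, HNRNPR = 0.5,
    SYNCRIP = 0.3, HNRNPU = 0.3, HNRNPA1 = 0.5, HNRNPA2B1 = 0.5, HNRNPH1 = 0.7,
    DDX17 = 0.5, DDX5 = 0.6, DHX15 = 0.8,
    TRA2B = 4.0, SFRS3 = 4.0, LUC7L2 = 8.0,
    SRSF6 = 3.5, SRSF7 = 3.0, SRSF11 = 3.0, RBM39 = 3.0,
    SF3B1 = 4.0, SF3A1 = 4.0, SNRPB2 = 3.5, DDX46 = 4.0, DDX39B = 1.5
  )
  stopifnot(identical(names(act), names(eda)))
  structure(
    list(active_vs_repressed = act, edc_vs_repressed = act * eda),
    edc_vs_active = eda
  )
}

#' Planted fold changes for the spiked-reference SILAC design
#'
#' In the second experimental design each of the three light complexes
#' (repressed, active early, EDC) is mixed with the same heavy reference
#' preparation, so per-complex abundances are read out against a common
#' internal standard. The reference is taken to have the active complex's
#' composition, so the planted light/heavy ratios per state follow directly
#' from [edc_study_fold_changes()].
#'
#' @return named list with elements `repressed`, `active`, `edc`, each a
#'   named vector of true light/heavy ratios against the heavy reference.
#' @export
spiked_reference_fold_changes <- function() {
  base <- edc_study_fold_changes()
  act <- base$active_vs_repressed
  eda <- attr(base, "edc_vs_active")
  list(
    repressed = 1 / act,
    active = stats::setNames(rep(1, length(act)), names(act)),
    edc = eda
  )
}

## deterministic pseudo-tryptic peptide sequences: 6-14 residues ending K/R
random_peptides <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  lens <- sample(6:14, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0(paste(sample(aa, l - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

#' Simulate a peptide-level SILAC quantification table
#'
#' Generates, for each configured comparison, peptide light/heavy intensity
#' pairs with multiplicative log-normal noise. For every protein the
#' expected light/heavy ratio equals its planted fold change times the
#' comparison's mixing error; anchor proteins have expected ratio equal to
#' the mixing error alone, which is what anchor normalization removes.
#'
#' @param config a [silac_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{peptides}{tibble with columns `peptide`, `protein`,
#'       `complex_pair`, `intensity_light`, `intensity_heavy` (`NA` = absent
#'       from that channel).}
#'     \item{truth}{a list recording the planted per-protein fold changes
#'       (tibble `protein`, `complex_pair`, `fold_change`) and the
#'       per-comparison `mixing_error`.}
#'   }
#' @export
generate_silac_experiment <- function(config) {
  if (!inherits(config, "silac_sim_config")) {
    abort("`config` must be created with silac_sim_config()")
  }
  with_seed(config$seed, {
    rows <- lapply(names(config$fold_changes), function(cp) {
      fc_named <- config$fold_changes[[cp]]
      fc <- stats::setNames(rep(1, length(config$proteins)), config$proteins)
      fc[names(fc_named)] <- fc_named
      mix <- config$mixing_error[[cp]]
      n_pep <- sample_range(config$peptides_per_protein, length(config$proteins))
      per_protein <- lapply(seq_along(config$proteins), function(i) {
        p <- config$proteins[i]
        k <- n_pep[i]
        base <- config$base_intensity * 10^runif(k, -1, 1)
        ch_sd <- config$log2_noise_sd / sqrt(2) # ratio noise = log2_noise_sd
        heavy <- base * 2^stats::rnorm(k, 0, ch_sd)
        light <- base * fc[[p]] * mix * 2^stats::rnorm(k, 0, ch_sd)
        if (config$missing_rate > 0) {
          gone <- runif(k) < config$missing_rate
          side <- runif(k) < 0.5
          light[gone & side] <- NA_real_
          heavy[gone & !side] <- NA_real_
        }
        tibble(
          peptide = random_peptides(k),
          protein = p,
          complex_pair = cp,
          intensity_light = light,
          intensity_heavy = heavy
        )
      })
      bind_rows(per_protein)
    })
    peptides <- bind_rows(rows)

    truth_fc <- bind_rows(lapply(names(config$fold_changes), function(cp) {
      fc <- stats::setNames(rep(1, length(config$proteins)), config$proteins)
      fc[names(config$fold_changes[[cp]])] <- config$fold_changes[[cp]]
      tibble(protein = names(fc), complex_pair = cp, fold_change = unname(fc))
    }))

    list(
      peptides = peptides,
      truth = list(
        fold_changes = truth_fc,
        mixing_error = config$mixing_error,
        anchor_ids = config$anchor_ids
      )
    )
  })
}

#' Simulate a spectral-count table
#'
#' Produces a reproducible table of (protein, spectral count, length) for
#' exercising NSAF computation. Counts follow a Poisson model whose rate
#' scales with protein length, reflecting that longer proteins yield more
#' tryptic peptides and hence more spectra.
#'
#' @param n_proteins number of proteins.
#' @param length_range `c(min, max)` protein length in amino acids.
#' @param spectra_per_100aa expected spectral count per 100 residues.
#' @param seed RNG seed.
#' @return tibble with columns `protein`, `spc`, `length`.
#' @export
generate_spectral_counts <- function(n_proteins,
                                     length_range = c(100L, 2000L),
                                     spectra_per_100aa = 5,
                                     seed = 1L) {
  check_scalar(n_proteins, "n_proteins", lower = 1, integerish = TRUE)
  check_range2(length_range, "length_range", lower = 1)
  check_scalar(spectra_per_100aa, "spectra_per_100aa", lower = 0)
  check_scalar(seed, "seed", integerish = TRUE)
  with_seed(seed, {
    len <- sample_range(length_range, n_proteins)
    tibble(
      protein = sprintf("SIMP%03d", seq_len(n_proteins)),
      spc = rpois(n_proteins, spectra_per_100aa * len / 100),
      length = as.integer(len)
    )
  })
}
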