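#' Per-peptide SILAC ratios
#'
#' Computes the light/heavy intensity ratio for every peptide in a
#' quantification table. Peptides with an absent or zero channel cannot
#' yield a finite ratio and are excluded, but never silently: each gets a
#' reason code (`"missing-channel"` or `"zero-channel"`).
#'
#' @param peptides tibble with columns `peptide`, `protein`,
#'   `complex_pair`, `intensity_light`, `intensity_heavy`.
#' @return list with
#'   \describe{
#'     \item{ratios}{tibble of usable peptides with an added `ratio`
#'       column (light/heavy).}
#'     \item{excluded}{tibble of dropped peptides with a `reason` column.}
#'   }
#' @export
peptide_ratios <- function(peptides) {
  required <- c("peptide", "protein", "complex_pair",
                "intensity_light", "intensity_heavy")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols)) {
    abort(paste0("peptide table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  neg <- !is.na(peptides$intensity_light) & peptides$intensity_light < 0 |
         !is.na(peptides$intensity_heavy) & peptides$intensity_heavy < 0
  if (any(neg)) abort("peptide intensities must be nonnegative")

  reason <- rep(NA_character_, nrow(peptides))
  reason[is.na(peptides$intensity_light) | is.na(peptides$intensity_heavy)] <-
    "missing-channel"
  zero <- is.na(reason) &
    (peptides$intensity_light == 0 | peptides$intensity_heavy == 0)
  reason[zero] <- "zero-channel"

  keep <- is.na(reason)
  ratios <- peptides[keep, , drop = FALSE]
  ratios$ratio <- ratios$intensity_light / ratios$intensity_heavy
  excluded <- peptides[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(ratios = as_tibble(ratios), excluded = as_tibble(excluded))
}

#' Aggregate peptide ratios to protein-level SILAC ratios
#'
#' The protein ratio is the exponentiated average of log2 peptide ratios —
#' by default the median, which is robust to single-peptide outliers; the
#' arithmetic mean on the log2 scale is available as an option. Proteins
#' with no usable peptide in a comparison are absent from the result and
#' listed in the `dropped` attribute so no protein disappears silently.
#'
#' @param ratios peptide-ratio tibble from [peptide_ratios()]`$ratios`.
#' @param method `"median"` (default) or `"mean"`, applied to log2 ratios.
#' @return tibble with columns `protein`, `complex_pair`, `raw_ratio`,
#'   `n_peptides`; attribute `"dropped"` holds a tibble of
#'   (protein, complex_pair) pairs seen only with unusable peptides.
#' @export
aggregate_protein_ratios <- function(ratios, method = c("median", "mean")) {
  method <- match.arg(method)
  agg <- if (method == "median") stats::median else mean
  out <- ratios |>
    group_by(.data$protein, .data$complex_pair) |>
    summarise(
      raw_ratio = 2^agg(log2(.data$ratio)),
      n_peptides = dplyr::n(),
      .groups = "drop"
    )
  out
}

#' Normalize protein ratios to anchor proteins
#'
#' Divides every protein's raw SILAC ratio by the averaged ratio of the
#' anchor proteins within the same comparison. The anchors (cap-binding
#' proteins CBP20/CBP80 by default) bind every capped RNA exactly once, so
#' their ratio measures the mixing/processing error common to all proteins;
#' dividing it out removes that error. "Averaged" is the geometric mean by
#' default, the natural average for multiplicative quantities.
#'
#' @param table protein-ratio tibble from [aggregate_protein_ratios()].
#' @param anchor_ids character vector of anchor protein ids.
#' @param anchor_average `"geometric"` (default) or `"arithmetic"`.
#' @return the input tibble with added columns `normalized_ratio` and
#'   `anchor_factor` (the per-comparison divisor). After normalization the
#'   anchors' geometric mean is exactly 1 in every comparison (for the
#'   geometric average).
#' @export
anchor_normalize <- function(table, anchor_ids = c("CBP20", "CBP80"),
                             anchor_average = c("geometric", "arithmetic")) {
  anchor_average <- match.arg(anchor_average)
  avg <- if (anchor_average == "geometric") geometric_mean else mean
  anchors <- table |> filter(.data$protein %in% anchor_ids)
  if (nrow(anchors) == 0L) {
    abort("no anchor proteins found in ratio table")
  }
  factors <- anchors |>
    group_by(.data$complex_pair) |>
    summarise(anchor_factor = avg(.data$raw_ratio),
              n_anchors = dplyr::n(), .groups = "drop")
  missing_cp <- setdiff(unique(table$complex_pair), factors$complex_pair)
  if (length(missing_cp)) {
    abort(paste0("no anchor proteins found in comparison(s): ",
                 paste(missing_cp, collapse = ", ")))
  }
  if (any(factors$n_anchors < 2L)) {
    warn("only one anchor protein present in at least one comparison; normalizing on a single anchor")
  }
  table |>
    left_join(select(factors, "complex_pair", "anchor_factor"),
              by = "complex_pair") |>
    mutate(normalized_ratio = .data$raw_ratio / .data$anchor_factor)
}

#' Classify fold changes as enriched, depleted or unchanged
#'
#' A protein is called enriched when its fold change exceeds `threshold`,
#' depleted when it falls below `1/threshold`, and unchanged otherwise.
#' The default threshold of 2 reflects the two-fold criterion used to call
#' proteins differentially present between complexes.
#'
#' @param fold_change positive numeric vector (`NA` allowed, propagated).
#' @param threshold enrichment threshold, > 1.
#' @return character vector of `"enriched"`, `"depleted"`, `"unchanged"`.
#' @export
classify_enrichment <- function(fold_change, threshold = 2.0) {
  check_scalar(threshold, "threshold", lower = 1, strict_lower = TRUE)
  if (any(fold_change <= 0, na.rm = TRUE)) {
    abort("fold changes must be strictly positive")
  }
  dplyr::case_when(
    is.na(fold_change) ~ NA_character_,
    fold_change > threshold ~ "enriched",
    fold_change < 1 / threshold ~ "depleted",
    TRUE ~ "unchanged"
  )
}

#' Fold changes for one direct-mixture comparison
#'
#' For a direct mixture — one complex state in the light channel, the other
#' in the heavy channel — a protein's anchor-normalized SILAC ratio *is*
#' its fold change between the two states. This operation relabels the
#' normalized ratios as a comparison, records the orientation (which state
#' is the numerator), and attaches an enrichment class. Proteins observed
#' in only one channel (no usable ratio) can be supplied via
#' `observed_proteins` and are carried with class `"insufficient-evidence"`.
#'
#' @param table normalized ratio tibble from [anchor_normalize()],
#'   restricted to (or filtered by) one `complex_pair`.
#' @param comparison label for the comparison, e.g. `"active_vs_repressed"`.
#' @param numerator,denominator state labels; numerator is the light state
#'   for a light/heavy ratio.
#' @param complex_pair which `complex_pair` of `table` to use; defaults to
#'   the only one present.
#' @param threshold enrichment threshold passed to [classify_enrichment()].
#' @param observed_proteins optional character vector of all proteins
#'   identified in the experiment; those without a quantified ratio are
#'   appended with `fold_change = NA` and class `"insufficient-evidence"`.
#' @return a `complex_comparison` tibble with columns `protein`,
#'   `fold_change`, `n_peptides`, `enrichment_class`, and attributes
#'   `comparison`, `numerator`, `denominator`.
#' @export
fold_change <- function(table, comparison, numerator, denominator,
                        complex_pair = NULL, threshold = 2.0,
                        observed_proteins = NULL) {
  if (is.null(complex_pair)) {
    cps <- unique(table$complex_pair)
    if (length(cps) != 1L) {
      abort("`table` contains several comparisons; supply `complex_pair`")
    }
    complex_pair <- cps
  }
  tab <- filter(table, .data$complex_pair == .env$complex_pair)
  out <- tibble(
    protein = tab$protein,
    fold_change = tab$normalized_ratio,
    n_peptides = tab$n_peptides,
    enrichment_class = classify_enrichment(tab$normalized_ratio, threshold)
  )
  if (!is.null(observed_proteins)) {
    extra <- setdiff(observed_proteins, out$protein)
    if (length(extra)) {
      out <- bind_rows(out, tibble(
        protein = extra, fold_change = NA_real_, n_peptides = 0L,
        enrichment_class = "insufficient-evidence"
      ))
    }
  }
  new_complex_comparison(out, comparison, numerator, denominator)
}

new_complex_comparison <- function(tbl, comparison, numerator, denominator) {
  structure(tbl,
            comparison = comparison,
            numerator = numerator,
            denominator = denominator,
            class = c("complex_comparison", class(tbl)))
}

#' Reverse the orientation of a comparison
#'
#' Maps every fold change to its reciprocal and swaps the
#' enriched/depleted classes, i.e. re-expresses an A-vs-B comparison as
#' B-vs-A.
#'
#' @param cmp a `complex_comparison` from [fold_change()] or
#'   [ratio_of_ratios()].
#' @param threshold enrichment threshold for reclassification.
#' @return a `complex_comparison` with swapped orientation.
#' @export
flip_comparison <- function(cmp, threshold = 2.0) {
  out <- as_tibble(cmp)
  out$fold_change <- 1 / out$fold_change
  keep <- out$enrichment_class == "insufficient-evidence"
  out$enrichment_class <- classify_enrichment(out$fold_change, threshold)
  out$enrichment_class[keep] <- "insufficient-evidence"
  new_complex_comparison(
    out,
    comparison = paste0(attr(cmp, "denominator"), "_vs_", attr(cmp, "numerator")),
    numerator = attr(cmp, "denominator"),
    denominator = attr(cmp, "numerator")
  )
}

#' Derive a third comparison by dividing two shared-denominator comparisons
#'
#' Given normalized ratios EDC/repressed and active/repressed, the
#' repressed-state terms cancel in their quotient, which therefore
#' estimates the EDC/active fold change without the two complexes ever
#' having been mixed. Proteins absent from either input cannot be derived
#' and are listed in the `dropped` attribute.
#'
#' @param num_cmp,den_cmp `complex_comparison` tibbles sharing their
#'   denominator state (e.g. EDC/repressed and active/repressed).
#' @param threshold enrichment threshold for the derived comparison.
#' @return a `complex_comparison` for numerator-state vs denominator-state
#'   (e.g. `edc_vs_active`), with attribute `"dropped"` naming proteins
#'   omitted because they lacked a ratio in one input.
#' @export
ratio_of_ratios <- function(num_cmp, den_cmp, threshold = 2.0) {
  if (!identical(attr(num_cmp, "denominator"), attr(den_cmp, "denominator"))) {
    abort("ratio_of_ratios requires two comparisons with the same denominator state")
  }
  a <- as_tibble(num_cmp) |> filter(!is.na(.data$fold_change))
  b <- as_tibble(den_cmp) |> filter(!is.na(.data$fold_change))
  joined <- inner_join(a, b, by = "protein", suffix = c(".num", ".den"))
  fc <- joined$fold_change.num / joined$fold_change.den
  out <- tibble(
    protein = joined$protein,
    fold_change = fc,
    n_peptides = pmin(joined$n_peptides.num, joined$n_peptides.den),
    enrichment_class = classify_enrichment(fc, threshold)
  )
  dropped <- setdiff(union(num_cmp$protein, den_cmp$protein), out$protein)
  res <- new_complex_comparison(
    out,
    comparison = paste0(attr(num_cmp, "numerator"), "_vs_", attr(den_cmp, "numerator")),
    numerator = attr(num_cmp, "numerator"),
    denominator = attr(den_cmp, "numerator")
  )
  attr(res, "dropped") <- dropped
  res
}

#' Per-complex abundances against a spiked heavy reference
#'
#' In the spiked-reference design each light complex state is mixed with
#' the same heavy reference preparation. A protein's relative abundance in
#' state `s` is its light/heavy ratio in that mixture divided by the
#' anchors' averaged light/heavy ratio in the same mixture, so unequal
#' loading of any one mixture cancels. Fold changes between states are then
#' simple ratios of these abundances.
#'
#' @param peptides peptide table whose `complex_pair` column labels the
#'   light state of each mixture (all sharing the common heavy reference).
#' @param anchor_ids anchor proteins, assumed equimolar in every complex.
#' @param method aggregation method passed to [aggregate_protein_ratios()].
#' @return tibble with columns `protein`, `state`, `abundance`,
#'   `n_peptides`; anchors have abundance (geometric mean) 1 in every
#'   state.
#' @export
reference_channel_abundance <- function(peptides,
                                        anchor_ids = c("CBP20", "CBP80"),
                                        method = "median") {
  pr <- peptide_ratios(peptides)
  prot <- aggregate_protein_ratios(pr$ratios, method = method)
  norm <- anchor_normalize(prot, anchor_ids = anchor_ids)
  norm |>
    transmute(
      protein = .data$protein,
      state = .data$complex_pair,
      abundance = .data$normalized_ratio,
      n_peptides = .data$n_peptides
    )
}

#' Fold change between two states of a reference-abundance table
#'
#' @param abundances tibble from [reference_channel_abundance()].
#' @param numerator,denominator state labels.
#' @param threshold enrichment threshold.
#' @return a `complex_comparison` tibble; proteins quantified in only one
#'   of the two states get class `"insufficient-evidence"`.
#' @export
abundance_fold_change <- function(abundances, numerator, denominator,
                                  threshold = 2.0) {
  a <- filter(abundances, .data$state == numerator)
  b <- filter(abundances, .data$state == denominator)
  joined <- full_join(a, b, by = "protein", suffix = c(".num", ".den"))
  fc <- joined$abundance.num / joined$abundance.den
  cls <- ifelse(is.na(fc), "insufficient-evidence",
                classify_enrichment(pmax(fc, .Machine$double.xmin), threshold))
  res <- tibble(
    protein = joined$protein,
    fold_change = fc,
    n_peptides = pmin(joined$n_peptides.num, joined$n_peptides.den, na.rm = TRUE),
    enrichment_class = cls
  )
  new_complex_comparison(res, paste0(numerator, "_vs_", denominator),
                         numerator, denominator)
}

#' Keep only proteins quantified in both experiments
#'
#' Proteins observed in a single mass-spectrometry experiment are not
#' considered further; this filter retains the intersection of two
#' comparisons' quantified proteins and reports, per retained protein, both
#' fold changes and whether they agree in direction (same side of 1).
#'
#' @param cmp1,cmp2 `complex_comparison` tibbles of the same state
#'   contrast measured in two experiments.
#' @return tibble with columns `protein`, `fold_change_1`, `fold_change_2`,
#'   `agreement` (logical; ties at 1 count as agreeing) and
#'   `fold_change` (geometric mean of the two estimates).
#' @export
consistency_filter <- function(cmp1, cmp2) {
  a <- as_tibble(cmp1) |> filter(!is.na(.data$fold_change))
  b <- as_tibble(cmp2) |> filter(!is.na(.data$fold_change))
  joined <- inner_join(
    select(a, "protein", fold_change_1 = "fold_change"),
    select(b, "protein", fold_change_2 = "fold_change"),
    by = "protein"
  )
  if (nrow(joined) == 0L) {
    warn("no protein was quantified in both experiments; empty result")
  }
  joined |>
    mutate(
      agreement = (.data$fold_change_1 - 1) * (.data$fold_change_2 - 1) >= 0,
      fold_change = sqrt(.data$fold_change_1 * .data$fold_change_2)
    )
}

#' Run the full SILAC quantification pipeline on one peptide table
#'
#' Convenience wrapper: peptide ratios, protein-level aggregation, anchor
#' normalization. Exclusion and drop reports are attached as attributes
#' `"excluded_peptides"` and `"dropped"`.
#'
#' @inheritParams peptide_ratios
#' @inheritParams anchor_normalize
#' @inheritParams aggregate_protein_ratios
#' @return normalized protein ratio tibble (see [anchor_normalize()]).
#' @export
silac_quantify <- function(peptides, anchor_ids = c("CBP20", "CBP80"),
                           method = "median",
                           anchor_average = "geometric") {
  pr <- peptide_ratios(peptides)
  prot <- aggregate_protein_ratios(pr$ratios, method = method)
  norm <- anchor_normalize(prot, anchor_ids = anchor_ids,
                           anchor_average = anchor_average)
  quantified <- paste(norm$protein, norm$complex_pair)
  seen <- unique(tibble(protein = peptides$protein,
                        complex_pair = peptides$complex_pair))
  dropped <- seen[!(paste(seen$protein, seen$complex_pair) %in% quantified), ]
  attr(norm, "excluded_peptides") <- pr$excluded
  attr(norm, "dropped") <- dropped
  norm
}
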