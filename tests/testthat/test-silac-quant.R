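test_that("peptide ratios divide light by heavy and exclude bad channels with reasons", {
  pep <- tibble::tibble(
    peptide = c("a", "b", "c", "d"),
    protein = "P", complex_pair = "cmp",
    intensity_light = c(2000, 1000, 0, NA),
    intensity_heavy = c(1000, 1000, 500, 800)
  )
  pr <- peptide_ratios(pep)
  expect_equal(pr$ratios$ratio, c(2.0, 1.0))
  expect_equal(pr$excluded$reason, c("zero-channel", "missing-channel"))
  expect_error(peptide_ratios(dplyr::mutate(pep, intensity_heavy = -1)),
               "nonnegative")
})

test_that("protein aggregation is the exponentiated median of log2 ratios", {
  agg <- function(r, method = "median") {
    pr <- peptide_ratios(peptides_from_ratios(list(P = r)))
    aggregate_protein_ratios(pr$ratios, method = method)
  }
  expect_equal(agg(c(2, 2, 2))$raw_ratio, 2.0)
  expect_equal(agg(c(1, 2, 4))$raw_ratio, 2.0)   # median of log2 {0,1,2} = 1
  expect_equal(agg(8)$raw_ratio, 8.0)
  expect_equal(agg(c(1, 2, 4))$n_peptides, 3L)
  # the mean option differs when ratios are skewed: mean log2 {0,1,4} = 5/3
  expect_equal(agg(c(1, 2, 16), method = "mean")$raw_ratio, 2^(5 / 3))
  expect_equal(agg(c(1, 2, 16))$raw_ratio, 2.0)
})

test_that("anchor normalization divides by the anchors' geometric mean", {
  tab <- function(r) {
    pr <- peptide_ratios(peptides_from_ratios(r))
    aggregate_protein_ratios(pr$ratios)
  }
  n1 <- anchor_normalize(tab(list(P = 3.0, CBP20 = 1.5, CBP80 = 1.5)))
  expect_equal(n1$normalized_ratio[n1$protein == "P"], 2.0)
  expect_equal(geometric_mean(n1$normalized_ratio[n1$protein != "P"]), 1.0)

  # geometric mean of {1.0, 2.25} is 1.5
  n2 <- anchor_normalize(tab(list(P = 3.0, CBP20 = 1.0, CBP80 = 2.25)))
  expect_equal(n2$normalized_ratio[n2$protein == "P"], 2.0)

  # arithmetic option: mean of {1.0, 2.25} is 1.625
  n3 <- anchor_normalize(tab(list(P = 3.0, CBP20 = 1.0, CBP80 = 2.25)),
                         anchor_average = "arithmetic")
  expect_equal(n3$normalized_ratio[n3$protein == "P"], 3.0 / 1.625)

  expect_error(anchor_normalize(tab(list(P = 3.0, Q = 1.0))), "no anchor")
  expect_warning(anchor_normalize(tab(list(P = 3.0, CBP20 = 1.5))),
                 "single anchor")
})

test_that("anchor geometric mean is exactly 1 after normalization (randomized)", {
  set.seed(42)
  for (i in 1:50) {
    ratios <- as.list(2^runif(6, -3, 3))
    names(ratios) <- c("CBP20", "CBP80", paste0("P", 1:4))
    pr <- peptide_ratios(peptides_from_ratios(ratios))
    norm <- anchor_normalize(aggregate_protein_ratios(pr$ratios))
    gm <- geometric_mean(norm$normalized_ratio[norm$protein %in% c("CBP20", "CBP80")])
    expect_equal(gm, 1.0, tolerance = 1e-12)
  }
})

test_that("direct-mixture fold changes keep orientation and reciprocate on flip", {
  pr <- peptide_ratios(peptides_from_ratios(
    list(P = 4.0, Q = 0.2, CBP20 = 1, CBP80 = 1),
    complex_pair = "active_vs_repressed"
  ))
  norm <- anchor_normalize(aggregate_protein_ratios(pr$ratios))
  cmp <- fold_change(norm, "active_vs_repressed", "active", "repressed",
                     observed_proteins = c("P", "Q", "R"))
  expect_equal(cmp$fold_change[cmp$protein == "P"], 4.0)
  expect_equal(attr(cmp, "numerator"), "active")
  expect_equal(cmp$enrichment_class[cmp$protein == "R"], "insufficient-evidence")

  rev <- flip_comparison(cmp)
  expect_equal(rev$fold_change[rev$protein == "P"], 0.25)
  expect_equal(attr(rev, "numerator"), "repressed")
  expect_equal(rev$enrichment_class[rev$protein == "P"], "depleted")
  expect_equal(rev$enrichment_class[rev$protein == "Q"], "enriched")
  expect_equal(rev$enrichment_class[rev$protein == "R"], "insufficient-evidence")
})

test_that("ratio of ratios cancels the shared denominator state", {
  mk <- function(fc, cp, num) {
    pr <- peptide_ratios(peptides_from_ratios(
      c(fc, list(CBP20 = 1, CBP80 = 1)), complex_pair = cp
    ))
    norm <- anchor_normalize(aggregate_protein_ratios(pr$ratios))
    fold_change(norm, cp, num, "repressed")
  }
  edc <- mk(list(P = 4.0, Q = 2.4, S = 1.0), "edc_vs_repressed", "edc")
  act <- mk(list(P = 1.0, Q = 0.8, R = 2.0), "active_vs_repressed", "active")
  ror <- ratio_of_ratios(edc, act)
  expect_equal(attr(ror, "comparison"), "edc_vs_active")
  expect_equal(ror$fold_change[ror$protein == "P"], 4.0)
  expect_equal(ror$fold_change[ror$protein == "Q"], 3.0)  # 2.4 / 0.8
  expect_setequal(attr(ror, "dropped"), c("R", "S", "CBP20", "CBP80")[
    !c("R", "S", "CBP20", "CBP80") %in% ror$protein])
  # proteins present in only one comparison are omitted, not fabricated
  expect_false("R" %in% ror$protein)

  # cancellation: identical inputs give 1 for any positive ratio
  set.seed(1)
  for (x in 2^runif(20, -5, 5)) {
    one <- mk(list(P = x), "edc_vs_repressed", "edc")
    expect_equal(ratio_of_ratios(one, one)$fold_change[1], 1.0)
  }
  # refuses comparisons that do not share the denominator state
  expect_error(ratio_of_ratios(edc, flip_comparison(act)), "same denominator")
})

test_that("spiked-reference abundances remove state-specific loading inflation", {
  # all proteins at light = heavy, but state s2 loaded 2x: anchors carry the
  # same inflation, so normalized abundances are 1 everywhere
  mk_state <- function(state, load) {
    peptides_from_ratios(
      list(P = rep(load, 3), CBP20 = rep(load, 3), CBP80 = rep(load, 3)),
      complex_pair = state
    )
  }
  pep <- dplyr::bind_rows(mk_state("s1", 1), mk_state("s2", 2))
  ab <- reference_channel_abundance(pep)
  expect_equal(ab$abundance, rep(1.0, nrow(ab)))

  fc <- abundance_fold_change(ab, "s2", "s1")
  expect_equal(fc$fold_change[fc$protein == "P"], 1.0)
})

test_that("noise-free spiked design recovers planted per-state fold changes", {
  cfg <- silac_sim_config(
    fold_changes = list(repressed = c(P = 0.25), active = c(P = 1), edc = c(P = 5)),
    log2_noise_sd = 0,
    mixing_error = c(repressed = 1.3, active = 0.8, edc = 1.1),
    seed = 13
  )
  pep <- generate_silac_experiment(cfg)$peptides
  ab <- reference_channel_abundance(pep)
  fc_ar <- abundance_fold_change(ab, "active", "repressed")
  expect_equal(fc_ar$fold_change[fc_ar$protein == "P"], 4.0)
  fc_ea <- abundance_fold_change(ab, "edc", "active")
  expect_equal(fc_ea$fold_change[fc_ea$protein == "P"], 5.0)
})

test_that("consistency filter keeps the two-experiment intersection and scores agreement", {
  c1 <- fold_change(
    tibble::tibble(protein = c("P", "Q"), complex_pair = "x",
                   normalized_ratio = c(3.1, 0.4), n_peptides = c(3L, 3L)),
    "x", "a", "b"
  )
  c2 <- fold_change(
    tibble::tibble(protein = c("P", "R"), complex_pair = "x",
                   normalized_ratio = c(2.4, 2.0), n_peptides = c(4L, 4L)),
    "x", "a", "b"
  )
  res <- consistency_filter(c1, c2)
  expect_equal(res$protein, "P")
  expect_true(res$agreement)
  expect_equal(res$fold_change, sqrt(3.1 * 2.4))

  c3 <- fold_change(
    tibble::tibble(protein = "P", complex_pair = "x",
                   normalized_ratio = 0.5, n_peptides = 2L),
    "x", "a", "b"
  )
  expect_false(consistency_filter(c1, c3)$agreement)
  c4 <- fold_change(
    tibble::tibble(protein = "Z", complex_pair = "x",
                   normalized_ratio = 1, n_peptides = 1L),
    "x", "a", "b"
  )
  expect_warning(res0 <- consistency_filter(c1, c4), "no protein")
  expect_equal(nrow(res0), 0L)
})

test_that("enrichment classification applies the two-fold rule", {
  expect_equal(classify_enrichment(2.5), "enriched")
  expect_equal(classify_enrichment(1.0), "unchanged")
  expect_equal(classify_enrichment(0.4), "depleted")   # 0.4 < 1/2
  expect_equal(classify_enrichment(2.0), "unchanged")  # strictly greater than
  expect_equal(classify_enrichment(c(3, 0.1), threshold = 4),
               c("unchanged", "depleted"))
  expect_error(classify_enrichment(-1), "positive")
})

test_that("normalized fold changes are invariant to rescaling one channel", {
  cfg <- silac_sim_config(seed = 21, log2_noise_sd = 0.3)
  pep <- generate_silac_experiment(cfg)$peptides
  norm1 <- silac_quantify(pep)
  for (k in c(0.01, 7, 1e4)) {
    scaled <- dplyr::mutate(pep, intensity_light = intensity_light * k)
    norm2 <- silac_quantify(scaled)
    expect_equal(norm2$normalized_ratio, norm1$normalized_ratio)
  }
})

test_that("raising a protein's light intensities never lowers its normalized ratio", {
  cfg <- silac_sim_config(seed = 31)
  pep <- generate_silac_experiment(cfg)$peptides
  base <- silac_quantify(pep)
  target <- "DDX17"
  for (k in c(1.5, 4)) {
    bumped <- dplyr::mutate(pep, intensity_light = ifelse(
      protein == target, intensity_light * k, intensity_light))
    norm <- silac_quantify(bumped)
    expect_true(all(norm$normalized_ratio[norm$protein == target] >=
                      base$normalized_ratio[base$protein == target]))
  }
})
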