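test_that("noise-free generation plants exact peptide ratios and anchors at 1", {
  cfg <- silac_sim_config(
    fold_changes = list(cmp = c(P = 4.0)),
    log2_noise_sd = 0, mixing_error = 1, missing_rate = 0, seed = 11
  )
  sim <- generate_silac_experiment(cfg)
  pep <- sim$peptides
  rp <- pep[pep$protein == "P", ]
  expect_equal(rp$intensity_light / rp$intensity_heavy, rep(4.0, nrow(rp)))
  anch <- pep[pep$protein %in% c("CBP20", "CBP80"), ]
  expect_equal(anch$intensity_light / anch$intensity_heavy, rep(1.0, nrow(anch)))
})

test_that("mixing error shifts anchors and is removed by anchor normalization", {
  cfg <- silac_sim_config(
    fold_changes = list(cmp = c(P = 4.0)),
    log2_noise_sd = 0, mixing_error = 1.2, seed = 3
  )
  sim <- generate_silac_experiment(cfg)
  anch <- sim$peptides[sim$peptides$protein %in% c("CBP20", "CBP80"), ]
  expect_equal(anch$intensity_light / anch$intensity_heavy,
               rep(1.2, nrow(anch)))
  # raw protein ratio is 4.8 = 4.0 x 1.2; normalization restores 4.0
  norm <- silac_quantify(sim$peptides)
  expect_equal(norm$raw_ratio[norm$protein == "P"], 4.8)
  expect_equal(norm$normalized_ratio[norm$protein == "P"], 4.0)
})

test_that("generation is deterministic for identical config and seed", {
  cfg <- silac_sim_config(seed = 7, missing_rate = 0.2)
  expect_identical(generate_silac_experiment(cfg),
                   generate_silac_experiment(cfg))
  sc <- generate_spectral_counts(30, seed = 7)
  expect_identical(sc, generate_spectral_counts(30, seed = 7))
  ec <- exon_sim_config(n_exons = 10, seed = 7)
  a <- generate_exon_cohort(ec)
  b <- generate_exon_cohort(ec)
  expect_identical(a$exons, b$exons)
  expect_identical(a$clusters, b$clusters)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
})

test_that("missingness marks one channel absent, never both", {
  cfg <- silac_sim_config(missing_rate = 0.4, seed = 5)
  pep <- generate_silac_experiment(cfg)$peptides
  expect_gt(sum(is.na(pep$intensity_light) | is.na(pep$intensity_heavy)), 0)
  expect_false(any(is.na(pep$intensity_light) & is.na(pep$intensity_heavy)))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(silac_sim_config(missing_rate = 1), "missing_rate")
  expect_error(silac_sim_config(mixing_error = 0), "mixing_error")
  expect_error(silac_sim_config(log2_noise_sd = -1), "log2_noise_sd")
  expect_error(
    silac_sim_config(fold_changes = list(cmp = c(P = -2))),
    "strictly positive"
  )
  expect_error(
    silac_sim_config(fold_changes = list(cmp = c(CBP20 = 2))),
    "anchor"
  )
  expect_error(generate_spectral_counts(0), "n_proteins")
})

test_that("planted architectures give the planted distal-only fraction by construction", {
  co <- generate_exon_cohort(exon_sim_config(
    n_exons = 10, zone_probabilities = c(a_d = 1), seed = 2
  ))
  asg <- classify_clusters(co$clusters, co$exons)
  summ <- cohort_summary(summarize_exons(asg, exon_ids = co$exons$exon_id))
  expect_equal(summ$distal_only_count, 10L)
  expect_equal(summ$distal_only_pct, 100)

  co2 <- generate_exon_cohort(exon_sim_config(
    n_exons = 10,
    zone_probabilities = c(a_only = 2, a_d = 4, b = 2, mixed = 2) / 10,
    seed = 2
  ))
  expect_equal(sum(co2$truth$exons$distal_only), 6L)
  asg2 <- classify_clusters(co2$clusters, co2$exons)
  summ2 <- cohort_summary(summarize_exons(asg2, exon_ids = co2$exons$exon_id))
  expect_equal(summ2$distal_only_pct, 60)
})

test_that("each upstream intron carries the planted branch point at the recorded offset", {
  co <- generate_exon_cohort(exon_sim_config(n_exons = 25, seed = 9))
  for (i in seq_len(nrow(co$exons))) {
    bps <- predict_bps(co$exons$up_intron_seq[i])
    expect_equal(bps$offset_3ss, co$truth$exons$bps_offset[i])
  }
})

test_that("geometrically infeasible cohort configurations fail up front", {
  expect_error(exon_sim_config(intron_length = c(50L, 800L)), "intron too short")
  expect_error(exon_sim_config(bps_offset = c(22L, 95L)), "search window")
})
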