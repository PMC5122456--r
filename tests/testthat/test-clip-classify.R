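test_that("derepressed-exon selection applies the inclusive delta-PSI rule and requires clusters", {
  exons <- dplyr::bind_rows(
    make_test_exon(exon_id = "e1", delta_psi = 20),
    make_test_exon(exon_id = "e2", delta_psi = 15),
    make_test_exon(exon_id = "e3", delta_psi = 30),
    make_test_exon(exon_id = "e4", delta_psi = 10),
    make_test_exon(exon_id = "e5", delta_psi = NA)
  )
  clusters <- dplyr::bind_rows(
    cluster_at_d3(exons[1, ], 150, id = "c1"),
    cluster_at_d3(exons[1, ], 160, id = "c2"),
    cluster_at_d3(exons[2, ], 150, id = "c3"),
    cluster_at_d3(exons[4, ], 150, id = "c4"),
    cluster_at_d3(exons[5, ], 150, id = "c5")
  )
  kept <- select_derepressed(exons, clusters, psi_threshold = 15)
  expect_setequal(kept$exon_id, c("e1", "e2"))
  excl <- attr(kept, "excluded")
  expect_equal(excl$reason[excl$exon_id == "e3"], "no-clusters")
  expect_equal(excl$reason[excl$exon_id == "e4"], "below-threshold")
  expect_equal(excl$reason[excl$exon_id == "e5"], "missing-delta-psi")
})

test_that("branch point prediction finds a planted consensus and breaks ties toward the 3'ss", {
  exon <- make_test_exon(bps_offset = 30L)
  bps <- predict_bps(exon$up_intron_seq)
  expect_equal(bps$offset_3ss, 30L)
  n <- nchar(exon$up_intron_seq)
  expect_equal(substr(exon$up_intron_seq, bps$pos, bps$pos), "A")

  # two identical consensus matches at -60 and -30: the -30 one wins
  bg <- strsplit(exon$up_intron_seq, "")[[1]]
  i60 <- n - 1L - 60L
  bg[(i60 - 3L):(i60 + 1L)] <- c("C", "T", "C", "A", "G")
  two <- paste(bg, collapse = "")
  expect_equal(predict_bps(two)$offset_3ss, 30L)

  expect_error(predict_bps(strrep("G", 120)), "no candidate branch point")
  expect_warning(
    short <- predict_bps(paste0(strrep("C", 40), "CTCAG", strrep("CT", 8), "AG")),
    "truncated"
  )
  expect_equal(substr(paste0(strrep("C", 40), "CTCAG", strrep("CT", 8), "AG"),
                      short$pos, short$pos), "A")
})

test_that("zone rules assign a, b, c, d from midpoint geometry", {
  exon <- make_test_exon(bps_offset = 28L)
  cl <- function(d3, id) cluster_at_d3(exon, d3, id = id)
  mid_exon <- make_cluster(exon, exon$exon_start + 50L, id = "cx")
  down <- make_cluster(exon, exon$exon_end + 10L, id = "cd")
  clusters <- dplyr::bind_rows(cl(150, "c150"), mid_exon, cl(40, "c40"),
                               cl(90, "c90"), down)
  asg <- classify_clusters(clusters, exon)
  zones <- setNames(asg$zone, asg$cluster_id)
  expect_equal(zones[["c150"]], "a")  # 150 > 100 from the 3'ss
  expect_equal(zones[["cx"]], "c")    # inside the exon
  expect_equal(zones[["c40"]], "b")   # 40 - 28 = 12 <= 25 from the BPS
  expect_equal(zones[["c90"]], "a")   # 90 - 28 = 62 > 25 from the BPS
  expect_equal(zones[["cd"]], "d")    # downstream of the 5'ss
  expect_false(any(asg$bps_degraded))
})

test_that("labels change exactly at the 100-nt, 25-nt and exon boundaries", {
  # branch point at -30: within the proximal window the a/b switch is at
  # 30 + 25 = 55 nt from the 3'ss
  exon <- make_test_exon(bps_offset = 30L)
  sweep <- function(exon, d3s) {
    cls <- dplyr::bind_rows(lapply(d3s, function(d) {
      cluster_at_d3(exon, d, width = 1L, id = paste0("s", d))
    }))
    classify_clusters(cls, exon)$zone
  }
  d3s <- c(103:101, 100, 57, 56, 55, 54, 1)
  expect_equal(sweep(exon, d3s),
               c("a", "a", "a", "a", "a", "a", "b", "b", "b"))

  # branch point at -80 exposes the 100-nt boundary itself: 101 is distal
  # by rule 'a', 100 falls within 25 nt of the BPS and becomes 'b'
  exon80 <- make_test_exon(bps_offset = 80L)
  expect_equal(sweep(exon80, c(101, 100)), c("a", "b"))
  # inclusive boundary reading flips only the threshold cases
  cls <- dplyr::bind_rows(lapply(c(101, 100), function(d) {
    cluster_at_d3(exon80, d, width = 1L, id = paste0("s", d))
  }))
  expect_equal(classify_clusters(cls, exon80, strict = FALSE)$zone, c("a", "a"))

  # exon and 5'ss boundaries
  edge <- dplyr::bind_rows(
    make_cluster(exon, exon$exon_start - 1L, width = 1L, id = "lastI"),
    make_cluster(exon, exon$exon_start, width = 1L, id = "firstE"),
    make_cluster(exon, exon$exon_end - 1L, width = 1L, id = "lastE"),
    make_cluster(exon, exon$exon_end, width = 1L, id = "firstD")
  )
  expect_equal(classify_clusters(edge, exon)$zone, c("b", "c", "c", "d"))
})

test_that("branch point failure in the proximal window degrades to 'b' with a flag", {
  exon <- make_test_exon()
  exon$up_intron_seq <- strrep("G", nchar(exon$up_intron_seq))
  prox <- cluster_at_d3(exon, 40, id = "p")
  dist <- cluster_at_d3(exon, 150, id = "q")
  asg <- classify_clusters(dplyr::bind_rows(prox, dist), exon)
  expect_equal(asg$zone, c("b", "a"))
  expect_equal(asg$bps_degraded, c(TRUE, FALSE)) # distal call needs no BPS
})

test_that("overlap mode resolves straddling clusters by precedence c > b > d > a", {
  exon <- make_test_exon()
  straddle <- tibble::tibble(
    cluster_id = "s", exon_id = exon$exon_id, chrom = exon$chrom,
    strand = "+", start = exon$exon_start - 6L, end = exon$exon_start + 5L
  )
  # midpoint rounds toward the 3'ss and lands in the intron -> b
  expect_equal(classify_clusters(straddle, exon)$zone, "b")
  # overlap mode sees exonic bases and prefers c
  expect_equal(classify_clusters(straddle, exon, position = "overlap")$zone, "c")
})

test_that("cluster association errors are raised, not guessed around", {
  exon <- make_test_exon()
  bad_exon <- cluster_at_d3(exon, 50, id = "x")
  bad_exon$exon_id <- "nope"
  expect_error(classify_clusters(bad_exon, exon), "unknown exon")
  bad_chrom <- cluster_at_d3(exon, 50, id = "x")
  bad_chrom$chrom <- "other"
  expect_error(classify_clusters(bad_chrom, exon), "chrom/strand")
  outside <- tibble::tibble(
    cluster_id = "x", exon_id = exon$exon_id, chrom = exon$chrom,
    strand = "+", start = exon$down_intron_end + 100L,
    end = exon$down_intron_end + 120L
  )
  expect_error(classify_clusters(outside, exon), "does not overlap")
})

test_that("zone labels are invariant under reverse-complementing the cohort", {
  co <- generate_exon_cohort(exon_sim_config(n_exons = 30, seed = 17))
  plus <- classify_clusters(co$clusters, co$exons)
  fl <- flip_exon_cohort(co)
  minus <- classify_clusters(fl$clusters, fl$exons)
  expect_equal(minus$zone, plus$zone[match(minus$cluster_id, plus$cluster_id)])
  # and sequences extracted from the flipped FASTA match the stored ones
  re_ex <- add_intron_sequences(
    dplyr::select(fl$exons, -"up_intron_seq"), fl$sequences
  )
  expect_equal(re_ex$up_intron_seq, fl$exons$up_intron_seq)
})

test_that("binding architectures are a pure function of the label multiset", {
  s <- function(zones) {
    asg <- tibble::tibble(exon_id = "e", zone = zones)
    summarize_exons(asg, exon_ids = "e")
  }
  both <- s(c("a", "d"))
  expect_equal(both$architecture, "distal-only")
  expect_true(both$both_sides)
  expect_equal(s(c("a", "b"))$architecture, "contains-b")
  expect_equal(s(c("c", "d"))$architecture, "contains-c")
  expect_equal(s(c("b", "c"))$architecture, "mixed")
  expect_equal(s(character(0))$architecture, "unbound")
  expect_false(s(character(0))$distal_only)
})

test_that("cohort summaries count every exon exactly once", {
  co <- generate_exon_cohort(exon_sim_config(
    n_exons = 10,
    zone_probabilities = c(a_d = 6, b = 2, c = 2) / 10, seed = 5
  ))
  asg <- classify_clusters(co$clusters, co$exons)
  summ <- cohort_summary(summarize_exons(asg, exon_ids = co$exons$exon_id))
  expect_equal(sum(summ$counts), 10L)
  expect_equal(summ$distal_only_pct, 60)
  expect_error(cohort_summary(summarize_exons(asg, exon_ids = character(0))),
               "empty cohort")
})
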