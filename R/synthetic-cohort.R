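#' Configuration for a synthetic exon/cluster cohort
#'
#' Describes a cohort of cassette exons with flanking introns on synthetic
#' single-gene loci, with CLIP clusters planted in known positional zones
#' and a branch-point consensus planted at a known offset in each upstream
#' intron's 3' end. Architecture counts are apportioned deterministically
#' (largest remainder) so planted fractions are exact by construction.
#'
#' @param n_exons cohort size. The default cohort of 95 exons mirrors a
#'   genome-wide set of regulator-repressed exons.
#' @param zone_probabilities named numeric vector over the architecture
#'   classes `a_only` (\{a\}), `d_only` (\{d\}), `a_d` (\{a, d\}), `b`
#'   (\{a, b\}), `c` (\{c, d\}), `mixed` (\{a, b, c, d\}); normalized to
#'   sum to 1. The default plants 56/95 distal-only exons (59%), most of
#'   them bound on both sides, and no exon-only or 3'ss-only architecture.
#' @param intron_length,exon_length,cluster_width integer ranges
#'   `c(min, max)` in nt.
#' @param bps_offset range of the planted branch adenosine's offset
#'   upstream of the 3'ss AG first base (exclusive), in nt.
#' @param delta_psi_range range of planted delta-PSI values (percentage
#'   points of increased inclusion upon regulator depletion).
#' @param seed RNG seed.
#' @return an object of class `exon_sim_config`.
#' @export
exon_sim_config <- function(n_exons = 95L,
                            zone_probabilities = c(
                              a_only = 11, d_only = 9, a_d = 36,
                              b = 20, c = 9, mixed = 10
                            ) / 95,
                            intron_length = c(300L, 800L),
                            exon_length = c(60L, 150L),
                            bps_offset = c(22L, 38L),
                            cluster_width = c(10L, 30L),
                            delta_psi_range = c(15, 90),
                            seed = 1L) {
  check_scalar(n_exons, "n_exons", lower = 1, integerish = TRUE)
  allowed <- c("a_only", "d_only", "a_d", "b", "c", "mixed")
  if (is.null(names(zone_probabilities)) ||
      !all(names(zone_probabilities) %in% allowed)) {
    abort(paste0("configuration error: `zone_probabilities` names must be among: ",
                 paste(allowed, collapse = ", ")))
  }
  if (any(zone_probabilities < 0) || sum(zone_probabilities) <= 0) {
    abort("configuration error: `zone_probabilities` must be nonnegative and sum > 0")
  }
  zone_probabilities <- zone_probabilities / sum(zone_probabilities)
  check_range2(intron_length, "intron_length", lower = 1)
  check_range2(exon_length, "exon_length", lower = 1)
  check_range2(bps_offset, "bps_offset", lower = 5)
  check_range2(cluster_width, "cluster_width", lower = 1)
  check_range2(delta_psi_range, "delta_psi_range", integerish = FALSE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (bps_offset[2] > 90) {
    abort("generation error: `bps_offset` must stay within the 100-nt branch point search window")
  }
  if (exon_length[1] < 12) {
    abort("generation error: exons shorter than 12 nt cannot hold an interior cluster midpoint")
  }
  min_needed <- 106L + cluster_width[2] + 10L
  if (intron_length[1] < min_needed) {
    abort(sprintf(
      "generation error: intron too short for requested offsets (min intron length %d < %d needed for a distal zone)",
      intron_length[1], min_needed
    ))
  }
  structure(
    list(
      n_exons = as.integer(n_exons),
      zone_probabilities = zone_probabilities,
      intron_length = as.integer(intron_length),
      exon_length = as.integer(exon_length),
      bps_offset = as.integer(bps_offset),
      cluster_width = as.integer(cluster_width),
      delta_psi_range = delta_psi_range,
      seed = as.integer(seed)
    ),
    class = "exon_sim_config"
  )
}

architecture_labels <- function(arch) {
  switch(arch,
    a_only = "a", d_only = "d", a_d = c("a", "d"),
    b = c("a", "b"), c = c("c", "d"), mixed = c("a", "b", "c", "d"),
    abort(sprintf("unknown architecture '%s'", arch))
  )
}

## upstream-intron sense sequence of length n with the branch consensus
## CTCAG planted so its A sits `offset` nt upstream of the AG first base,
## a pyrimidine (C/T) tract between branch point and AG, and the terminal AG
plant_intron_3p <- function(n, offset) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  s[n - 1L] <- "A"; s[n] <- "G"
  i_b <- n - 1L - offset
  s[(i_b - 3L):(i_b + 1L)] <- c("C", "T", "C", "A", "G")
  py <- seq(i_b + 2L, n - 2L)
  if (length(py)) s[py] <- sample(c("C", "T"), length(py), replace = TRUE)
  s
}

## interval of width w centred (3'ss-rounded) on midpoint m, clamped to locus
cluster_interval <- function(m, w, locus_len) {
  start <- m - (w - 1L) %/% 2L
  start <- max(0L, min(start, locus_len - w))
  c(start, start + w)
}

#' Generate a synthetic exon cohort with planted binding architectures
#'
#' Builds one synthetic gene locus per exon (upstream intron, cassette
#' exon, downstream intron on the plus strand; see [flip_exon_cohort()]
#' for minus-strand fixtures), plants a branch-point consensus at a
#' recorded offset in each upstream intron's 3' end, and places one CLIP
#' cluster per zone of the exon's assigned architecture. Cluster midpoints
#' are kept at least 5 nt inside their intended zone so rule testing is
#' separated from boundary tie-breaking.
#'
#' @param config an [exon_sim_config()].
#' @return list with
#'   \describe{
#'     \item{exons}{exon-model tibble (`exon_id`, `chrom`, `strand`,
#'       exon/intron intervals, `up_intron_seq`, `delta_psi`).}
#'     \item{clusters}{cluster tibble (`cluster_id`, `exon_id`, `chrom`,
#'       `strand`, `start`, `end`).}
#'     \item{sequences}{[Biostrings::DNAStringSet] of full locus
#'       sequences, named by chromosome.}
#'     \item{truth}{list of tibbles `exons` (architecture, distal-only
#'       flag, planted BPS offset) and `clusters` (true zone per
#'       cluster).}
#'   }
#' @export
generate_exon_cohort <- function(config = exon_sim_config()) {
  if (!inherits(config, "exon_sim_config")) {
    abort("`config` must be created with exon_sim_config()")
  }
  with_seed(config$seed, {
    n <- config$n_exons
    counts <- apportion(n, config$zone_probabilities)
    archs <- sample(rep(names(counts), counts))

    exon_rows <- vector("list", n)
    cluster_rows <- vector("list", n)
    seqs <- character(n)
    chroms <- sprintf("gene_%03d", seq_len(n))
    exon_ids <- sprintf("exon_%03d", seq_len(n))

    for (i in seq_len(n)) {
      ui <- sample_range(config$intron_length)
      ex <- sample_range(config$exon_length)
      di <- sample_range(config$intron_length)
      off <- sample_range(config$bps_offset)
      L <- ui + ex + di
      exon_start <- ui
      exon_end <- ui + ex

      locus <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      locus[seq_len(ui)] <- plant_intron_3p(ui, off)
      seqs[i] <- paste(locus, collapse = "")

      labels <- architecture_labels(archs[i])
      ws <- sample_range(config$cluster_width, length(labels))
      cl <- vector("list", length(labels))
      for (j in seq_along(labels)) {
        w <- ws[j]
        m <- switch(labels[j],
          a = {
            d3 <- sample_range(c(106L, ui - w - 5L))
            (exon_start - 2L) - d3
          },
          b = {
            lo <- max(3L, off - 20L)
            hi <- min(95L, off + 18L)
            d3 <- sample_range(c(lo, hi))
            (exon_start - 2L) - d3
          },
          c = sample_range(c(exon_start + 5L, exon_end - 6L)),
          d = sample_range(c(exon_end + 5L, L - w - 5L))
        )
        iv <- cluster_interval(m, w, L)
        cl[[j]] <- tibble(
          cluster_id = sprintf("%s_cl%d", exon_ids[i], j),
          exon_id = exon_ids[i],
          chrom = chroms[i], strand = "+",
          start = iv[1], end = iv[2],
          true_zone = labels[j]
        )
      }
      cluster_rows[[i]] <- bind_rows(cl)
      exon_rows[[i]] <- tibble(
        exon_id = exon_ids[i], chrom = chroms[i], strand = "+",
        exon_start = exon_start, exon_end = exon_end,
        up_intron_start = 0L, up_intron_end = exon_start,
        down_intron_start = exon_end, down_intron_end = L,
        up_intron_seq = substr(seqs[i], 1L, ui),
        bps_offset = off,
        architecture = archs[i]
      )
    }

    exons <- bind_rows(exon_rows)
    exons$delta_psi <- round(runif(n, config$delta_psi_range[1],
                                   config$delta_psi_range[2]), 1)
    clusters_full <- bind_rows(cluster_rows)
    truth <- list(
      exons = tibble(
        exon_id = exons$exon_id,
        architecture = exons$architecture,
        distal_only = exons$architecture %in% c("a_only", "d_only", "a_d"),
        bps_offset = exons$bps_offset,
        delta_psi = exons$delta_psi
      ),
      clusters = select(clusters_full, "cluster_id", "exon_id", zone = "true_zone")
    )
    exons$bps_offset <- NULL
    exons$architecture <- NULL
    list(
      exons = exons,
      clusters = select(clusters_full, -"true_zone"),
      sequences = Biostrings::DNAStringSet(stats::setNames(seqs, chroms)),
      truth = truth
    )
  })
}

#' Mirror a cohort onto the minus strand
#'
#' Reverse-complements every locus and mirrors all coordinates
#' (`pos' = L - pos`, intervals swapped), flipping the strand to `-`.
#' Zone labels are invariant under this transformation, which is the basis
#' of the strand-symmetry tests. Sense-strand sequences such as
#' `up_intron_seq` are unchanged because they are already strand-relative.
#'
#' @param cohort a cohort list from [generate_exon_cohort()].
#' @return a cohort list of the same shape on the minus strand.
#' @export
flip_exon_cohort <- function(cohort) {
  lens <- stats::setNames(Biostrings::width(cohort$sequences),
                          names(cohort$sequences))
  mirror <- function(start, end, L) {
    new_start <- L - end
    new_end <- L - start
    list(start = new_start, end = new_end)
  }
  ex <- cohort$exons
  L <- unname(lens[ex$chrom])
  m_ex <- mirror(ex$exon_start, ex$exon_end, L)
  m_ui <- mirror(ex$up_intron_start, ex$up_intron_end, L)
  m_di <- mirror(ex$down_intron_start, ex$down_intron_end, L)
  ex$exon_start <- m_ex$start; ex$exon_end <- m_ex$end
  ex$up_intron_start <- m_ui$start; ex$up_intron_end <- m_ui$end
  ex$down_intron_start <- m_di$start; ex$down_intron_end <- m_di$end
  ex$strand <- "-"

  cl <- cohort$clusters
  Lc <- unname(lens[cl$chrom])
  m_cl <- mirror(cl$start, cl$end, Lc)
  cl$start <- m_cl$start; cl$end <- m_cl$end
  cl$strand <- "-"

  list(
    exons = ex,
    clusters = cl,
    sequences = Biostrings::reverseComplement(cohort$sequences),
    truth = cohort$truth
  )
}
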