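#' Default branch-point position weight matrix
#'
#' A 5-position probability matrix for the mammalian branch point sequence,
#' anchored on the pyrimidine-rich consensus (yUnAy family) with the
#' canonical instance `cucAg`; the branch adenosine sits at position 4.
#' Columns are motif positions, rows are `A`, `C`, `G`, `T`. Scores are
#' log2 odds against a uniform background. The matrix is data: supply your
#' own to [predict_bps()] to change the model.
#'
#' @return a 4 x 5 numeric probability matrix (columns sum to 1).
#' @export
default_bps_pwm <- function() {
  m <- matrix(
    c(0.08, 0.42, 0.08, 0.42,   # y
      0.08, 0.17, 0.08, 0.67,   # U
      0.15, 0.40, 0.15, 0.30,   # n (slight C bias)
      0.94, 0.02, 0.02, 0.02,   # branch A
      0.10, 0.25, 0.40, 0.25),  # g in the cucAg instance
    nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL)
  )
  m
}

#' Predict the branch point in the 3' end of an intron
#'
#' Scans the final `window` nucleotides of an upstream intron (excluding
#' the last `exclude_3p` bases — the terminal AG and the base before it)
#' for the adenosine-centred candidate maximizing the position-weight
#' -matrix score. The branch adenosine occupies position 4 of the 5-nt
#' motif. Ties are broken toward the 3' splice site, where mammalian
#' branch points usually sit.
#'
#' @param seq character scalar: the 3'-terminal sequence of the upstream
#'   intron on the transcribed strand, ending at the intron's last base
#'   (the G of the terminal AG).
#' @param window search window size in nt (default 100).
#' @param pwm 4 x 5 probability matrix with rows A, C, G, T; see
#'   [default_bps_pwm()].
#' @param exclude_3p number of intron-terminal bases excluded from the
#'   search (default 3).
#' @return list with `pos` (1-based index of the branch adenosine within
#'   `seq`), `offset_3ss` (nt upstream of the first base of the terminal
#'   AG, exclusive), `score` (log2-odds), and `window` (the searched index
#'   range).
#' @export
predict_bps <- function(seq, window = 100L, pwm = default_bps_pwm(),
                        exclude_3p = 3L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort("`seq` must be a single nucleotide string")
  }
  bases <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  n <- length(bases)
  if (n < exclude_3p + 5L) abort("sequence too short for branch point search")
  win_end <- n - exclude_3p
  win_start <- win_end - window + 1L
  if (win_start < 1L) {
    warn(sprintf(
      "sequence (%d nt) shorter than search window (%d nt); window truncated",
      n, window + exclude_3p
    ))
    win_start <- 1L
  }
  cand <- which(bases == "A")
  cand <- cand[cand >= win_start & cand <= win_end & cand >= 4L & cand <= n - 1L]
  if (length(cand) == 0L) abort("no candidate branch point: no adenosine in search window")

  lod <- log2(pwm / 0.25)
  scores <- vapply(cand, function(i) {
    pent <- match(bases[(i - 3L):(i + 1L)], rownames(lod))
    if (anyNA(pent)) return(-Inf)
    sum(lod[cbind(pent, 1:5)])
  }, numeric(1))
  if (all(!is.finite(scores))) abort("no candidate branch point: ambiguous bases in all candidate motifs")
  best <- max(scores)
  ## tie-break toward the 3' splice site = largest index
  i <- max(cand[scores == best])
  list(
    pos = i,
    offset_3ss = (n - 1L) - i,
    score = best,
    window = c(win_start, win_end)
  )
}

## genomic coordinate (0-based) of the first base of the upstream intron's
## terminal AG, on the transcribed strand
three_prime_ss_pos <- function(exons) {
  ifelse(exons$strand == "+", exons$exon_start - 2L, exons$exon_end + 1L)
}

## distance from `pos` to `ref`, counted upstream along the transcribed
## strand (positive = pos is upstream of ref), exclusive
upstream_dist <- function(pos, ref, strand) {
  ifelse(strand == "+", ref - pos, pos - ref)
}

#' Midpoint of a cluster interval, rounded toward the 3' splice site
#'
#' For odd-length intervals the midpoint is unique; for even lengths the
#' more 3'ss-proximal of the two central bases is taken, so the decision
#' point is deterministic.
#'
#' @param start,end 0-based half-open interval.
#' @param tss3 genomic position of the exon's 3'ss AG first base.
#' @return 0-based genomic position of the midpoint base.
#' @export
cluster_midpoint <- function(start, end, tss3) {
  len <- end - start
  if (any(len < 1L)) abort("cluster interval length must be >= 1")
  lo <- start + (len - 1L) %/% 2L
  hi <- start + len %/% 2L
  ifelse(abs(hi - tss3) < abs(lo - tss3), hi, lo)
}

## zone of a single genomic position relative to one exon model
position_zone <- function(pos, exon, bps_offset_3ss, strict = TRUE,
                          prox_window = 100L, bps_margin = 25L) {
  gt <- if (strict) `>` else `>=`
  if (pos >= exon$exon_start && pos < exon$exon_end) return("c")
  downstream <- if (exon$strand == "+") pos >= exon$exon_end else pos < exon$exon_start
  if (downstream) return("d")
  tss3 <- three_prime_ss_pos(exon)
  d3 <- upstream_dist(pos, tss3, exon$strand)
  if (gt(d3, prox_window)) return("a")
  if (is.na(bps_offset_3ss)) return(NA_character_) # BPS needed but unavailable
  b <- if (exon$strand == "+") tss3 - bps_offset_3ss else tss3 + bps_offset_3ss
  dbps <- upstream_dist(pos, b, exon$strand)
  if (gt(dbps, bps_margin)) "a" else "b"
}

#' Assign iCLIP clusters to positional zones around repressed exons
#'
#' Implements the positional rules for regulator binding sites around a
#' cassette exon. Zones: `a` = distal upstream intron, `b` = branch
#' point / polypyrimidine region, `c` = exon, `d` = downstream intron.
#' Decision sequence per cluster (midpoint mode, the default): midpoint in
#' the exon gives `c`; downstream of the 5'ss gives `d`; more than
#' `prox_window` nt upstream of the 3'ss AG gives `a`; otherwise the
#' upstream intron's branch point is predicted and the cluster is `a` when
#' more than `bps_margin` nt upstream of the branch adenosine, else `b`.
#' When branch-point prediction fails in the proximal region the cluster
#' is conservatively labelled `b` and flagged (`bps_degraded`), so distal-
#' only architectures are never overcalled.
#'
#' @param clusters tibble with columns `cluster_id`, `exon_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @param exons exon-model tibble with columns `exon_id`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`, `up_intron_start`,
#'   `up_intron_end`, `down_intron_start`, `down_intron_end`,
#'   `up_intron_seq` (3'-terminal upstream-intron sequence, transcribed
#'   strand).
#' @param prox_window proximal window: clusters more than this many nt
#'   upstream of the 3'ss AG are distal (default 100).
#' @param bps_margin clusters more than this many nt upstream of the
#'   predicted branch adenosine are distal (default 25).
#' @param strict use strict ">" at both thresholds (the default, matching
#'   "more than"); `FALSE` uses ">=".
#' @param position `"midpoint"` (default) applies the rules to the cluster
#'   midpoint; `"overlap"` labels every base of the cluster and resolves
#'   multiple zones by the precedence c > b > d > a (sensitivity-analysis
#'   mode).
#' @param window,pwm branch-point search parameters, see [predict_bps()].
#' @return tibble with columns `cluster_id`, `exon_id`, `zone`,
#'   `midpoint`, `dist_3ss` (nt upstream of the 3'ss AG; negative when the
#'   midpoint is at/after it), `bps_offset_3ss`, `bps_score`,
#'   `bps_degraded`. One branch point is predicted per exon and shared by
#'   its proximal clusters.
#' @export
classify_clusters <- function(clusters, exons,
                              prox_window = 100L, bps_margin = 25L,
                              strict = TRUE,
                              position = c("midpoint", "overlap"),
                              window = 100L, pwm = default_bps_pwm()) {
  position <- match.arg(position)
  required <- c("cluster_id", "exon_id", "chrom", "strand", "start", "end")
  if (!all(required %in% names(clusters))) {
    abort(paste0("cluster table needs columns: ", paste(required, collapse = ", ")))
  }
  exon_idx <- match(clusters$exon_id, exons$exon_id)
  if (anyNA(exon_idx)) {
    abort(paste0("association error: cluster(s) refer to unknown exon(s): ",
                 paste(unique(clusters$exon_id[is.na(exon_idx)]), collapse = ", ")))
  }

  bps_cache <- new.env(parent = emptyenv())
  exon_bps <- function(exon) {
    key <- exon$exon_id
    if (!is.null(bps_cache[[key]])) return(bps_cache[[key]])
    res <- tryCatch(
      predict_bps(exon$up_intron_seq, window = window, pwm = pwm),
      error = function(e) list(pos = NA_integer_, offset_3ss = NA_integer_,
                               score = NA_real_, failed = conditionMessage(e))
    )
    bps_cache[[key]] <- res
    res
  }

  out <- vector("list", nrow(clusters))
  for (k in seq_len(nrow(clusters))) {
    cl <- clusters[k, ]
    exon <- exons[exon_idx[k], ]
    if (cl$chrom != exon$chrom || cl$strand != exon$strand) {
      abort(sprintf(
        "association error: cluster %s does not match exon %s chrom/strand",
        cl$cluster_id, exon$exon_id
      ))
    }
    locus_lo <- min(exon$up_intron_start, exon$down_intron_start, exon$exon_start)
    locus_hi <- max(exon$up_intron_end, exon$down_intron_end, exon$exon_end)
    if (cl$end <= locus_lo || cl$start >= locus_hi) {
      abort(sprintf("association error: cluster %s does not overlap the locus of exon %s",
                    cl$cluster_id, exon$exon_id))
    }
    tss3 <- three_prime_ss_pos(exon)
    mid <- cluster_midpoint(cl$start, cl$end, tss3)

    zone_at <- function(pos) {
      z <- position_zone(pos, exon, NA_integer_, strict = strict,
                         prox_window = prox_window, bps_margin = bps_margin)
      bps_off <- NA_integer_; bps_score <- NA_real_; degraded <- FALSE
      if (is.na(z)) { # proximal: branch point required
        bps <- exon_bps(exon)
        if (is.na(bps$offset_3ss)) {
          z <- "b"; degraded <- TRUE
        } else {
          bps_off <- bps$offset_3ss; bps_score <- bps$score
          z <- position_zone(pos, exon, bps_off, strict = strict,
                             prox_window = prox_window, bps_margin = bps_margin)
        }
      }
      list(zone = z, bps_offset_3ss = bps_off, bps_score = bps_score,
           degraded = degraded)
    }

    if (position == "midpoint") {
      res <- zone_at(mid)
    } else {
      per_base <- lapply(seq(cl$start, cl$end - 1L), zone_at)
      zones <- vapply(per_base, `[[`, character(1), "zone")
      pick <- intersect(c("c", "b", "d", "a"), zones)[1]
      res <- per_base[[match(pick, zones)]]
    }
    out[[k]] <- tibble(
      cluster_id = cl$cluster_id,
      exon_id = exon$exon_id,
      zone = res$zone,
      midpoint = mid,
      dist_3ss = upstream_dist(mid, tss3, exon$strand),
      bps_offset_3ss = res$bps_offset_3ss,
      bps_score = res$bps_score,
      bps_degraded = res$degraded
    )
  }
  bind_rows(out)
}

#' Select derepressed exons with nearby regulator clusters
#'
#' Keeps exons whose splicing increases by at least `psi_threshold`
#' percentage points upon regulator depletion (delta-PSI, inclusive
#' boundary) and that carry at least one associated CLIP cluster. Exons
#' excluded for any reason are reported, not silently dropped.
#'
#' @param exons exon-model tibble with a `delta_psi` column (percentage
#'   points).
#' @param clusters cluster tibble with an `exon_id` column.
#' @param psi_threshold minimum delta-PSI in percentage points (default 15).
#' @return the retained subset of `exons`; attribute `"excluded"` is a
#'   tibble of (exon_id, reason) with reasons `"missing-delta-psi"`,
#'   `"below-threshold"` or `"no-clusters"`.
#' @export
select_derepressed <- function(exons, clusters, psi_threshold = 15) {
  n_cl <- table(clusters$exon_id)
  has_cl <- exons$exon_id %in% names(n_cl)[n_cl > 0]
  reason <- dplyr::case_when(
    is.na(exons$delta_psi) ~ "missing-delta-psi",
    exons$delta_psi < psi_threshold ~ "below-threshold",
    !has_cl ~ "no-clusters",
    TRUE ~ NA_character_
  )
  retained <- exons[is.na(reason), , drop = FALSE]
  attr(retained, "excluded") <- tibble(
    exon_id = exons$exon_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  retained
}

#' Summarize zone labels into per-exon binding architectures
#'
#' An exon's architecture is a pure function of its multiset of cluster
#' zone labels: `unbound` (no clusters), `distal-only` (all labels in
#' \{a, d\}), `contains-b` (has `b` but no `c`), `contains-c` (has `c` but
#' no `b`), `mixed` (has both `b` and `c`).
#'
#' @param assignments per-cluster tibble from [classify_clusters()] (needs
#'   `exon_id` and `zone`).
#' @param exon_ids optional character vector of the full cohort; exons
#'   without any cluster appear as `unbound`.
#' @return tibble with columns `exon_id`, `labels` (comma-joined sorted
#'   zone labels), `architecture`, `has_upstream_distal`, `has_downstream`,
#'   `both_sides`, `distal_only`.
#' @export
summarize_exons <- function(assignments, exon_ids = NULL) {
  ids <- exon_ids %||% unique(assignments$exon_id)
  per <- lapply(ids, function(id) {
    z <- assignments$zone[assignments$exon_id == id]
    arch <- if (length(z) == 0L) {
      "unbound"
    } else if (all(z %in% c("a", "d"))) {
      "distal-only"
    } else if ("b" %in% z && "c" %in% z) {
      "mixed"
    } else if ("b" %in% z) {
      "contains-b"
    } else {
      "contains-c"
    }
    tibble(
      exon_id = id,
      labels = paste(sort(z), collapse = ","),
      architecture = arch,
      has_upstream_distal = "a" %in% z,
      has_downstream = "d" %in% z,
      both_sides = ("a" %in% z) && ("d" %in% z),
      distal_only = arch == "distal-only"
    )
  })
  bind_rows(per)
}

#' Cohort-level counts and fractions of binding architectures
#'
#' @param summaries per-exon tibble from [summarize_exons()].
#' @return list with `n` (cohort size), `counts` (named integer vector per
#'   architecture class, summing to `n`), `fractions_pct` (percentages to
#'   0.1), `distal_only_count`, `distal_only_pct`, and
#'   `both_sides_of_distal` (distal-only exons bound on both sides).
#' @export
cohort_summary <- function(summaries) {
  if (nrow(summaries) == 0L) abort("empty cohort")
  classes <- c("distal-only", "contains-b", "contains-c", "mixed", "unbound")
  counts <- vapply(classes, function(cl) sum(summaries$architecture == cl),
                   integer(1))
  n <- nrow(summaries)
  list(
    n = n,
    counts = counts,
    fractions_pct = round(100 * counts / n, 1),
    distal_only_count = unname(counts["distal-only"]),
    distal_only_pct = round(100 * counts[["distal-only"]] / n, 1),
    both_sides_of_distal = sum(summaries$both_sides & summaries$distal_only)
  )
}
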