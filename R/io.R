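#' Read and write peptide quantification tables
#'
#' Tab-separated with header columns `peptide`, `protein`, `complex_pair`,
#' `intensity_light`, `intensity_heavy`. Absent channel intensities are
#' stored as `NA` (not zero), so missingness stays distinct from a
#' measured zero.
#'
#' @param path file path.
#' @return tibble of peptides.
#' @export
read_peptide_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    peptide = readr::col_character(),
    protein = readr::col_character(),
    complex_pair = readr::col_character(),
    intensity_light = readr::col_double(),
    intensity_heavy = readr::col_double()
  ))
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    abort(sprintf("parse error in %s at line %d: %s", path,
                  prob$row[1] + 1L, prob$expected[1]))
  }
  required <- c("peptide", "protein", "complex_pair",
                "intensity_light", "intensity_heavy")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("peptide TSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  both_absent <- is.na(tab$intensity_light) & is.na(tab$intensity_heavy)
  if (any(both_absent)) {
    abort(sprintf("parse error in %s at line %d: peptide absent from both channels",
                  path, which(both_absent)[1] + 1L))
  }
  tab
}

#' @rdname read_peptide_tsv
#' @param peptides peptide tibble to write.
#' @export
write_peptide_tsv <- function(peptides, path) {
  readr::write_tsv(peptides, path)
  invisible(path)
}

#' Read and write spectral-count tables
#'
#' Tab-separated with header columns `protein`, `spc`, `length` (and
#' optionally `nsaf` on write).
#'
#' @param path file path.
#' @return tibble of spectral-count records.
#' @export
read_spectral_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    spc = readr::col_integer(),
    length = readr::col_integer(),
    .default = readr::col_double()
  ))
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    abort(sprintf("parse error in %s at line %d: %s", path,
                  prob$row[1] + 1L, prob$expected[1]))
  }
  required <- c("protein", "spc", "length")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("spectral-count TSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' @rdname read_spectral_tsv
#' @param records spectral-count tibble to write.
#' @export
write_spectral_tsv <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read and write BED6 cluster intervals
#'
#' BED coordinates are 0-based half-open, which is also the package's
#' internal convention, so columns map through unchanged. The BED `name`
#' field carries `cluster_id` (or `cluster_id|exon_id` when an exon
#' association is present).
#'
#' @param path file path.
#' @return tibble with columns `cluster_id`, `exon_id` (`NA` when absent
#'   from the name field), `chrom`, `strand`, `start`, `end`, `score`.
#' @export
read_bed6 <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      abort(sprintf("parse error in %s at line %d: expected 6 BED fields, got %d",
                    path, i, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("parse error in %s at line %d: non-numeric interval", path, i))
    }
    if (s >= e) {
      abort(sprintf("parse error in %s at line %d: start (%s) must be < end (%s)",
                    path, i, f[2], f[3]))
    }
    if (!f[6] %in% c("+", "-")) {
      abort(sprintf("parse error in %s at line %d: strand must be + or -", path, i))
    }
  }
  gr <- rtracklayer::import(path, format = "BED")
  name <- gr$name %||% rep(NA_character_, length(gr))
  parts <- strsplit(name, "|", fixed = TRUE)
  tibble(
    cluster_id = vapply(parts, function(p) p[1] %||% NA_character_, character(1)),
    exon_id = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
                     character(1)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = if (is.null(gr$score)) 0 else as.numeric(gr$score)
  )
}

#' @rdname read_bed6
#' @param clusters cluster tibble (columns `cluster_id`, optional
#'   `exon_id`, `chrom`, `strand`, `start`, `end`, optional `score`).
#' @export
write_bed6 <- function(clusters, path) {
  name <- if ("exon_id" %in% names(clusters) && !all(is.na(clusters$exon_id))) {
    paste(clusters$cluster_id, clusters$exon_id, sep = "|")
  } else {
    clusters$cluster_id
  }
  gr <- GenomicRanges::GRanges(
    seqnames = clusters$chrom,
    ranges = IRanges::IRanges(start = clusters$start + 1L, end = clusters$end),
    strand = clusters$strand,
    name = name,
    score = if ("score" %in% names(clusters)) clusters$score else 0
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write exon models as GFF3
#'
#' Each exon model becomes three GFF3 features sharing an `ID`/`Parent`
#' relationship: `cassette_exon` plus `upstream_intron` and
#' `downstream_intron`. GFF3 is 1-based closed; conversion to the
#' package's 0-based half-open convention happens here and only here.
#' Sequences are not stored in the GFF3; attach them from a locus FASTA
#' with [add_intron_sequences()].
#'
#' @param path file path.
#' @return exon-model tibble (without `up_intron_seq`).
#' @export
read_exon_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ex <- gr[typ == "cassette_exon"]
  ui <- gr[typ == "upstream_intron"]
  di <- gr[typ == "downstream_intron"]
  if (length(ex) == 0L) abort(sprintf("no cassette_exon features in %s", path))
  id <- ex$ID
  first_parent <- function(gr) {
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  }
  iui <- match(id, first_parent(ui))
  idi <- match(id, first_parent(di))
  if (anyNA(iui) || anyNA(idi)) {
    abort(sprintf("exon model(s) in %s lack flanking intron features", path))
  }
  ui <- ui[iui]
  di <- di[idi]
  tibble(
    exon_id = id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    exon_start = GenomicRanges::start(ex) - 1L,
    exon_end = GenomicRanges::end(ex),
    up_intron_start = GenomicRanges::start(ui) - 1L,
    up_intron_end = GenomicRanges::end(ui),
    down_intron_start = GenomicRanges::start(di) - 1L,
    down_intron_end = GenomicRanges::end(di),
    delta_psi = if (is.null(ex$delta_psi)) NA_real_ else as.numeric(ex$delta_psi)
  )
}

#' @rdname read_exon_gff3
#' @param exons exon-model tibble.
#' @export
write_exon_gff3 <- function(exons, path) {
  mk <- function(start, end, type, id = NULL, parent = NULL, psi = NULL) {
    gr <- GenomicRanges::GRanges(
      seqnames = exons$chrom,
      ranges = IRanges::IRanges(start = start + 1L, end = end),
      strand = exons$strand,
      type = type,
      source = "exonrnp"
    )
    if (!is.null(id)) gr$ID <- id
    if (!is.null(parent)) gr$Parent <- parent
    if (!is.null(psi)) gr$delta_psi <- psi
    gr
  }
  psi <- if ("delta_psi" %in% names(exons)) exons$delta_psi else NULL
  gr <- c(
    mk(exons$exon_start, exons$exon_end, "cassette_exon",
       id = exons$exon_id, psi = psi),
    mk(exons$up_intron_start, exons$up_intron_end, "upstream_intron",
       id = paste0(exons$exon_id, ":ui"), parent = exons$exon_id),
    mk(exons$down_intron_start, exons$down_intron_end, "downstream_intron",
       id = paste0(exons$exon_id, ":di"), parent = exons$exon_id)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet]; duplicate identifiers are an
#'   error.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicate sequence identifiers in %s: %s", path,
                  paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Attach upstream-intron 3' sequences to exon models from locus FASTA
#'
#' Extracts each exon's upstream-intron sequence from its locus sequence,
#' on the transcribed strand (reverse-complemented for minus-strand
#' exons), and stores it in `up_intron_seq` as required by
#' [classify_clusters()] and [predict_bps()].
#'
#' @param exons exon-model tibble.
#' @param sequences [Biostrings::DNAStringSet] named by chromosome.
#' @return the exon tibble with an `up_intron_seq` column.
#' @export
add_intron_sequences <- function(exons, sequences) {
  missing_chr <- setdiff(exons$chrom, names(sequences))
  if (length(missing_chr)) {
    abort(paste0("no sequence for chromosome(s): ",
                 paste(missing_chr, collapse = ", ")))
  }
  seqs <- vapply(seq_len(nrow(exons)), function(i) {
    s <- Biostrings::subseq(sequences[[exons$chrom[i]]],
                            start = exons$up_intron_start[i] + 1L,
                            end = exons$up_intron_end[i])
    if (exons$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  exons$up_intron_seq <- seqs
  exons
}

#' Write and read a JSON run summary
#'
#' Scalars are written unboxed and numbers at full precision.
#'
#' @param x a list (or other jsonlite-serializable object).
#' @param path file path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_summary
#' @export
read_json_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a pipeline run configuration from YAML
#'
#' Every tunable of the pipeline can be set in one YAML file; unset keys
#' fall back to package defaults. The seed must be explicit so runs are
#' reproducible by construction.
#'
#' @param path YAML file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    anchors = c("CBP20", "CBP80"),
    enrichment_threshold = 2.0,
    psi_threshold = 15,
    prox_window = 100L,
    bps_margin = 25L,
    aggregation = "median"
  )
  if (is.null(cfg$seed)) abort("configuration error: `seed` must be set explicitly")
  utils::modifyList(defaults, cfg)
}
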