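#!/usr/bin/env Rscript
# Stage 3: normalized spectral abundance factors for the complex.
#
# Reads the spectral-count table from stage 1, computes NSAF per protein,
# and writes results/nsaf/nsaf.tsv sorted by abundance.

suppressPackageStartupMessages({
  library(exonrnp)
  library(dplyr)
})

out <- "results/nsaf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_spectral_tsv("results/data/spectral_counts.tsv")
res <- nsaf(counts) |> arrange(desc(nsaf))
write_spectral_tsv(res, file.path(out, "nsaf.tsv"))

message(nrow(res), " proteins; NSAF sums to ", format(sum(res$nsaf)))
message("Top protein: ", res$protein[1], " (NSAF ", round(res$nsaf[1], 4), ")")
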