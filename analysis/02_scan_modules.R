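#!/usr/bin/env Rscript

# Step 2: the module census. Scans the non-coding DNA of both census
# contigs for Su(H) sites and proneural A boxes, builds inverted pairs,
# classifies SPS vs SPS+A, and writes the per-module tables and GFF3
# tracks. Reads the bundle written by 01_simulate_census.R when present,
# otherwise regenerates it (same seed, identical sequence).

suppressMessages(library(spsarch))

seed <- 20230
in_dir <- "results/census"

scan_one <- function(tag) {
  fa <- file.path(in_dir, sprintf("census_%s.fasta", tag))
  gff <- file.path(in_dir, sprintf("census_%s.gff3", tag))
  if (file.exists(fa) && file.exists(gff)) {
    run_scan(fa, gff, out_dir = file.path("results", paste0("scan_", tag)))
  } else {
    sim <- generate_contig(census_specs(seed = seed)[[tag]])
    run_scan(sim, out_dir = file.path("results", paste0("scan_", tag)))
  }
}

for (tag in c("a", "b")) {
  res <- scan_one(tag)
  cat("\n== species", tag, "==\n")
  print(res)
  m <- res$modules
  cat(sprintf("  %d SPS+A and %d bare SPS modules; spacers: %s\n",
              res$summary$n_sps_a, res$summary$n_sps,
              paste(names(res$summary$spacer_counts), "bp x",
                    res$summary$spacer_counts, collapse = ", ")))
  cat("  upstream distances by gene:\n")
  up <- m[!is.na(m$side) & m$side == "upstream", ]
  for (i in order(up$distance_bp)) {
    cat(sprintf("    %-8s %6d bp upstream (%s, spacer %d, Y %s/%s)\n",
                up$gene_id[i], up$distance_bp[i], up$module_class[i],
                up$spacer_bp[i], up$y_upstream[i], up$y_downstream[i]))
  }
  cat("  genes with a C in the upstream Y position:",
      paste(sort(unique(m$gene_id[!is.na(m$y_upstream) &
                                    m$y_upstream == "C"])),
            collapse = ", "), "\n")
  cat("  tables:", paste(res$files, collapse = ", "), "\n")
}
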