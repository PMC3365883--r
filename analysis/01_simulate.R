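#!/usr/bin/env Rscript
# Build the simulated survey: a reference barcode library (40 species,
# 2 haplotypes each, 658 bp) and 168 stomach-content query fragments with
# the observed read-length mixture, including cannibal queries from the
# predator species and dark-taxon queries from species withheld from the
# reference library. Writes the fixture files and the answer sheet under
# results/fixtures/.

suppressMessages(library(barcodediet))

seed <- 1L
out_dir <- "results/fixtures"
fx <- make_demo_fixture(out_dir, seed = seed)

truth <- fx$truth
cat("reference library:",
    length(unique(read_taxonomy(fx$paths$taxonomy)$species)),
    "referenced species; withheld (dark) species:",
    length(fx$withheld), "\n")
cat("queries:", nrow(truth), "| categories:\n")
print(table(truth$category))
cat("read lengths >= 600 bp:",
    sprintf("%.1f%%", 100 * mean(truth$length >= 600)),
    "| < 200 bp:", sum(truth$length < 200), "\n")
cat("fixtures in", out_dir, "\n")
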