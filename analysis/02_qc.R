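#!/usr/bin/env Rscript
# Quality control of the simulated stomach-content fragments: length gate
# at the 100 bp mini-barcode floor, ambiguity gate, and reading-frame /
# stop-codon screen under the vertebrate-mitochondrial code. Writes
# results/qc.tsv.

suppressMessages(library(barcodediet))

queries <- read_fasta("results/fixtures/queries.fasta")
qc <- qc_batch(queries)
write_table(qc$reports, "results/qc.tsv")

cat("queries in:", qc$summary[["n_input"]],
    "| passing:", qc$summary[["n_pass"]], "\n")
cat("failure reasons:\n")
print(qc$summary[-(1:2)])
cat("stop codons in best frame (should be zero for clean simulations):",
    sum(qc$reports$stops_in_best_frame), "\n")
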