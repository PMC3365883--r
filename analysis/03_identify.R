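#!/usr/bin/env Rscript
# Taxonomic identification of the QC-passed fragments: ranked K2P matches
# against the reference library, the <3% divergence species rule, and the
# neighbor-joining strict-criterion fallback for queries without a close
# match. Scores the assignments against the simulator's answer sheet.
# Writes results/assignments.tsv.

suppressMessages(library(barcodediet))

refs <- read_fasta("results/fixtures/reference.fasta")
taxonomy <- read_taxonomy("results/fixtures/reference_taxonomy.tsv")
queries <- read_fasta("results/fixtures/queries.fasta")
truth <- utils::read.delim("results/fixtures/truth.tsv",
                           colClasses = "character")

qc <- qc_batch(queries)
res <- identify_batch(qc$passing, refs, taxonomy)
write_table(res$assignments, "results/assignments.tsv")

cat("assignments by method:\n"); print(res$report$by_method)
cat("assignments by rank:\n"); print(res$report$by_rank)

m <- merge(res$assignments, truth, by.x = "query_id", by.y = "id")
nd <- m[m$category != "dark", ]
dk <- m[m$category == "dark", ]
cat(sprintf("correct species among referenced-species queries: %.1f%% (n=%d)\n",
            100 * mean(nd$species.x == nd$species.y), nrow(nd)))
cat("dark queries called at species rank:", sum(dk$rank == "species"),
    "of", nrow(dk), "\n")
cg <- dk[dk$genus.y %in% unique(refs_genus <- taxonomy$genus) &
           dk$method == "strict-tree", ]
if (nrow(cg))
  cat(sprintf("dark queries with referenced congener assigned correct genus: %.1f%% (n=%d)\n",
              100 * mean(cg$genus.x == cg$genus.y), nrow(cg)))
cannibal <- m[m$category == "cannibal", ]
cat("cannibal queries recovered as the predator species:",
    sum(cannibal$species.x == cannibal$species.y), "of", nrow(cannibal), "\n")
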