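#!/usr/bin/env Rscript
# Diet composition from the published survey prey tables bundled with the
# package: percent composition by number at class / family / species /
# crustacean-order level, taxon richness, new regional records against the
# prior checklist, and cannibalism. Writes the composition tables under
# results/.

suppressMessages(library(barcodediet))

asn <- study_prey_assignments()
cat("prey sequences:", sum(asn$count),
    "(fish", sum(asn$count[asn$class == "fish"]),
    "/ crustacean", sum(asn$count[asn$class == "crustacean"]), ")\n\n")

cls <- percent_n(asn, "class", "all")
fam <- percent_n(asn, "family", "fish_only")
sp <- percent_n(asn, "species", "fish_only")
ord <- percent_n(asn, "order", "crustacean_only")
write_table(cls, "results/composition_class.tsv")
write_table(fam, "results/composition_family.tsv")
write_table(sp, "results/composition_species.tsv")
write_table(ord, "results/composition_crustacean_order.tsv")

cat("%N by class:\n")
print(cls[, c("taxon", "count", "percent_n_display")], row.names = FALSE)
cat("\ntop fish families (%N, fish-only denominator):\n")
print(utils::head(fam[, c("taxon", "count", "percent_n_display")], 4),
      row.names = FALSE)
cat("\ncrustacean orders (%N, crustacean-only denominator):\n")
print(ord[, c("taxon", "count", "percent_n_display")], row.names = FALSE)

rich <- richness(asn[asn$class == "fish", ])
write_table(data.frame(rank = names(rich), n_taxa = as.integer(rich)),
            "results/richness.tsv")
cat("\nfish prey richness:", paste(names(rich), rich, collapse = ", "), "\n")

new_rec <- flag_new_records(asn, study_checklist())
write_table(data.frame(species = new_rec), "results/new_records.tsv")
cat("new records for the region (", length(new_rec), "):\n  ",
    paste(new_rec, collapse = "\n   "), "\n", sep = "")

cann <- flag_cannibalism(asn, "Pterois volitans")
cat("cannibalism: ", cann$count, " prey sequences match the predator\n",
    sep = "")
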