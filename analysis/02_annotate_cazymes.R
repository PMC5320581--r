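#!/usr/bin/env Rscript
# Call CAZymes on the simulated genome from its raw dual-evidence tables,
# applying the published filter thresholds, and assign carbohydrate sets.

library(gppulr)

genome <- read_genome_tsv("results/sim_genome.tsv")
hmm <- read.delim("results/sim_hmm_evidence.tsv")
blast <- read.delim("results/sim_blast_evidence.tsv")

t <- filter_thresholds()
kept_h <- filter_hmm_hits(hmm, t)
kept_b <- filter_blast_hits(blast, t)
cat("HMM evidence:", nrow(hmm), "rows,", nrow(kept_h), "pass the filters.\n")
cat("Protein-search evidence:", nrow(blast), "rows,", nrow(kept_b),
    "pass.\n")

res <- call_cazymes(genome, hmm, blast, t = t)
sets <- assign_carbohydrate_sets(res$calls)
res$calls$carb_sets <- vapply(sets[res$calls$gene_id],
                              paste, character(1), collapse = ";")
write.table(res$calls, "results/sim_cazyme_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_genome_tsv(res$genome, "results/sim_genome_annotated.tsv")

cat("Called", nrow(res$calls), "CAZymes;",
    sum(res$calls$carb_sets != ""), "map to a carbohydrate set.\n")
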