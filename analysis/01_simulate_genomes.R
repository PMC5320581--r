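#!/usr/bin/env Rscript
# Simulate an annotated genome with planted polysaccharide utilization
# loci, decoy gene clusters and mock CAZyme evidence, and write the
# artifacts consumed by the downstream steps.

library(gppulr)

dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 101)
sim <- generate_genome(cfg, include_enzyme_labels = FALSE)

write_genome_tsv(sim$genome, "results/sim_genome.tsv")
write.table(sim$truth, "results/sim_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$hmm, "results/sim_hmm_evidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$blast, "results/sim_blast_evidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", n_genes(sim$genome), "genes on one contig:",
    nrow(sim$truth), "planted loci,", nrow(sim$decoys), "decoy clusters,",
    nrow(sim$hmm), "HMM evidence rows (",
    sum(!duplicated(sim$hmm$gene_id)), "genes ),",
    nrow(sim$blast), "protein-search rows.\n")
cat("Planted loci:", paste(sim$truth$pul_name, collapse = ", "), "\n")
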