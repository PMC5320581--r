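#!/usr/bin/env Rscript
# Cross locus-family presence against the transcribed growth phenotypes.

library(gppulr)

growth <- fixture_growth_matrix()
presence <- fixture_pul_presence()
pairs <- data.frame(
  pul_family = c("Eub-3", "Eub-4", "Ros-2", "AG1-GH53"),
  substrate = c("inulin", "inulin", "arabinoxylan", "arabinogalactan_type1"))

rep <- phenotype_concordance(presence, growth, pairs)
write.table(rep, "results/phenotype_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(as.data.frame(rep), row.names = FALSE)
cat("\nInulin locus exceptions:", rep$exceptions[rep$pul_family == "Eub-3"],
    "\n")
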