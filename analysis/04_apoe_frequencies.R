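#!/usr/bin/env Rscript
# Stage 4 -- APOE epsilon diplotypes from the rs429358/rs7412 proxy SNPs
# and ancestry x phenotype genotype frequency tables, plus a pooled table
# (counts summed, proportions recomputed).

library(demcatalog)

loaded <- read_vcf("scratch/cohort/cohort.vcf", intervals = NULL)
samples <- read_manifest("scratch/cohort/manifest.tsv")
keep_s <- readLines("results/qc_pass_samples.txt")
samples <- samples[samples$sample_id %in% keep_s, ]
gm <- loaded$gm[samples$sample_id, ]

dip <- call_diplotype(gm[, "chr19:44908684:T:C"], gm[, "chr19:44908822:C:T"])
tab <- apoe_freq_table(dip, samples)
write.table(tab, "results/apoe_frequencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

e44 <- tab[tab$diplotype == "e4/e4", ]
cat("e4/e4 proportions by ancestry and phenotype:\n")
print(e44[order(e44$ancestry, e44$phenotype),
          c("ancestry", "phenotype", "n", "proportion")], row.names = FALSE)
cat("ambiguous double-heterozygote calls:",
    sum(dip$ambiguous, na.rm = TRUE), "\n")
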