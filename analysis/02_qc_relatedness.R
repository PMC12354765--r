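#!/usr/bin/env Rscript
# Stage 2 -- sample- and variant-level QC on the simulated cohort:
# call rates, heterozygosity F, sex-label concordance, KING-robust kinship
# with greedy pruning at the cousin-level cutoff (0.0884), then variant
# filters (call rate, HWE in controls, differential missingness).

library(demcatalog)

loaded <- read_vcf("scratch/cohort/cohort.vcf", intervals = NULL)
samples <- read_manifest("scratch/cohort/manifest.tsv",
                         enforce_control_age = TRUE)
gm <- loaded$gm[samples$sample_id, ]

sqc <- sample_qc(gm, samples)
write.table(sqc, "results/sample_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("samples excluded:", sum(sqc$excluded), "of", nrow(sqc), "--",
    paste(unique(unlist(strsplit(sqc$exclusion_reasons[sqc$excluded], ";"))),
          collapse = ", "), "\n")

keep <- samples$sample_id[!sqc$excluded]
vqc <- variant_qc(gm[keep, ], samples[samples$sample_id %in% keep, ])
write.table(vqc, "results/variant_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("variants excluded:", sum(vqc$excluded), "of", nrow(vqc), "\n")

writeLines(keep, "results/qc_pass_samples.txt")
writeLines(vqc$variant[!vqc$excluded], "results/qc_pass_variants.txt")
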