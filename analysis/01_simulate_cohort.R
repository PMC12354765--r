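#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic multi-ancestry cohort used by every
# downstream stage: 1,000 cases / 1,500 controls over three ancestries with
# realistic APOE epsilon-haplotype gradients, the 21-variant modifier panel
# (two with planted effects), rare coding variants in the 11 genes, and a
# couple of planted relatives.

library(demcatalog)

dir.create("results", showWarnings = FALSE)
mv <- modifier_variants()
mods <- data.frame(rsid = mv$rsid, freq = 0.10, main_or = 1,
                   interaction_or = 1)
mods$freq[mods$rsid == "rs10423769"] <- 0.25
mods$interaction_or[mods$rsid == "rs10423769"] <- 0.6  # e4-specific protection
mods$freq[mods$rsid == "rs449647"] <- 0.35
mods$main_or[mods$rsid == "rs449647"] <- 0.85

cfg <- sim_config(
  seed = 20260930L,
  n_cases = c(EUR = 250L, AFR = 100L, AAC = 60L),
  n_controls = c(EUR = 375L, AFR = 150L, AAC = 90L),
  modifiers = mods, rare_per_gene = 8L, rare_case_or = 1.8,
  missing_rate = 0.005, n_qc_snps = 1500L, n_duplicate_pairs = 1L,
  n_parent_offspring_pairs = 2L)

co <- simulate_cohort(cfg, dir = "scratch/cohort")
cat("cohort written:", paste(basename(co$paths), collapse = ", "), "\n")
cat(nrow(co$samples), "samples x", ncol(co$gm), "variants;",
    sum(co$samples$phenotype != "control"), "cases\n")
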