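# demcatalog

Multi-ancestry characterization of coding and splicing variation in eleven
Alzheimer's disease / related-dementia (AD/ADRD) genes — *APP*, *PSEN1*,
*PSEN2*, *TREM2*, *MAPT*, *GRN*, *GBA1*, *SNCA*, *TBK1*, *TARDBP*, *APOE* —
as a tested, reusable R pipeline. It is written for statistical geneticists
who need the analysis stages of a biobank-scale dementia characterization
to run, verifiably, without access-controlled data:

1. **QC and relatedness** — sample call rate, excess heterozygosity
   (|F| > 0.25), sex-label concordance, KING-robust kinship
   φ̂ = (N_het,het − 2·N_opp-hom)/(N_het(i) + N_het(j)) with deterministic
   greedy pruning at the cousin cutoff (φ > 0.0884), exact Hardy-Weinberg
   (controls, p < 1e-4) and Fisher differential-missingness tests.
2. **Prioritization** — indel left-alignment to a canonical
   (chrom, pos, ref, alt) key, the six-class consequence filter, and the
   case-only ∧ CADD > 20 sieve with known/novel classification and
   cross-biobank catalog assembly.
3. **APOE** — ε diplotypes from rs429358/rs7412 (ε4 = C,C; ε3 = T,C;
   ε2 = T,T; ambiguous double heterozygote called ε2/ε4 and flagged),
   ancestry × phenotype frequency tables, count-level pooling.
4. **Modifier models** — the 21 protective/resilience variants across APOE
   strata: carrier frequencies, and protective / conditional / R² (EM-based
   two-locus LD) / interaction logistic models fit by the package's own
   IRLS with explicit separation and collinearity diagnostics.
5. **Burden** — from-scratch SKAT-O: Q_ρ = r′GWR_ρWG′r with Beta(1,25)
   weights on MAF ≤ 0.01 variants, mixture-of-chi-square p-values
   (moment matching + characteristic-function refinement), min-p
   combination over the ρ grid, a residual-permutation oracle, and an
   exact-moment conditional p-value for the sparse small-sample regime.
6. **PRS** — weighted-dosage scores with allele-orientation checks,
   nearest-rank top-quartile subsetting, and per-modifier enrichment
   models with or without an APOE ε4-dose covariate.
7. **Synthetic data** — a seeded generator (APOE haplotype frequencies per
   ancestry, modifier main/interaction odds ratios, rare case-enriched
   variants, relatedness plants, missingness) plus packaged fixtures,
   including a machine-readable transcription of the published
   discovery-phase variant catalog.

## Worked example

```r
library(demcatalog)

# a seeded two-ancestry cohort with one planted protective modifier
co <- simulate_cohort(sim_config(
  seed = 42, n_cases = c(EUR = 1000L), n_controls = c(EUR = 1000L),
  modifiers = data.frame(rsid = "rs10423769", freq = 0.25,
                         main_or = 0.5, interaction_or = 1),
  rare_per_gene = 0L))

dip <- call_diplotype(co$gm[, "chr19:44908684:T:C"],
                      co$gm[, "chr19:44908822:C:T"])
table(dip$diplotype)[c("e3/e3", "e3/e4", "e4/e4")]
#> e3/e3 e3/e4 e4/e4
#>  1145   538    58

dose <- co$gm[, grep("chr22", colnames(co$gm))]
protective_model(dose, co$samples)[, c("term", "odds_ratio", "p")]
#>     term odds_ratio           p
#> 1 dosage  0.4896809 1.47998e-18
```

The planted odds ratio of 0.5 is recovered (0.49, 95% CI covering 0.5);
the diplotype counts reflect the default European ε4 haplotype frequency
(0.14) under random mating, enriched by the default ε4 disease odds ratio
(3 per allele) in this balanced case-control sample. Counting the packaged
transcription of the published discovery tables:

```r
asm <- assemble_catalog(load_fixture("printed_catalog"))
unlist(asm$summary[c("n_total", "n_known", "n_novel")])
#> n_total  n_known  n_novel
#>     156       23      133
```

## Analysis workflow

`analysis/01_simulate_cohort.R` … `analysis/07_prs_stratification.R` run
the whole pipeline in order on a seeded synthetic cohort (the cohort files
land in `scratch/`, the result tables in `results/`):

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

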