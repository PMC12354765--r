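---
title: "Methods: multi-ancestry characterization of dementia-gene variation"
author: "demcatalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-ancestry characterization of dementia-gene variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demcatalog)
```

# The problem

Large biobanks now hold whole-genome sequences for tens of thousands of
people with Alzheimer's disease and related dementias (AD/ADRD) and for
screened elderly controls, across many genetic ancestries. `demcatalog`
implements, as reusable and tested R functions, the analysis pipeline such a
characterization needs: cohort quality control and relatedness pruning,
case-only prioritization of deleterious coding and splicing variants in
eleven dementia genes (*APP*, *PSEN1*, *PSEN2*, *TREM2*, *MAPT*, *GRN*,
*GBA1*, *SNCA*, *TBK1*, *TARDBP*, *APOE*), APOE ε-diplotype calling with
ancestry-stratified frequency tables, a four-model regression framework for
protective and resilience variants, gene-level rare-variant burden testing,
and polygenic-risk-score (PRS) stratified enrichment.

Because the underlying biobank genotypes are access-controlled, the package
ships two substitutes that make every stage testable at the desk: a
synthetic cohort generator with known planted truth, and a machine-readable
transcription of the published discovery-phase variant catalog whose summary
counts the counting code must reproduce exactly.

# Quality control

Sample-level QC mirrors standard sequencing-cohort practice: call rate
(default exclusion below 0.95), excess heterozygosity via the inbreeding-style
statistic $F = 1 - O_{het}/E_{het}$ with $E_{het} = \sum_j 2 p_j (1 - p_j)$
over the sample's called sites (excluded when $|F| > 0.25$), a label
comparison between reported and genetically determined sex (the gene panel
excludes chrX, so no intensity modeling is attempted), and relatedness
pruning. Kinship uses the robust heterozygote/opposite-homozygote estimator

$$\hat\varphi_{ij} = \frac{N^{het,het}_{ij} - 2\,N^{opp}_{ij}}
{N^{het}_i + N^{het}_j},$$

computed over jointly called sites: about 0.5 for duplicates, 0.25 for
parent-offspring, 0 for unrelated pairs. Pairs above the cousin-level
cutoff 0.0884 are resolved greedily: the sample in the most flagged pairs is
dropped first, ties broken by lower call rate and then lexicographic sample
id, which makes the exclusion set deterministic and order-independent. The
estimator form and the tie-break rule are documented implementation choices;
the cutoff is the conventional value halfway between third- and
second-degree relatives on the log scale.

Variant-level QC applies per-cohort call-rate thresholds, the conditional
exact Hardy-Weinberg test in controls (flag at $p < 10^{-4}$), and a
two-sided Fisher exact test of differential missingness by case-control
status (flag at $p \le 10^{-4}$). The Hardy-Weinberg test sums the
probabilities of heterozygote counts no more probable than the observed one
given the allele counts; no mid-p correction is applied, and monomorphic
sites return 1 by convention. Degenerate cohorts (no cases or no controls)
abort the case/control tests with an explicit error.

A practical caveat the synthetic experiments make visible: kinship and
heterozygosity are only stable when estimated from many informative sites.
An 11-gene panel alone carries a handful of common variants, so the
generator can emit a configurable backbone of common background SNPs
(`n_qc_snps`) emulating the genome-wide pruned panel these checks run on in
production pipelines; the analysis drivers use 1,500.

# Variant normalization and the prioritization sieve

Variants are reduced to a canonical `(chrom, pos, ref, alt)` key: shared
trailing bases are trimmed (prepending the upstream reference base whenever
an allele would empty, which left-shifts indels maximally), then shared
leading bases are trimmed while both alleles keep at least one base. The
operation is idempotent, and the test suite checks it against a brute-force
oracle that enumerates every equivalent spelling and picks the smallest
position. Coordinates are 1-based inclusive throughout; genotypes are
treated as unphased and phase separators ignored.

The sieve keeps six consequence classes (missense, frameshift, start loss,
stop loss, stop gain, splicing), then emits a catalog entry for every
variant that in a given dataset has at least one case carrier, zero control
carriers, and CADD phred strictly greater than 20 (the top-1% genome-wide
deleteriousness proxy; the threshold is strict, so CADD = 20.0 is excluded).
Case-only status is evaluated within each discovery dataset separately —
a variant can be case-only in one biobank while appearing in another's
controls — and cross-dataset presence is reported as a replication flag
rather than an exclusion. Known/novel classification is an exact key match
against a normalized knowledge table; merged catalogs are deduplicated on
the key, with conflicting gene assignments treated as an error.

# APOE ε diplotypes

The ε alleles are haplotypes of rs429358 and rs7412 (ε4 = C,C; ε3 = T,C;
ε2 = T,T; ε1 = C,T). From unphased genotypes, eight of the nine genotype
pairs map uniquely; the double heterozygote is chemically ambiguous between
ε2/ε4 and ε1/ε3. It is called ε2/ε4 and flagged `ambiguous = TRUE` — ε1 is
vanishingly rare and ε1 genotypes are essentially never reported — so
downstream strata can exclude ambiguous calls if desired. The ε3/ε3 stratum
excludes ambiguous calls by construction; the ε4-carrier stratum includes
ε2/ε4 and ε1/ε4. Frequency tables count called diplotypes per ancestry ×
phenotype group; pooling across cohorts sums counts and recomputes
proportions (never averages them).

# The four-model framework for modifier variants

The packaged panel holds the 21 reported variants (11 protective, 10
resilience), keyed by rsID and effect allele. The paper's sources print no
genomic coordinates for them, so the packaged table deliberately carries
none: synthetic cohorts place them at synthetic coordinates, and real
analyses match by rsID in the user's annotation.

For each modifier the package fits, by its own iteratively reweighted
least-squares logistic regression:

* **protective**: case status ~ dosage + sex + age + PCs, whole cohort;
* **conditional**: the same model restricted to an APOE stratum (ε4
  carriers, ε4/ε4, or ε3/ε3) — restriction, rather than an APOE covariate,
  is the primary reading of "in the presence of APOE"; a covariate-adjusted
  variant remains available through the design-matrix helper;
* **R²**: two-locus haplotype frequencies between the modifier and each
  APOE proxy SNP by expectation-maximization over unphased genotypes
  (double heterozygotes fractionally assigned, convergence at
  $\Delta < 10^{-10}$), reporting $r^2 = D^2/(p_A p_a p_B p_b)$ and $D'$;
* **interaction**: dosage + APOE indicator + dosage × indicator + sex +
  age + PCs, with the Wald test on the product term as the reported
  interaction p.

Dosage is the additive 0/1/2 effect-allele count by default (carrier coding
available), ten PCs are adjusted for (matching the burden analysis
convention; the source names only "PCs"), and p-values are reported raw —
no multiple-testing correction is applied by default, mirroring the
original analysis. The IRLS fitter declares convergence at score norm
below 1e-8 or relative deviance change below 1e-10 (max 100 iterations),
takes standard errors from observed information, screens out constant
covariate columns, and reports complete separation and collinearity as
explicit non-convergence diagnostics rather than silent output. Carrier
frequencies are tabulated per modifier × ancestry × phenotype over three
denominators: total population, total ε4/ε4, and total ε4 carriers.

# Rare-variant burden

Gene-level association uses a from-scratch implementation of the optimal
unified variance-component test. With null-model residuals
$r = y - \hat\mu$ from the covariate-only logistic fit, weights $w_j$ equal
to the Beta(1, 25) density at each variant's MAF, and
$R_\rho = (1-\rho)I + \rho \mathbf{1}\mathbf{1}'$,

$$Q_\rho = r' G W R_\rho W G' r,$$

interpolating between the kernel test ($\rho = 0$) and the weighted burden
test ($\rho = 1$) over the grid $\{0, 0.1^2, \dots, 0.9^2, 1\}$. Null
p-values come from the mixture of chi-squares given by the eigenvalues of
the covariate-projected kernel, evaluated by moment matching with a
characteristic-function (Imhof-type) numerical refinement; the grid is
combined through the minimum-p statistic with the standard one-dimensional
integration over the shared χ²(1) component, falling back to a
Bonferroni-adjusted minimum p (flagged in the output) if the integration
fails. Rare means MAF ≤ 0.01 computed over all non-missing QC-passed
samples (cases plus controls; a controls-only alternative is documented),
and two functional categories are supported: synonymous-only, and
nonsynonymous excluding both synonymous variants and known disease-causing
keys. Missing genotypes are mean-imputed per variant by default. Every
constant sits in `burden_config()`.

Two safeguards surround the asymptotic p-values, because at a thousand
samples with variants this rare the weighted scores are sums over a
handful of carriers and the chi-square mixture misstates the null CDF by
up to one or two percentage points. A permutation oracle
(`permutation_pvalue()`) samples the reduced-model null directly — its
default scheme permutes the null-model residual vector (the
Freedman-Lane-style construction that is exactly exchangeable for a score
statistic; stratified label permutation is kept as an option). And a
small-sample analytic companion (`skat_perm_moment_pvalue()`) evaluates
the same conditional null without sampling: the first three moments of
Q under permutation of the observed residuals have closed forms in the
residual power sums and contractions of the kernel — computed exactly by
enumerating index-slot partitions with Möbius inversion, the same device
behind moment-approximated Mantel and Moran randomization tests — and a
three-moment chi-square fit to them tracks the 10,000-permutation oracle
within Monte-Carlo error in the regimes the tests cover. The published
GBA1 enrichment p-value is data-dependent and deliberately not a package
target; the package's claims are oracle agreement and operating
characteristics.

# PRS stratification

Scores are weighted dosage sums over variants matched by position with an
allele-orientation check (swapped effect/other alleles flip the dosage to
$2-d$; unmatched alleles are dropped with a log message; missing dosages
are mean-imputed). Z-scores are standardized within the scored set (the
original analysis was single-ancestry, so no within-ancestry option is
needed by default). The high-risk stratum is the top quartile by the
nearest-rank-from-the-top rule: threshold at the $\lceil n/4 \rceil$-th
largest score, all boundary ties included, so at least 25% of samples are
always selected and the subset is order-invariant. Within the stratum,
per-modifier logistic enrichment models run under two covariate sets — PRS
z + sex + age + PC1-5, and the same plus APOE status coded as ε4 dose
(0/1/2), a documented choice since the source does not define the coding.
A small synthetic weight panel ships with the package so no GWAS download
is required.

# The synthetic-data generator

`sim_config()` fixes the study conditions: per-ancestry case/control cell
counts, per-ancestry APOE haplotype frequencies (defaults follow the
familiar gradient — higher ε4 in African and African-admixed ancestries
than European), a per-allele ε4 log odds ratio of log 3, modifier allele
frequencies with main and interaction-with-ε4 odds ratios, per-gene rare
variants with uniform MAFs in [5 × 10⁻⁴, 8 × 10⁻³], covariates, optional
duplicate/parent-offspring plants, and genotype missingness. Phenotypes are
assigned prospectively — covariates and genotypes are drawn for an
oversampled pool, case status is drawn from the logistic model, and the
requested cells are then sampled — which preserves the configured odds
ratios under case-control sampling (logistic slopes are consistent under
outcome-dependent sampling); infeasible cell requests abort before any
output is written. Everything is reproducible from the seed, byte-for-byte
in the emitted VCF/TSV/JSON files.

What the generator does **not** emulate: linkage disequilibrium structure
(sites are independent given ancestry), sequencing artifacts beyond uniform
missingness, age- or sex-dependent penetrance, and ancestry confounding in
the PCs (centroids plus isotropic noise, no effect on phenotype unless
configured). Passing tests therefore demonstrate correctness of the
statistical machinery under its stated assumptions, not robustness to the
correlated noise of real sequencing data.

# Problem sizes and numerical choices

The test suite and acceptance script run at sizes a laptop handles in
minutes, chosen as the smallest that make the statistical claims sharp:
kinship benchmarks at 2,000 SNPs (±0.02 on parent-offspring means),
Hardy-Weinberg calibration over 10,000 replicates, SKAT-O validated against
a 10,000-permutation oracle at n = 1,000 with 20 rare variants, and
parameter recovery over 100 seeded replicates at n = 4,000 (main odds
ratio 0.5) and n = 6,000 (ε4-interaction odds ratio 2.0), requiring 95% CI
coverage and at least 80% power. The analysis drivers use a ~1,000-sample,
three-ancestry cohort with a 1,500-SNP QC backbone as an illustration.

Other numerical choices: exact-test ties are compared with a 1 + 10⁻¹⁰
relative tolerance so floating-point equality cannot flip a tail; the EM
stops at Δ < 10⁻¹⁰ (max 1,000 iterations) and monomorphic sites report NA
rather than a fabricated r²; IRLS uses step-halving to keep the deviance
monotone; the SKAT-O ρ = 1 grid point is nudged to 0.999 inside the
combination integral where the decomposition degenerates; catalog writes
sort rows (gene, chrom, pos, alt) and use fixed column order so repeated
writes are byte-identical.

# Known limitations

Ancestry labels are consumed, never inferred (the upstream ancestry
prediction pipeline is explicitly out of scope), as are consequence and
CADD annotation, ACMG classification, and EHR cohort construction. The
ε1-containing double-heterozygote resolution is a convention, not an
inference. Carrier-frequency tables and model fits are only as meaningful
as the strata are large; fits in thin strata are flagged (`low_n`) rather
than suppressed. The burden test's analytic null relies on asymptotics
that thin out below a few hundred samples or a handful of carriers — that
is precisely what the permutation oracle is packaged for.
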