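#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a case/control dementia cohort: APOE proxy-SNP
#' genotypes drawn from per-ancestry epsilon-haplotype frequencies under
#' random mating, modifier variants with configurable main and
#' interaction-with-e4 odds ratios, rare case-enriched coding variants per
#' gene, covariates (sex, age, ancestry-centroid PCs), optional relatedness
#' plants and genotype missingness. Phenotype assignment is prospective: a
#' logistic model combining the e4 dose, modifier dosages, interactions and
#' rare-variant burden generates case status in an oversampled pool, from
#' which the requested per-ancestry cell counts are drawn.
#'
#' @param seed mandatory RNG seed.
#' @param n_cases,n_controls named integer vectors (names = ancestries).
#' @param related_dementia_fraction fraction of cases labelled as related
#'   dementias rather than AD.
#' @param apoe_haplotype_freqs matrix (ancestry rows x columns e1,e2,e3,e4)
#'   of haplotype frequencies summing to 1 per row; default: e4-enriched
#'   African-ancestry rows, mirroring the frequency gradients the pipeline
#'   is designed to detect.
#' @param beta_e4 per-allele log odds ratio of the e4 haplotype.
#' @param modifiers data.frame with `rsid`, `freq`, `main_or`,
#'   `interaction_or` (interaction with e4 carriage); NULL for the packaged
#'   21-variant panel at neutral effects.
#' @param rare_per_gene number of rare variants simulated per gene.
#' @param rare_maf_range uniform range for rare-variant population MAFs.
#' @param rare_case_or odds ratio per rare alt allele (shared by the
#'   non-synonymous variants).
#' @param synonymous_fraction fraction of rare variants that are synonymous
#'   (carrying no effect).
#' @param base_prevalence pool-level disease probability at zero genetic
#'   load.
#' @param sex_ratio probability a sample is male.
#' @param missing_rate per-genotype missingness probability.
#' @param n_qc_snps number of common background SNPs (population frequency
#'   uniform on 0.1-0.5, no phenotype effect) emulating the genome-wide
#'   pruned panel that relatedness and heterozygosity checks run on; the
#'   11-gene panel alone carries too few informative sites for stable
#'   kinship estimates.
#' @param n_duplicate_pairs,n_parent_offspring_pairs relatedness plants.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = c(EUR = 300L),
                       n_controls = c(EUR = 300L),
                       related_dementia_fraction = 0.25,
                       apoe_haplotype_freqs = NULL,
                       beta_e4 = log(3),
                       modifiers = NULL,
                       rare_per_gene = 6L,
                       rare_maf_range = c(5e-4, 8e-3),
                       rare_case_or = 1,
                       synonymous_fraction = 1 / 3,
                       base_prevalence = 0.25,
                       sex_ratio = 0.5,
                       missing_rate = 0,
                       n_qc_snps = 0L,
                       n_duplicate_pairs = 0L,
                       n_parent_offspring_pairs = 0L) {
  if (missing(seed)) stop("seed is mandatory")
  ancs <- union(names(n_cases), names(n_controls))
  stopifnot(all(ancs %in% ANCESTRIES))
  if (is.null(apoe_haplotype_freqs)) {
    apoe_haplotype_freqs <- t(vapply(ancs, function(a) {
      e4 <- switch(a, AFR = 0.21, AAC = 0.19, EUR = 0.14, FIN = 0.17, 0.12)
      c(e1 = 0, e2 = 0.07, e3 = 1 - 0.07 - e4, e4 = e4)
    }, numeric(4)))
  }
  stopifnot(all(abs(rowSums(apoe_haplotype_freqs) - 1) < 1e-8))
  if (is.null(modifiers)) {
    mv <- modifier_variants()
    modifiers <- data.frame(rsid = mv$rsid, freq = 0.1, main_or = 1,
                            interaction_or = 1, stringsAsFactors = FALSE)
  }
  structure(list(seed = seed, n_cases = n_cases, n_controls = n_controls,
                 ancestries = ancs,
                 related_dementia_fraction = related_dementia_fraction,
                 apoe_haplotype_freqs = apoe_haplotype_freqs,
                 beta_e4 = beta_e4, modifiers = modifiers,
                 rare_per_gene = rare_per_gene,
                 rare_maf_range = rare_maf_range,
                 rare_case_or = rare_case_or,
                 synonymous_fraction = synonymous_fraction,
                 base_prevalence = base_prevalence, sex_ratio = sex_ratio,
                 missing_rate = missing_rate, n_qc_snps = n_qc_snps,
                 n_duplicate_pairs = n_duplicate_pairs,
                 n_parent_offspring_pairs = n_parent_offspring_pairs),
            class = "sim_config")
}

# haplotype definitions at (rs429358, rs7412); alleles written ref/alt
APOE_SITES <- data.frame(
  rsid = c("rs429358", "rs7412"), chrom = "chr19",
  pos = c(44908684L, 44908822L), ref = c("T", "C"), alt = c("C", "T"),
  stringsAsFactors = FALSE)

# per-haplotype allele indicator: does the haplotype carry the alt allele?
APOE_HAP_ALT <- matrix(c(1, 1,   # e1: C at rs429358, T at rs7412
                         0, 1,   # e2
                         0, 0,   # e3
                         1, 0),  # e4
                       nrow = 4, byrow = TRUE,
                       dimnames = list(c("e1", "e2", "e3", "e4"),
                                       c("rs429358", "rs7412")))

#' Generate a synthetic cohort
#'
#' See [sim_config()] for the generative model. With `dir` supplied, a VCF,
#' manifest TSV, annotation TSV and truth JSON are written
#' deterministically (same seed, byte-identical files).
#'
#' @param config [sim_config()].
#' @param dir optional output directory.
#' @return list with `gm` (samples x variants dose matrix), `samples`
#'   (manifest), `variants` (annotation), `truth` (planted effects,
#'   diplotypes, carrier lists), and `paths` when files were written.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  oversample <- 8L
  pools <- list()
  for (anc in config$ancestries) {
    n_need <- sum(config$n_cases[anc], config$n_controls[anc], na.rm = TRUE)
    n_pool <- max(200L, oversample * n_need)
    hap_freq <- config$apoe_haplotype_freqs[anc, ]
    h1 <- sample(names(hap_freq), n_pool, replace = TRUE, prob = hap_freq)
    h2 <- sample(names(hap_freq), n_pool, replace = TRUE, prob = hap_freq)
    g429358 <- APOE_HAP_ALT[h1, "rs429358"] + APOE_HAP_ALT[h2, "rs429358"]
    g7412 <- APOE_HAP_ALT[h1, "rs7412"] + APOE_HAP_ALT[h2, "rs7412"]
    e4_dose <- (h1 == "e4") + (h2 == "e4")
    mod_g <- vapply(config$modifiers$freq, function(f) {
      stats::rbinom(n_pool, 2L, f)
    }, integer(n_pool))
    colnames(mod_g) <- config$modifiers$rsid
    lp <- stats::qlogis(config$base_prevalence) + config$beta_e4 * e4_dose +
      drop(mod_g %*% log(config$modifiers$main_or)) +
      drop((mod_g * (e4_dose >= 1)) %*% log(config$modifiers$interaction_or))
    pools[[anc]] <- list(anc = anc, h1 = h1, h2 = h2,
                         g429358 = unname(g429358), g7412 = unname(g7412),
                         e4_dose = unname(e4_dose), mod_g = mod_g, lp = lp)
  }

  # rare variants: positions inside the gene intervals, shared population
  # MAFs; non-synonymous ones carry the configured case-enrichment OR
  iv <- gene_intervals()
  rare <- NULL
  if (config$rare_per_gene > 0L) {
    rows <- list()
    for (i in seq_len(nrow(iv))) {
      pos <- sort(sample(seq.int(iv$start[i] + 10L, iv$end[i] - 10L),
                         config$rare_per_gene))
      maf <- stats::runif(config$rare_per_gene, config$rare_maf_range[1L],
                          config$rare_maf_range[2L])
      syn <- stats::runif(config$rare_per_gene) < config$synonymous_fraction
      conseq <- ifelse(syn, "synonymous",
                       sample(c("missense", "stop_gain", "splicing"),
                              config$rare_per_gene, replace = TRUE,
                              prob = c(0.8, 0.1, 0.1)))
      cadd <- ifelse(syn, stats::runif(config$rare_per_gene, 0, 10),
                     stats::runif(config$rare_per_gene, 10, 35))
      rows[[i]] <- data.frame(gene = iv$gene[i], chrom = iv$chrom[i],
                              pos = pos, ref = "A", alt = "G", maf = maf,
                              consequence = conseq,
                              cadd_phred = round(cadd, 1),
                              stringsAsFactors = FALSE)
    }
    rare <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  # background common-SNP panel for relatedness / heterozygosity QC:
  # shared population frequencies, no phenotype effect
  qc_freq <- if (config$n_qc_snps > 0L)
    stats::runif(config$n_qc_snps, 0.1, 0.5) else numeric(0)

  draw_cell <- function(pool, want_case, n_want) {
    y <- pool$y
    idx <- which(y == as.integer(want_case) & !pool$taken)
    if (length(idx) < n_want) {
      stop("infeasible config: only ", length(idx), " ",
           if (want_case) "cases" else "controls", " available for ",
           pool$anc, " (requested ", n_want, "); increase the pool or ",
           "relax the configured odds ratios")
    }
    idx[seq_len(n_want)]
  }

  sample_blocks <- list()
  geno_blocks <- list()
  truth_blocks <- list()
  sid0 <- 0L
  for (anc in config$ancestries) {
    pool <- pools[[anc]]
    n_pool <- length(pool$lp)
    rare_g <- NULL
    burden <- 0
    if (!is.null(rare)) {
      rare_g <- vapply(rare$maf, function(f) stats::rbinom(n_pool, 2L, f),
                       integer(n_pool))
      eff <- rare$consequence != "synonymous"
      burden <- drop(rare_g[, eff, drop = FALSE] %*%
                       rep(log(config$rare_case_or), sum(eff)))
    }
    qc_g <- if (config$n_qc_snps > 0L)
      vapply(qc_freq, function(f) stats::rbinom(n_pool, 2L, f),
             integer(n_pool)) else NULL
    y <- stats::rbinom(n_pool, 1L, stats::plogis(pool$lp + burden))
    pool$y <- y
    pool$taken <- rep(FALSE, n_pool)
    nc <- if (!is.na(config$n_cases[anc])) config$n_cases[anc] else 0L
    nk <- if (!is.na(config$n_controls[anc])) config$n_controls[anc] else 0L
    case_idx <- draw_cell(pool, TRUE, nc)
    pool$taken[case_idx] <- TRUE
    ctrl_idx <- draw_cell(pool, FALSE, nk)
    sel <- c(case_idx, ctrl_idx)
    nb <- length(sel)
    is_case <- c(rep(TRUE, nc), rep(FALSE, nk))
    n_rd <- round(config$related_dementia_fraction * nc)
    phen <- c(rep(c("related_dementia", "AD"), c(n_rd, nc - n_rd)),
              rep("control", nk))
    ids <- sprintf("S%05d", sid0 + seq_len(nb))
    sid0 <- sid0 + nb
    sex <- ifelse(stats::runif(nb) < config$sex_ratio, "male", "female")
    age <- numeric(nb)
    age[is_case] <- round(stats::rnorm(sum(is_case), 72, 8), 1)
    age[!is_case] <- round(65 + stats::rexp(sum(!is_case), 1 / 7), 1)
    pcs <- matrix(round(stats::rnorm(nb * 10, mean = match(anc, ANCESTRIES),
                                     sd = 0.5), 4), nb, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    block <- data.frame(
      sample_id = ids, phenotype = phen, ancestry = anc, sex = sex,
      reported_sex = sex, genetic_sex = sex, age_years = pmax(age, 40),
      age_kind = ifelse(is_case, "onset", "at_study"), dataset = "SYNTH",
      stringsAsFactors = FALSE)
    sample_blocks[[anc]] <- cbind(block, pcs)
    geno_blocks[[anc]] <- cbind(
      pool$g429358[sel], pool$g7412[sel],
      pool$mod_g[sel, , drop = FALSE],
      if (!is.null(rare_g)) rare_g[sel, , drop = FALSE],
      if (!is.null(qc_g)) qc_g[sel, , drop = FALSE])
    truth_blocks[[anc]] <- data.frame(
      sample_id = ids, hap1 = pool$h1[sel], hap2 = pool$h2[sel],
      e4_dose = pool$e4_dose[sel], stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, c(unname(sample_blocks),
                              list(make.row.names = FALSE)))
  gm <- do.call(rbind, unname(geno_blocks))
  rownames(gm) <- samples$sample_id
  colnames(gm) <- NULL

  # variant table: APOE proxies, modifiers (synthetic placements on chr22
  # outside the gene panel), rare variants
  mod_sites <- data.frame(
    rsid = config$modifiers$rsid, chrom = "chr22",
    pos = 10000000L + 1000L * seq_len(nrow(config$modifiers)),
    ref = "C", alt = config$modifiers$effect_allele %||% "T",
    stringsAsFactors = FALSE)
  n_qc <- config$n_qc_snps
  qc_sites <- if (n_qc > 0L) data.frame(
    chrom = "chr20", pos = 1000000L + 100L * seq_len(n_qc), ref = "A",
    alt = "G", stringsAsFactors = FALSE) else NULL
  variants <- data.frame(
    chrom = c(APOE_SITES$chrom, mod_sites$chrom,
              if (!is.null(rare)) rare$chrom else character(0),
              if (n_qc > 0L) qc_sites$chrom else character(0)),
    pos = c(APOE_SITES$pos, mod_sites$pos,
            if (!is.null(rare)) rare$pos else integer(0),
            if (n_qc > 0L) qc_sites$pos else integer(0)),
    ref = c(APOE_SITES$ref, mod_sites$ref,
            if (!is.null(rare)) rare$ref else character(0),
            if (n_qc > 0L) qc_sites$ref else character(0)),
    alt = c(APOE_SITES$alt, mod_sites$alt,
            if (!is.null(rare)) rare$alt else character(0),
            if (n_qc > 0L) qc_sites$alt else character(0)),
    gene = c("APOE", "APOE", rep(NA_character_, nrow(mod_sites)),
             if (!is.null(rare)) rare$gene else character(0),
             rep(NA_character_, n_qc)),
    rsid = c(APOE_SITES$rsid, mod_sites$rsid,
             if (!is.null(rare)) rep(NA_character_, nrow(rare))
             else character(0),
             rep(NA_character_, n_qc)),
    consequence = c("other", "other", rep("other", nrow(mod_sites)),
                    if (!is.null(rare)) rare$consequence else character(0),
                    rep("other", n_qc)),
    cadd_phred = c(NA, NA, rep(NA_real_, nrow(mod_sites)),
                   if (!is.null(rare)) rare$cadd_phred else numeric(0),
                   rep(NA_real_, n_qc)),
    stringsAsFactors = FALSE)
  colnames(gm) <- variant_key(variants$chrom, variants$pos, variants$ref,
                              variants$alt)

  # relatedness plants: duplicates copy all calls; parent-offspring pairs
  # transmit one allele per site and draw the other from the allele freqs
  extra_samples <- list()
  extra_geno <- list()
  plant_pairs <- list()
  site_freq <- colMeans(gm) / 2
  plant_from <- seq_len(min(nrow(gm),
                            config$n_duplicate_pairs +
                              config$n_parent_offspring_pairs))
  k <- 0L
  for (d in seq_len(config$n_duplicate_pairs)) {
    k <- k + 1L
    src <- plant_from[k]
    id <- sprintf("DUP%03d", d)
    extra_samples[[length(extra_samples) + 1L]] <-
      transform(samples[src, , drop = FALSE], sample_id = id)
    extra_geno[[length(extra_geno) + 1L]] <- gm[src, ]
    plant_pairs[[length(plant_pairs) + 1L]] <-
      data.frame(id_i = samples$sample_id[src], id_j = id,
                 relation = "duplicate", stringsAsFactors = FALSE)
  }
  for (d in seq_len(config$n_parent_offspring_pairs)) {
    k <- k + 1L
    src <- plant_from[k]
    id <- sprintf("CHD%03d", d)
    parent <- gm[src, ]
    transmitted <- ifelse(parent == 1L, stats::rbinom(ncol(gm), 1L, 0.5),
                          parent / 2L)
    other <- stats::rbinom(ncol(gm), 1L, site_freq)
    extra_samples[[length(extra_samples) + 1L]] <-
      transform(samples[src, , drop = FALSE], sample_id = id)
    extra_geno[[length(extra_geno) + 1L]] <- as.integer(transmitted + other)
    plant_pairs[[length(plant_pairs) + 1L]] <-
      data.frame(id_i = samples$sample_id[src], id_j = id,
                 relation = "parent_offspring", stringsAsFactors = FALSE)
  }
  if (length(extra_samples) > 0L) {
    samples <- rbind(samples, do.call(rbind, extra_samples))
    gm <- rbind(gm, do.call(rbind, extra_geno))
    rownames(gm) <- samples$sample_id
  }

  if (config$missing_rate > 0) {
    drop_mask <- matrix(stats::runif(length(gm)) < config$missing_rate,
                        nrow(gm), ncol(gm))
    gm[drop_mask] <- NA_integer_
  }

  truth <- list(
    seed = config$seed,
    beta_e4 = config$beta_e4,
    modifiers = config$modifiers,
    rare_case_or = config$rare_case_or,
    diplotypes = do.call(rbind, c(unname(truth_blocks),
                                  list(make.row.names = FALSE))),
    related_pairs = if (length(plant_pairs) > 0L)
      do.call(rbind, c(plant_pairs, list(make.row.names = FALSE))) else NULL)

  out <- list(gm = gm, samples = samples, variants = variants, truth = truth)
  if (!is.null(dir)) out$paths <- write_cohort(out, dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (GT-only VCF 4.2), `manifest.tsv`, `annotation.tsv`
#' and `truth.json`. All writes are deterministic: the same cohort object
#' produces byte-identical files.
#'
#' @param cohort [simulate_cohort()] output.
#' @param dir output directory (created if needed).
#' @return named character vector of paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "cohort.vcf")
  man <- file.path(dir, "manifest.tsv")
  ann <- file.path(dir, "annotation.tsv")
  tru <- file.path(dir, "truth.json")

  v <- cohort$variants
  gm <- cohort$gm
  ord <- order(v$chrom, v$pos, v$alt)
  v <- v[ord, , drop = FALSE]
  gm <- gm[, ord, drop = FALSE]
  gt_str <- matrix("./.", nrow(gm), ncol(gm))
  gt_str[!is.na(gm) & gm == 0L] <- "0/0"
  gt_str[!is.na(gm) & gm == 1L] <- "0/1"
  gt_str[!is.na(gm) & gm == 2L] <- "1/1"
  con <- file(vcf, open = "wb")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##contig=<ID=", unique(v$chrom), ">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "FORMAT", rownames(gm)), collapse = "\t")),
             con, sep = "\n")
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i],
            if (is.na(v$rsid[i])) "." else v$rsid[i], v$ref[i], v$alt[i],
            ".", "PASS", "GT", gt_str[, i]), collapse = "\t")
  }, "")
  writeLines(body, con, sep = "\n")
  close(con)

  write_tsv_stable <- function(df, path) {
    con2 <- file(path, open = "wb")
    utils::write.table(df, con2, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", na = "NA")
    close(con2)
  }
  write_tsv_stable(cohort$samples, man)
  write_tsv_stable(cohort$variants, ann)
  jsonlite::write_json(cohort$truth, tru, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  c(vcf = vcf, manifest = man, annotation = ann, truth = tru)
}

#' Plant a prioritization truth set with single-violation decoys
#'
#' Adds `k` variants guaranteed to be carried by at least one case and no
#' control with CADD above 20, plus three decoys that each violate exactly
#' one sieve criterion: one with a control carrier (CADD 35), one case-only
#' at CADD exactly 20 (strict threshold excludes it), and one case-only
#' synonymous variant (CADD 25).
#'
#' @param cohort [simulate_cohort()] output.
#' @param k number of true planted variants.
#' @param gene gene whose interval hosts the planted positions.
#' @return the cohort with extra columns and `truth$planted` listing the
#'   true keys and `truth$decoys` the decoy keys.
#' @export
plant_prioritization_truth <- function(cohort, k = 5L, gene = "APP") {
  iv <- gene_intervals()
  iv <- iv[iv$gene == gene, ]
  is_case <- cohort$samples$phenotype != "control"
  case_idx <- which(is_case)
  ctrl_idx <- which(!is_case)
  stopifnot(length(case_idx) >= 1L, length(ctrl_idx) >= 1L)
  n <- nrow(cohort$gm)
  specs <- list()
  for (i in seq_len(k)) {
    specs[[i]] <- list(tag = "planted", cadd = 20.5 + 2 * i,
                       conseq = "missense",
                       carriers = case_idx[1 + (i - 1) %% length(case_idx)])
  }
  specs[[k + 1L]] <- list(tag = "decoy_control_carrier", cadd = 35,
                          conseq = "missense",
                          carriers = c(case_idx[1L], ctrl_idx[1L]))
  specs[[k + 2L]] <- list(tag = "decoy_cadd_at_threshold", cadd = 20,
                          conseq = "missense", carriers = case_idx[1L])
  specs[[k + 3L]] <- list(tag = "decoy_synonymous", cadd = 25,
                          conseq = "synonymous", carriers = case_idx[1L])
  used <- cohort$variants$pos[cohort$variants$chrom == iv$chrom]
  pos_pool <- setdiff(seq.int(iv$start, iv$start + 10L * length(specs) + 50L),
                      used)
  keys <- character(length(specs))
  tags <- character(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    g <- integer(n)
    g[s$carriers] <- 1L
    pos <- pos_pool[i]
    row <- data.frame(chrom = iv$chrom, pos = pos, ref = "A", alt = "T",
                      gene = gene, rsid = NA_character_,
                      consequence = s$conseq, cadd_phred = s$cadd,
                      stringsAsFactors = FALSE)
    cohort$variants <- rbind(cohort$variants, row)
    cohort$gm <- cbind(cohort$gm, g)
    keys[i] <- variant_key(iv$chrom, pos, "A", "T")
    tags[i] <- s$tag
    colnames(cohort$gm)[ncol(cohort$gm)] <- keys[i]
  }
  cohort$truth$planted <- keys[tags == "planted"]
  cohort$truth$decoys <- stats::setNames(keys[tags != "planted"],
                                         tags[tags != "planted"])
  cohort
}

#' Load a packaged fixture table
#'
#' `printed_catalog` is the machine-readable transcription of the published
#' discovery-phase variant catalog (per-dataset rows with gene, position,
#' alleles, CADD, ancestry, known/novel status and cross-database
#' replication markers); `modifier_variants` is the 21-variant
#' protective/resilience panel; `toy_weights` is a small synthetic PRS
#' weight panel.
#'
#' @param name one of "printed_catalog", "modifier_variants", "toy_weights".
#' @return data.frame.
#' @export
load_fixture <- function(name = c("printed_catalog", "modifier_variants",
                                  "toy_weights")) {
  name <- match.arg(name)
  file <- switch(name, printed_catalog = "printed_catalog.tsv",
                 modifier_variants = "modifier_variants.tsv",
                 toy_weights = "toy_prs_weights.tsv")
  path <- system.file("extdata", file, package = "demcatalog")
  if (name == "toy_weights") return(read_prs_weights(path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}
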