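#' Per-sample genotype call rate
#'
#' @param gm genotype matrix (samples x variants, values 0/1/2/NA).
#' @param threshold samples with rate strictly below this are flagged
#'   (default 0.95, matching the sample-level QC rule).
#' @return data.frame with `sample_id`, `call_rate`, `excluded`.
#' @export
sample_call_rate <- function(gm, threshold = 0.95) {
  if (ncol(gm) < 1L) stop("call rate undefined: genotype matrix has no variants")
  rate <- rowMeans(!is.na(gm))
  data.frame(sample_id = rownames(gm), call_rate = rate,
             excluded = rate < threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-sample excess-heterozygosity statistic F
#'
#' F = 1 - observed het / expected het, where the expectation sums
#' 2 p_j (1 - p_j) over the sample's non-missing variants using cohort-wide
#' alternate-allele frequencies p_j. Samples with |F| above the threshold
#' (default 0.25) are flagged; samples whose expected heterozygosity is zero
#' (all their called sites monomorphic) get NA with a warning.
#'
#' @param gm genotype matrix (samples x variants, 0/1/2/NA).
#' @param threshold exclusion threshold on |F|.
#' @return data.frame with `sample_id`, `het_F`, `excluded`.
#' @export
heterozygosity_F <- function(gm, threshold = 0.25) {
  p <- colMeans(gm, na.rm = TRUE) / 2
  ehet_site <- 2 * p * (1 - p)
  called <- !is.na(gm)
  o_het <- rowSums(gm == 1, na.rm = TRUE)
  e_het <- as.vector(called %*% ehet_site)
  f <- ifelse(e_het > 0, 1 - o_het / e_het, NA_real_)
  if (anyNA(f)) {
    warning("F undefined for ", sum(is.na(f)),
            " sample(s): no polymorphic called sites")
  }
  data.frame(sample_id = rownames(gm), het_F = f,
             excluded = !is.na(f) & abs(f) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Robust pairwise kinship coefficient (heterozygote/opposite-homozygote form)
#'
#' phi-hat = (N_het,het - 2 N_opposite-hom) / (N_het(i) + N_het(j)), computed
#' over variants non-missing in both samples. Approximately 0.5 for
#' duplicates/MZ twins, 0.25 for parent-offspring, 0 for unrelated pairs.
#'
#' @param gi,gj genotype vectors (0/1/2/NA) for the two samples.
#' @return kinship estimate, or NA (with warning) if the denominator is zero.
#' @export
kinship_phi <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  denom <- sum(gi == 1) + sum(gj == 1)
  if (denom == 0L) {
    warning("kinship undefined: no heterozygous calls in either sample")
    return(NA_real_)
  }
  (n_hh - 2 * n_opp) / denom
}

#' All pairwise kinship coefficients for a cohort
#'
#' Every pair is computed (no pre-screen shortcut); the counting is done
#' with dense matrix products, so cohorts of a few thousand samples take
#' seconds. Pairs with an undefined estimate (no heterozygous calls in
#' either member over the jointly non-missing sites) are returned as NA
#' with a single warning.
#'
#' @param gm genotype matrix (samples x variants).
#' @return data.frame with `id_i`, `id_j`, `phi` (i < j in sample order).
#' @export
kinship_pairs <- function(gm) {
  n <- nrow(gm)
  ids <- rownames(gm)
  M <- (!is.na(gm)) * 1
  G <- gm
  G[is.na(G)] <- -1L
  H <- (G == 1L) * 1
  A0 <- (G == 0L) * 1
  A2 <- (G == 2L) * 1
  n_hh <- tcrossprod(H)
  opp <- tcrossprod(A0, A2)
  n_opp <- opp + t(opp)
  hm <- tcrossprod(H, M)
  denom <- hm + t(hm)
  phi <- (n_hh - 2 * n_opp) / denom
  iu <- which(upper.tri(phi), arr.ind = TRUE)
  out <- data.frame(id_i = ids[iu[, 1L]], id_j = ids[iu[, 2L]],
                    phi = phi[iu], stringsAsFactors = FALSE)
  out$phi[!is.finite(out$phi)] <- NA_real_
  if (anyNA(out$phi)) {
    warning("kinship undefined for ", sum(is.na(out$phi)),
            " pair(s): no heterozygous calls")
  }
  out <- out[order(iu[, 1L], iu[, 2L]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy relatedness pruning
#'
#' Repeatedly drops the sample participating in the most pairs above the
#' kinship threshold (default 0.0884, the cousin-level cutoff); ties are
#' broken by lower call rate, then lexicographically smaller sample id, so
#' the exclusion set is deterministic and order-independent. On exit no
#' retained pair exceeds the threshold.
#'
#' @param pairs data.frame with `id_i`, `id_j`, `phi`.
#' @param call_rates named numeric vector of per-sample call rates (used for
#'   tie-breaking; missing samples count as call rate 1).
#' @param threshold kinship cutoff.
#' @return character vector of excluded sample ids (possibly empty).
#' @export
prune_related <- function(pairs, call_rates = NULL, threshold = 0.0884) {
  pairs <- pairs[!is.na(pairs$phi) & pairs$phi > threshold, , drop = FALSE]
  excluded <- character(0)
  while (nrow(pairs) > 0L) {
    ids <- c(pairs$id_i, pairs$id_j)
    deg <- table(ids)
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1L) {
      cr <- if (is.null(call_rates)) rep(1, length(cand)) else {
        out <- call_rates[cand]
        out[is.na(out)] <- 1
        out
      }
      cand <- cand[cr == min(cr)]
      cand <- sort(cand)[1L]
    }
    excluded <- c(excluded, cand)
    keep <- pairs$id_i != cand & pairs$id_j != cand
    pairs <- pairs[keep, , drop = FALSE]
  }
  sort(excluded)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the allele counts:
#' the p-value sums the probabilities of all heterozygote counts no more
#' probable than the observed one (two-sided by probability ordering; no
#' mid-p correction). Monomorphic sites return 1 by convention.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom - order
#'   does not matter).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) stop("no genotypes")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_het) up to a constant: multinomial x 2^het given allele counts
  lp <- hets * log(2) + lgamma(n + 1) -
    (lgamma((n_a - hets) / 2 + 1) + lgamma(hets + 1) +
       lgamma((n_b - hets) / 2 + 1))
  lp <- lp - max(lp)
  prob <- exp(lp) / sum(exp(lp))
  obs <- prob[hets == n_ab]
  min(1, sum(prob[prob <= obs * (1 + 1e-10)]))
}

#' Differential missingness test between cases and controls
#'
#' Two-sided Fisher exact test on the 2x2 missing/called x case/control
#' table for one variant.
#'
#' @param miss_case,called_case,miss_ctrl,called_ctrl cell counts.
#' @return two-sided p-value.
#' @export
diff_missingness_test <- function(miss_case, called_case, miss_ctrl, called_ctrl) {
  if (miss_case + called_case == 0L || miss_ctrl + called_ctrl == 0L) {
    stop("both case and control groups must be non-empty")
  }
  tab <- matrix(c(miss_case, called_case, miss_ctrl, called_ctrl), nrow = 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Variant-level quality control report
#'
#' Applies the variant filters: call rate, Hardy-Weinberg exact test in
#' controls (p < `hwe_p`), differential missingness by case/control status
#' (p <= `diff_miss_p`) and an optional minor-allele-frequency floor.
#' Per-cohort profiles differ in thresholds; all are arguments.
#'
#' @param gm genotype matrix (samples x variants).
#' @param samples manifest data.frame aligned with `rownames(gm)`.
#' @param call_rate_min variant call-rate threshold (strictly below fails).
#' @param hwe_p HWE exact p threshold in controls (strictly below fails).
#' @param diff_miss_p differential-missingness threshold (at or below fails).
#' @param maf_min optional MAF floor (variants strictly below are flagged);
#'   NULL disables the filter.
#' @return data.frame, one row per variant, with statistics, `excluded`
#'   and a semicolon-joined `exclusion_reasons` column.
#' @export
variant_qc <- function(gm, samples, call_rate_min = 0.95, hwe_p = 1e-4,
                       diff_miss_p = 1e-4, maf_min = NULL) {
  stopifnot(identical(rownames(gm), samples$sample_id))
  is_case <- samples$phenotype != "control"
  if (!any(is_case) || !any(!is_case)) {
    stop("degenerate cohort: need at least one case and one control for variant QC")
  }
  ctrl <- gm[!is_case, , drop = FALSE]
  out <- lapply(seq_len(ncol(gm)), function(j) {
    g <- gm[, j]
    rate <- mean(!is.na(g))
    af <- mean(g, na.rm = TRUE) / 2
    maf <- if (is.nan(af)) NA_real_ else min(af, 1 - af)
    gc <- ctrl[, j]
    gc <- gc[!is.na(gc)]
    hwe <- if (length(gc) == 0L) 1 else
      hwe_exact_test(sum(gc == 0), sum(gc == 1), sum(gc == 2))
    dm <- diff_missingness_test(sum(is.na(gm[is_case, j])),
                                sum(!is.na(gm[is_case, j])),
                                sum(is.na(gm[!is_case, j])),
                                sum(!is.na(gm[!is_case, j])))
    reasons <- character(0)
    if (rate < call_rate_min) reasons <- c(reasons, "low_call_rate")
    if (hwe < hwe_p) reasons <- c(reasons, "hwe_controls")
    if (dm <= diff_miss_p) reasons <- c(reasons, "differential_missingness")
    if (!is.null(maf_min) && !is.na(maf) && maf < maf_min)
      reasons <- c(reasons, "low_maf")
    data.frame(variant = colnames(gm)[j], call_rate = rate,
               hwe_p_controls = hwe, diff_missingness_p = dm, maf = maf,
               excluded = length(reasons) > 0L,
               exclusion_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample-level quality control report
#'
#' Combines call rate, heterozygosity F, the reported-vs-genetic sex label
#' comparison, and relatedness pruning into one exclusion report.
#'
#' @param gm genotype matrix (samples x variants).
#' @param samples manifest data.frame aligned with `rownames(gm)`; a
#'   `genetic_sex` column (same vocabulary as `sex`) enables the sex check.
#' @param call_rate_min,het_f_max,kinship_max thresholds.
#' @return data.frame, one row per sample, with statistics, `excluded` and
#'   `exclusion_reasons`.
#' @export
sample_qc <- function(gm, samples, call_rate_min = 0.95, het_f_max = 0.25,
                      kinship_max = 0.0884) {
  stopifnot(identical(rownames(gm), samples$sample_id))
  cr <- sample_call_rate(gm, threshold = call_rate_min)
  hf <- suppressWarnings(heterozygosity_F(gm, threshold = het_f_max))
  sex_mismatch <- if ("genetic_sex" %in% names(samples)) {
    !is.na(samples$genetic_sex) & samples$genetic_sex != "unknown" &
      samples$reported_sex != "unknown" &
      samples$genetic_sex != samples$reported_sex
  } else rep(FALSE, nrow(samples))
  related <- prune_related(kinship_pairs(gm),
                           stats::setNames(cr$call_rate, cr$sample_id),
                           threshold = kinship_max)
  reasons <- mapply(function(id, a, b, c) {
    r <- character(0)
    if (a) r <- c(r, "low_call_rate")
    if (b) r <- c(r, "excess_heterozygosity")
    if (c) r <- c(r, "sex_mismatch")
    if (id %in% related) r <- c(r, "relatedness")
    paste(r, collapse = ";")
  }, cr$sample_id, cr$excluded, hf$excluded, sex_mismatch)
  data.frame(sample_id = cr$sample_id, call_rate = cr$call_rate,
             het_F = hf$het_F, sex_mismatch = sex_mismatch,
             excluded = nzchar(reasons),
             exclusion_reasons = unname(reasons),
             row.names = NULL, stringsAsFactors = FALSE)
}
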