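#' Read a PRS weights table
#'
#' Tab-separated with columns `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`. Comment lines start with `#`.
#'
#' @param path weights TSV.
#' @return validated data.frame.
#' @export
read_prs_weights <- function(path) {
  w <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols) > 0L) {
    stop("weights file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(w$chrom, w$pos, sep = ":")
  if (anyDuplicated(key)) stop("duplicate variant keys in weights file")
  if (any(!is.finite(w$beta))) stop("non-finite beta in weights file")
  w
}

#' Weighted-allele polygenic risk score
#'
#' raw score = sum over matched variants of dosage x beta. Weight rows are
#' matched to genotype variants by (chrom, pos) with an allele-orientation
#' check: when effect/other alleles are swapped relative to the genotype
#' ref/alt, the dosage is flipped (2 - d); rows whose alleles match neither
#' orientation are dropped with a message. Missing dosages are mean-imputed
#' per variant. Z-scores are standardized over the scored samples and the
#' top quartile flagged by [top_quartile_subset()]'s threshold rule.
#'
#' @param gm genotype matrix (samples x variants, alt-allele dose) whose
#'   column names are `chrom:pos:ref:alt` keys.
#' @param weights data.frame from [read_prs_weights()].
#' @return data.frame with `sample_id`, `raw_score`, `z_score`,
#'   `top_quartile`; matched/dropped counts as attributes.
#' @export
score_prs <- function(gm, weights) {
  parts <- strsplit(colnames(gm), ":", fixed = TRUE)
  gkey <- vapply(parts, function(p) paste(p[1L], p[2L], sep = ":"), "")
  ref <- vapply(parts, `[`, "", 3L)
  alt <- vapply(parts, `[`, "", 4L)
  wkey <- paste(weights$chrom, weights$pos, sep = ":")
  idx <- match(wkey, gkey)
  matched <- 0L
  dropped <- 0L
  contrib <- matrix(0, nrow(gm), 0)
  betas <- numeric(0)
  for (i in seq_along(wkey)) {
    j <- idx[i]
    if (is.na(j)) next
    d <- gm[, j]
    if (weights$effect_allele[i] == alt[j] &&
        weights$other_allele[i] == ref[j]) {
      # orientation matches: dose counts effect allele
    } else if (weights$effect_allele[i] == ref[j] &&
               weights$other_allele[i] == alt[j]) {
      d <- 2 - d
    } else {
      dropped <- dropped + 1L
      message("allele mismatch for ", wkey[i], "; row dropped")
      next
    }
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    contrib <- cbind(contrib, d)
    betas <- c(betas, weights$beta[i])
    matched <- matched + 1L
  }
  if (matched < 1L) stop("no weight variants matched the genotype data")
  raw <- drop(contrib %*% betas)
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else
    rep(0, length(raw))
  out <- data.frame(sample_id = rownames(gm), raw_score = raw, z_score = z,
                    stringsAsFactors = FALSE)
  out$top_quartile <- out$sample_id %in% top_quartile_subset(out)
  attr(out, "n_matched") <- matched
  attr(out, "n_dropped") <- dropped
  out
}

#' Select the top-quartile (highest genetic risk) samples
#'
#' Nearest-rank rule from the top: the threshold is the k-th largest raw
#' score with k = ceiling(n / 4), and every sample at or above it is
#' selected, so ties at the boundary are all included and at least 25% of
#' scored samples are selected. Invariant to sample order.
#'
#' @param results data.frame from [score_prs()] (`sample_id`, `raw_score`).
#' @return character vector of selected sample ids.
#' @export
top_quartile_subset <- function(results) {
  n <- nrow(results)
  k <- ceiling(n / 4)
  thr <- sort(results$raw_score, decreasing = TRUE)[k]
  sort(results$sample_id[results$raw_score >= thr])
}

#' Modifier-variant enrichment within the high-PRS stratum
#'
#' Per-modifier logistic regression of case status on effect-allele dosage
#' within the top-quartile subset, under one of two covariate sets:
#' A = PRS z-score + sex + age + PC1-5; B = A plus APOE status coded as the
#' e4 allele dose. Modifiers with zero carriers in the subset are reported
#' untestable.
#'
#' @param subset_ids sample ids of the high-PRS stratum.
#' @param modifier_gm genotype matrix (samples x modifiers, rsID columns).
#' @param samples manifest data.frame with PC columns.
#' @param prs [score_prs()] output.
#' @param diplotypes [call_diplotype()] output (needed for set B).
#' @param covariate_set "A" or "B".
#' @return data.frame, one row per modifier, ModelFit columns plus
#'   `testable`.
#' @export
modifier_enrichment <- function(subset_ids, modifier_gm, samples, prs,
                                diplotypes = NULL,
                                covariate_set = c("A", "B")) {
  covariate_set <- match.arg(covariate_set)
  sel <- samples$sample_id %in% subset_ids
  samples <- samples[sel, , drop = FALSE]
  modifier_gm <- modifier_gm[sel, , drop = FALSE]
  z <- prs$z_score[match(samples$sample_id, prs$sample_id)]
  y <- as.numeric(samples$phenotype != "control")
  pc_cols <- paste0("PC", 1:5)
  pc_cols <- pc_cols[pc_cols %in% names(samples)]
  base <- cbind(intercept = 1, z = z,
                sex = as.numeric(samples$sex == "male"),
                age = samples$age_years,
                as.matrix(samples[, pc_cols, drop = FALSE]))
  if (covariate_set == "B") {
    if (is.null(diplotypes)) stop("covariate set B needs APOE diplotypes")
    e4 <- diplotypes$e4_dose[sel]
    base <- cbind(base, apoe = e4)
  }
  out <- lapply(colnames(modifier_gm), function(rs) {
    d <- modifier_gm[, rs]
    ok <- !is.na(d) & stats::complete.cases(base)
    if (sum(d[ok] > 0, na.rm = TRUE) == 0L) {
      return(data.frame(rsid = rs, testable = FALSE, beta = NA_real_,
                        se = NA_real_, wald_z = NA_real_, p = NA_real_,
                        odds_ratio = NA_real_, converged = FALSE,
                        diagnostic = "no_carriers_in_subset",
                        n_used = sum(ok), stringsAsFactors = FALSE))
    }
    fit <- logistic_fit(y[ok], cbind(dosage = d[ok],
                                     base[ok, , drop = FALSE]))
    row <- model_fit_row(fit, "enrichment", "top_quartile")
    data.frame(rsid = rs, testable = TRUE, beta = row$beta, se = row$se,
               wald_z = row$wald_z, p = row$p, odds_ratio = row$odds_ratio,
               converged = row$converged, diagnostic = row$diagnostic,
               n_used = row$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
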