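#' Packaged table of the 21 protective / resilience variants
#'
#' Eleven protective and ten resilience (disease-modifying) variants
#' reported for Alzheimer's disease, keyed by rsID with their locus,
#' effect allele and class. Genomic placements are not part of this table;
#' the synthetic-data generator assigns synthetic coordinates and real
#' analyses match by rsID against the user's annotation.
#'
#' @return data.frame with columns `rsid`, `locus`, `effect_allele`, `klass`.
#' @export
modifier_variants <- function() {
  path <- system.file("extdata", "modifier_variants.tsv",
                      package = "demcatalog")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(sum(tab$klass == "protective") == 11L,
            sum(tab$klass == "resilient") == 10L)
  tab
}

#' Carrier frequencies of modifier variants across APOE strata
#'
#' A carrier holds at least one effect allele (heterozygous or homozygous).
#' For every modifier x ancestry x phenotype combination, rows are produced
#' for the three denominators: the total population, total e4/e4 carriers,
#' and total e4 carriers (heterozygous or homozygous). Only rows with a
#' nonzero denominator are emitted. Modifiers absent from the genotype data
#' produce a warning and all-missing rows.
#'
#' @param modifier_gm genotype matrix (samples x modifiers, effect-allele
#'   dose 0/1/2/NA) with rsIDs as column names.
#' @param diplotypes [call_diplotype()] output aligned with rows.
#' @param samples manifest data.frame aligned with rows.
#' @return data.frame with `rsid`, `ancestry`, `phenotype`,
#'   `denominator_kind`, `n_carriers`, `denominator_n`, `proportion`.
#' @export
carrier_frequencies <- function(modifier_gm, diplotypes, samples) {
  stopifnot(nrow(modifier_gm) == nrow(samples),
            nrow(diplotypes) == nrow(samples))
  strata <- list(total_population = rep(TRUE, nrow(samples)),
                 total_e4e4 = diplotypes$is_e4e4,
                 total_e4_carriers = diplotypes$is_e4_carrier)
  groups <- unique(samples[, c("ancestry", "phenotype")])
  groups <- groups[order(groups$ancestry, groups$phenotype), , drop = FALSE]
  out <- list()
  for (rs in colnames(modifier_gm)) {
    g <- modifier_gm[, rs]
    if (all(is.na(g))) {
      warning("modifier ", rs, " has no genotype calls; reporting missing")
    }
    for (i in seq_len(nrow(groups))) {
      in_group <- samples$ancestry == groups$ancestry[i] &
        samples$phenotype == groups$phenotype[i]
      for (kind in names(strata)) {
        sel <- in_group & strata[[kind]] & !is.na(g)
        denom <- sum(sel)
        if (denom == 0L && !all(is.na(g))) next
        out[[length(out) + 1L]] <- data.frame(
          rsid = rs, ancestry = groups$ancestry[i],
          phenotype = groups$phenotype[i], denominator_kind = kind,
          n_carriers = if (denom > 0L) sum(g[sel] > 0) else NA_integer_,
          denominator_n = denom,
          proportion = if (denom > 0L) sum(g[sel] > 0) / denom else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Iteratively reweighted least squares with convergence declared when the
#' maximum absolute score falls below 1e-8 or the relative deviance change
#' below 1e-10 (at most 100 iterations). Standard errors come from the
#' observed information. Constant predictor columns (beyond one intercept)
#' are screened out and listed in `dropped_columns`; complete separation
#' (diverging coefficients with a non-vanishing gradient) and rank
#' deficiency are detected and reported as `converged = FALSE` with a
#' diagnostic, never as silent output.
#'
#' @param y binary response vector (0/1).
#' @param X design matrix including the intercept column.
#' @return list with `coef`, `se`, `wald_z`, `p`, `converged`, `diagnostic`,
#'   `n_used`, `deviance`, `fitted`, `vcov`.
#' @export
logistic_fit <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X)) stop("need more observations than parameters")
  # internal screening: constant columns other than one intercept are
  # dropped and reported, not fitted
  constant <- apply(X, 2, function(col) all(col == col[1L]))
  dropped_columns <- character(0)
  if (sum(constant) > 1L) {
    keep_first <- which(constant)[1L]
    drop_idx <- setdiff(which(constant), keep_first)
    dropped_columns <- colnames(X)[drop_idx]
    X <- X[, -drop_idx, drop = FALSE]
    constant <- constant[-drop_idx]
  }
  if (any(constant) && all(X[, which(constant)[1L]] == 0)) {
    stop("constant zero column cannot serve as intercept")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    return(list(coef = rep(NA_real_, ncol(X)), se = NULL, wald_z = NULL,
                p = NULL, converged = FALSE, diagnostic = "collinear",
                n_used = nrow(X), deviance = NA_real_, fitted = NULL,
                vcov = NULL, dropped_columns = dropped_columns))
  }
  p <- ncol(X)
  beta <- numeric(p)
  if (any(constant)) {
    mu0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
    i0 <- which(constant)[1L]
    beta[i0] <- log(mu0 / (1 - mu0)) / X[1L, i0]
  }
  dev_old <- Inf
  diagnostic <- ""
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (max(abs(score)) < 1e-8 ||
        (is.finite(dev_old) && abs(dev_old - dev) / (abs(dev) + 0.1) < 1e-10)) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20 && max(abs(score)) > 1e-4) {
      diagnostic <- "separation"
      break
    }
    dev_old <- dev
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      diagnostic <- "singular_information"
      break
    }
    # step-halving to keep the deviance decreasing
    for (h in 0:5) {
      beta_new <- beta + step / 2^h
      mu_new <- pmin(pmax(stats::plogis(drop(X %*% beta_new)), 1e-12), 1 - 1e-12)
      dev_new <- -2 * sum(y * log(mu_new) + (1 - y) * log(1 - mu_new))
      if (dev_new <= dev + 1e-8) break
    }
    beta <- beta_new
  }
  if (!converged && diagnostic == "") diagnostic <- "max_iterations"
  if (converged && max(abs(beta)) > 20 && max(abs(score)) > 1e-4) {
    converged <- FALSE
    diagnostic <- "separation"
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  info <- crossprod(X * (mu * (1 - mu)), X)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, p) else sqrt(diag(vc))
  z <- beta / se
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       wald_z = stats::setNames(z, colnames(X)),
       p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
       converged = converged, diagnostic = diagnostic,
       n_used = nrow(X),
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)),
       fitted = mu, vcov = vc, dropped_columns = dropped_columns)
}

# shared design-matrix builder: dosage + sex + age + PCs
modifier_design <- function(dosage, samples, n_pcs = 10L, extra = NULL) {
  pc_cols <- paste0("PC", seq_len(n_pcs))
  pc_cols <- pc_cols[pc_cols %in% names(samples)]
  X <- cbind(intercept = 1, dosage = dosage,
             sex = as.numeric(samples$sex == "male"),
             age = samples$age_years)
  if (length(pc_cols) > 0L) {
    X <- cbind(X, as.matrix(samples[, pc_cols, drop = FALSE]))
  }
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

model_fit_row <- function(fit, model, stratum, term = "dosage") {
  if (!fit$converged || is.null(fit$p)) {
    return(data.frame(model = model, stratum = stratum, term = term,
                      beta = NA_real_, se = NA_real_, wald_z = NA_real_,
                      p = NA_real_, odds_ratio = NA_real_,
                      converged = fit$converged,
                      diagnostic = fit$diagnostic, n_used = fit$n_used,
                      stringsAsFactors = FALSE))
  }
  data.frame(model = model, stratum = stratum, term = term,
             beta = fit$coef[term], se = fit$se[term],
             wald_z = fit$wald_z[term], p = fit$p[term],
             odds_ratio = exp(fit$coef[term]), converged = TRUE,
             diagnostic = "", n_used = fit$n_used,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Protective model: modifier main effect on case status
#'
#' logit(case) ~ dosage + sex + age + PCs over the whole cohort (fitted per
#' ancestry by the analysis drivers). Dosage is the additive 0/1/2 count of
#' the effect allele by default; `carrier_coding = TRUE` collapses to 0/1.
#'
#' @param dosage effect-allele dose vector (0/1/2/NA).
#' @param samples manifest with `phenotype`, `sex`, `age_years`, PCs.
#' @param n_pcs number of principal components to adjust for.
#' @param carrier_coding use carrier (0/1) instead of additive coding.
#' @return one-row ModelFit data.frame plus the full fit as attribute `fit`.
#' @export
protective_model <- function(dosage, samples, n_pcs = 10L,
                             carrier_coding = FALSE) {
  ok <- !is.na(dosage)
  dosage <- dosage[ok]
  samples <- samples[ok, , drop = FALSE]
  if (all(dosage == 0)) stop("no carriers of the modifier allele")
  if (carrier_coding) dosage <- as.numeric(dosage > 0)
  y <- as.numeric(samples$phenotype != "control")
  fit <- logistic_fit(y, modifier_design(dosage, samples, n_pcs))
  out <- model_fit_row(fit, "protective", "all")
  attr(out, "fit") <- fit
  out
}

#' Conditional model: modifier effect within an APOE stratum
#'
#' The cohort is restricted to the requested APOE stratum (e4 carriers,
#' e4/e4 homozygotes, or e3/e3) and the protective model refitted there.
#' Strata with fewer than 10 carriers are still fitted but flagged `low_n`.
#'
#' @param dosage effect-allele dose vector.
#' @param samples manifest data.frame.
#' @param diplotypes [call_diplotype()] output aligned with `samples`.
#' @param stratum one of "e4", "e4e4", "e3e3".
#' @param n_pcs number of PCs.
#' @return one-row ModelFit data.frame with a `low_n` column.
#' @export
conditional_model <- function(dosage, samples, diplotypes,
                              stratum = c("e4", "e4e4", "e3e3"),
                              n_pcs = 10L) {
  stratum <- match.arg(stratum)
  sel <- switch(stratum, e4 = diplotypes$is_e4_carrier,
                e4e4 = diplotypes$is_e4e4, e3e3 = diplotypes$is_e3e3)
  sel <- sel & !is.na(dosage)
  y <- as.numeric(samples$phenotype[sel] != "control")
  fit <- logistic_fit(y, modifier_design(dosage[sel],
                                         samples[sel, , drop = FALSE], n_pcs))
  out <- model_fit_row(fit, "conditional", stratum)
  out$low_n <- sum(dosage[sel] > 0, na.rm = TRUE) < 10L
  attr(out, "fit") <- fit
  out
}

#' Interaction model: modifier x APOE product term
#'
#' logit(case) ~ dosage + apoe_indicator + dosage:apoe_indicator + sex +
#' age + PCs, where the APOE indicator is membership of the chosen stratum
#' (e4 carrier, e4/e4, or e3/e3) coded 0/1. The Wald test on the product
#' term is the reported interaction p-value.
#'
#' @inheritParams conditional_model
#' @return one-row ModelFit data.frame for the interaction term.
#' @export
interaction_model <- function(dosage, samples, diplotypes,
                              stratum = c("e4", "e4e4", "e3e3"),
                              n_pcs = 10L) {
  stratum <- match.arg(stratum)
  ind <- switch(stratum, e4 = diplotypes$is_e4_carrier,
                e4e4 = diplotypes$is_e4e4, e3e3 = diplotypes$is_e3e3)
  ok <- !is.na(dosage) & diplotypes$called
  dosage <- dosage[ok]; ind <- as.numeric(ind[ok])
  samples <- samples[ok, , drop = FALSE]
  y <- as.numeric(samples$phenotype != "control")
  extra <- cbind(apoe = ind, dosage_x_apoe = dosage * ind)
  fit <- logistic_fit(y, modifier_design(dosage, samples, n_pcs, extra))
  out <- model_fit_row(fit, "interaction", stratum, term = "dosage_x_apoe")
  attr(out, "fit") <- fit
  out
}

#' Two-locus haplotype frequencies and LD by EM
#'
#' Estimates the four haplotype frequencies between a modifier variant and
#' an APOE proxy SNP from unphased genotypes by
#' expectation-maximization: double heterozygotes are fractionally assigned
#' between the coupling and repulsion phases using the current estimates;
#' convergence when the largest frequency change is below 1e-10 (at most
#' 1000 iterations). Reports r2 = D^2 / (pA pa pB pb) and D'.
#'
#' @param g1,g2 genotype vectors (0/1/2/NA counts of the alternate allele)
#'   at the two sites.
#' @return list with `haplotype_freqs` (AB, Ab, aB, ab where A/B denote the
#'   alternate alleles), `r2`, `d_prime`, `iterations`, `n_used`.
#' @export
ld_r2_em <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2L) stop("need at least 2 jointly called samples")
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(haplotype_freqs = c(AB = NA, Ab = NA, aB = NA, ab = NA),
                r2 = NA_real_, d_prime = NA_real_, iterations = 0L,
                n_used = n))
  }
  dh <- g1 == 1 & g2 == 1     # double heterozygotes: phase-ambiguous
  # haplotype counts known unambiguously from the other eight genotypes
  n_AABB <- sum(g1 == 2 & g2 == 2); n_AABb <- sum(g1 == 2 & g2 == 1)
  n_AAbb <- sum(g1 == 2 & g2 == 0); n_AaBB <- sum(g1 == 1 & g2 == 2)
  n_Aabb <- sum(g1 == 1 & g2 == 0); n_aaBB <- sum(g1 == 0 & g2 == 2)
  n_aaBb <- sum(g1 == 0 & g2 == 1); n_aabb <- sum(g1 == 0 & g2 == 0)
  n_AaBb <- sum(dh)
  base <- c(AB = 2 * n_AABB + n_AABb + n_AaBB,
            Ab = 2 * n_AAbb + n_AABb + n_Aabb,
            aB = 2 * n_aaBB + n_aaBb + n_AaBB,
            ab = 2 * n_aabb + n_aaBb + n_Aabb)
  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: split double heterozygotes between AB/ab and Ab/aB phases
    coupling <- h["AB"] * h["ab"]
    repulsion <- h["Ab"] * h["aB"]
    frac <- if (coupling + repulsion > 0) coupling / (coupling + repulsion)
            else 0.5
    counts <- base + n_AaBb * c(frac, 1 - frac, 1 - frac, frac)
    h_new <- counts / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < 1e-10 || iter >= 1000L) break
  }
  D <- h["AB"] - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(haplotype_freqs = h,
       r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))),
       d_prime = unname(abs(D) / d_max),
       iterations = iter, n_used = n)
}
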