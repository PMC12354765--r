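#' Configuration for gene-level rare-variant burden testing
#'
#' Defaults follow the canonical optimal unified test: variants with
#' MAF <= 0.01, Beta(1, 25) density weights on MAF, and a rho grid
#' {0, 0.1^2, ..., 0.9^2, 1} interpolating between the variance-component
#' kernel test (rho = 0) and the weighted burden test (rho = 1).
#'
#' @param maf_max rare-variant MAF ceiling (inclusive).
#' @param beta_a,beta_b Beta density weight parameters.
#' @param rho_grid correlation grid; must contain 0 and 1 inside [0, 1].
#' @param category functional category: synonymous variants only, or
#'   nonsynonymous excluding known disease-causing variants.
#' @param n_pcs covariate PCs for the null model.
#' @return list of class `burden_config`.
#' @export
burden_config <- function(maf_max = 0.01, beta_a = 1, beta_b = 25,
                          rho_grid = c(0, (seq_len(9) / 10)^2, 1),
                          category = c("nonsynonymous_excluding_known",
                                       "synonymous_only"),
                          n_pcs = 10L) {
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1), 0 %in% rho_grid,
            1 %in% rho_grid)
  structure(list(maf_max = maf_max, beta_a = beta_a, beta_b = beta_b,
                 rho_grid = rho_grid, category = match.arg(category),
                 n_pcs = n_pcs), class = "burden_config")
}

#' Select a gene's rare variants and compute their weights
#'
#' Keeps variants in the gene with MAF at or below the ceiling that match
#' the functional category. For `nonsynonymous_excluding_known`, synonymous
#' variants and any variant whose key appears in the known-variant table are
#' dropped; `synonymous_only` keeps synonymous variants alone. Weights are
#' the Beta(a, b) density evaluated at each variant's MAF.
#'
#' @param gene gene symbol.
#' @param variants annotation data.frame (`gene`, `chrom`, `pos`, `ref`,
#'   `alt`, `consequence`).
#' @param maf named numeric vector of MAFs keyed by variant key.
#' @param config [burden_config()].
#' @param known optional data.frame of known variants (same key columns).
#' @return list with `keys` and `weights`, or NULL (with message attribute)
#'   when the selection is empty.
#' @export
select_rare_variants <- function(gene, variants, maf, config = burden_config(),
                                 known = NULL) {
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  sel <- variants$gene == gene & !is.na(maf[keys]) &
    maf[keys] <= config$maf_max
  if (config$category == "synonymous_only") {
    sel <- sel & variants$consequence == "synonymous"
  } else {
    sel <- sel & variants$consequence != "synonymous"
    if (!is.null(known) && nrow(known) > 0L) {
      kk <- variant_key(known$chrom, known$pos, known$ref, known$alt)
      sel <- sel & !(keys %in% kk)
    }
  }
  if (!any(sel)) {
    message("gene ", gene, " skipped: no rare ", config$category,
            " variants")
    return(NULL)
  }
  k <- keys[sel]
  list(keys = k,
       weights = unname(stats::dbeta(maf[k], config$beta_a, config$beta_b)))
}

#' Null covariate model for score-based burden statistics
#'
#' Fits the logistic null (case status on covariates only) and exposes the
#' residuals y - mu and variance weights mu (1 - mu) needed by the score
#' statistics.
#'
#' @param y binary phenotype vector.
#' @param X covariate design matrix including intercept (NULL for
#'   intercept-only).
#' @return list with `fitted`, `residuals`, `weights`, `X`, `fit`.
#' @export
null_model <- function(y, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  fit <- logistic_fit(y, X)
  if (!fit$converged) stop("null model did not converge: ", fit$diagnostic)
  mu <- fit$fitted
  list(fitted = mu, residuals = y - mu, weights = mu * (1 - mu), X = X,
       fit = fit)
}

# eigenvalues of the projected kernel for a given rho, via the
# covariate-adjusted half-kernel Z = P0^{1/2} G W (computed without any
# n x n matrix)
skat_half_kernel <- function(G, w, null) {
  V <- null$weights
  X <- null$X
  Z <- sqrt(V) * sweep(G, 2, w, `*`)
  XtVX <- crossprod(X * V, X)
  # project out the covariate space in the sqrt(V) metric
  B <- crossprod(X * V, sweep(G, 2, w, `*`))        # p x m
  Z - (sqrt(V) * X) %*% solve(XtVX, B)
}

rho_sqrt_mix <- function(m, rho) {
  # matrix square root of R_rho = (1-rho) I + rho 11' (compound symmetry)
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  diag(a, m) + matrix(b, m, m)
}

get_lambda <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > mean(ev[ev > 0]) * 1e-10]
}

# survival probability of sum(lambda_j chi^2_1) at q: moment matching
# (modified Liu et al.) used as first pass and for quantiles
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), muX = l + d,
       sigmaX = sqrt(2) * sqrt(l + 2 * d), l = l, d = d)
}

liu_pvalue <- function(q, lambda) {
  pr <- liu_params(lambda)
  qx <- (q - pr$muQ) / pr$sigmaQ * pr$sigmaX + pr$muX
  stats::pchisq(qx, df = pr$l, ncp = pr$d, lower.tail = FALSE)
}

# survival probability by numerical inversion of the characteristic
# function (Imhof's formulation) -- the refinement used for small p
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     subdivisions = 2000L, rel.tol = 1e-9,
                     abs.tol = 1e-12)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  min(max(0.5 + val / pi, 1e-14), 1)
}

mixture_pvalue <- function(q, lambda, refine_at = 1e-3) {
  p <- liu_pvalue(q, lambda)
  if (!is.na(p) && p < refine_at) {
    p2 <- imhof_pvalue(q, lambda)
    if (!is.na(p2) && p2 > 0) p <- p2
  }
  p
}

#' Variance-component score statistic Q_rho and its analytic p-value
#'
#' Q_rho = (y - mu)' G W R_rho W G' (y - mu) with W = diag(w) and
#' R_rho = (1 - rho) I + rho 11'. The null distribution is the mixture of
#' chi-squares whose weights are the eigenvalues of the covariate-projected
#' kernel; p-values come from moment matching with a characteristic-function
#' refinement when p < 1e-3.
#'
#' @param G rare-variant genotype matrix (samples x variants), columns
#'   aligned with `w`; missing entries should be imputed beforehand.
#' @param w variant weight vector.
#' @param null [null_model()] output.
#' @param rho correlation parameter in [0, 1].
#' @return list with `Q`, `p`, `lambda`.
#' @export
skat_statistic <- function(G, w, null, rho = 0) {
  G <- as.matrix(G)
  stopifnot(ncol(G) == length(w))
  if (all(G == 0)) stop("no rare alleles in genotype matrix")
  s <- drop(crossprod(sweep(G, 2, w, `*`), null$residuals))
  Q <- (1 - rho) * sum(s^2) + rho * sum(s)^2
  Z <- skat_half_kernel(G, w, null)
  m <- ncol(G)
  R_half <- rho_sqrt_mix(m, rho)
  K <- R_half %*% crossprod(Z) %*% R_half
  lambda <- get_lambda(K)
  # characteristic-function inversion is cheap for a single statistic, so
  # use it whenever it converges; moment matching is the fallback
  list(Q = Q, p = mixture_pvalue(Q, lambda, refine_at = 1), lambda = lambda)
}

#' Optimal unified burden test (SKAT-O)
#'
#' Computes Q_rho and its p-value across the rho grid and combines them via
#' the minimum-p statistic with the standard one-dimensional numerical
#' integration over the shared chi-square(1) component. When the
#' integration fails, the Bonferroni-adjusted minimum p (min p x grid size,
#' capped at 1) is reported and the method flagged.
#'
#' @param G rare-variant genotype matrix (missing entries mean-imputed per
#'   variant unless `impute = FALSE`, in which case rows with missingness
#'   are dropped).
#' @param w weight vector from [select_rare_variants()].
#' @param null [null_model()] output.
#' @param config [burden_config()].
#' @param impute mean-impute missing genotypes (standard behavior).
#' @return list of class `skat_result`: `p_skato`, `rho_grid`, `Q_rho`,
#'   `p_rho`, `rho_min`, `method`, `m_variants`, `converged`.
#' @export
skato <- function(G, w, null, config = burden_config(), impute = TRUE) {
  G <- as.matrix(G)
  if (anyNA(G)) {
    if (impute) {
      for (j in seq_len(ncol(G))) {
        miss <- is.na(G[, j])
        if (any(miss)) G[miss, j] <- mean(G[, j], na.rm = TRUE)
      }
    } else {
      stop("missing genotypes present and impute = FALSE")
    }
  }
  rho_grid <- config$rho_grid
  stats_rho <- lapply(rho_grid, function(r) skat_statistic(G, w, null, r))
  Q_rho <- vapply(stats_rho, `[[`, 0, "Q")
  p_rho <- vapply(stats_rho, `[[`, 0, "p")
  minp <- min(p_rho)
  rho_min <- rho_grid[which.min(p_rho)]
  if (length(rho_grid) == 1L) {
    return(structure(list(p_skato = p_rho, rho_grid = rho_grid,
                          Q_rho = Q_rho, p_rho = p_rho, rho_min = rho_min,
                          method = "single_rho", m_variants = ncol(G),
                          converged = TRUE), class = "skat_result"))
  }
  p_comb <- skato_combine(G, w, null, rho_grid, p_rho, stats_rho)
  if (is.na(p_comb)) {
    p_skato <- min(1, minp * length(rho_grid))
    method <- "min_p_bonferroni_fallback"
    converged <- FALSE
  } else {
    p_skato <- min(1, max(p_comb, minp))
    method <- "integration"
    converged <- TRUE
  }
  structure(list(p_skato = p_skato, rho_grid = rho_grid, Q_rho = Q_rho,
                 p_rho = p_rho, rho_min = rho_min, method = method,
                 m_variants = ncol(G), converged = converged),
            class = "skat_result")
}

# min-p combination: P(min_rho p_rho <= T) by conditioning on the common
# chi-square(1) component of the compound-symmetric kernel
skato_combine <- function(G, w, null, rho_grid, p_rho, stats_rho) {
  Z <- skat_half_kernel(G, w, null)
  m <- ncol(Z)
  # rho = 1 is degenerate in the decomposition; nudge per standard practice
  r_all <- pmin(rho_grid, 0.999)
  z_mean <- rowMeans(Z)
  z_mean_sq <- sum(z_mean^2)
  if (z_mean_sq < 1e-300) return(NA_real_)
  cof <- drop(crossprod(z_mean, Z)) / z_mean_sq
  Z1 <- outer(z_mean, cof)          # projection onto the burden direction
  Z2 <- Z - Z1
  lambda <- get_lambda(crossprod(Z2))
  if (length(lambda) == 0L) return(NA_real_)
  MuQ <- sum(lambda)
  VarRemain <- 4 * sum(crossprod(Z1) * crossprod(Z2))
  VarQ <- 2 * sum(lambda^2) + VarRemain
  tau <- (m^2 * r_all + (1 - r_all) * sum(cof^2)) * z_mean_sq
  # per-rho quantiles of Q_rho at level T = min p (via Liu moment matching)
  T_min <- min(p_rho)
  q_min <- vapply(seq_along(r_all), function(i) {
    pr <- liu_params(stats_rho[[i]]$lambda)
    qx <- stats::qchisq(T_min, df = pr$l, ncp = pr$d, lower.tail = FALSE)
    (qx - pr$muX) / pr$sigmaX * pr$sigmaQ + pr$muQ
  }, 0)
  sd_ratio <- sqrt(VarQ - VarRemain) / sqrt(VarQ)
  integrand <- function(x) {
    vapply(x, function(xi) {
      bound <- min((q_min - tau * xi) / (1 - r_all))
      if (bound > sum(lambda) * 1e4) {
        surv <- 0
      } else {
        # scale toward the mixture's own spread before evaluating its tail
        bstd <- (bound - MuQ) * sd_ratio + MuQ
        surv <- mixture_pvalue(bstd, lambda)
        if (is.na(surv)) surv <- liu_pvalue(bstd, lambda)
        surv <- min(max(surv, 0), 1)
      }
      (1 - surv) * stats::dchisq(xi, df = 1)
    }, 0)
  }
  val <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = 40, subdivisions = 1000L,
                     abs.tol = 1e-25)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  1 - val
}

#' Permutation oracle for burden statistics
#'
#' Recomputes the score statistic under permutation and reports
#' p-hat = (1 + #\{Q_perm >= Q_obs\}) / (B + 1). Two schemes:
#' `"residual"` (default) permutes the null-model residual vector — the
#' reduced-model (Freedman-Lane-style) scheme that is exactly exchangeable
#' for a score statistic and the one the analytic moment approximation
#' [skat_perm_moment_pvalue()] describes; `"label"` permutes phenotype
#' labels within strata of the discretized fitted null probabilities
#' (deciles), which approximates the same null but retains within-stratum
#' fitted-probability jitter.
#'
#' @param G genotype matrix (no missing entries).
#' @param w weight vector.
#' @param y binary phenotype.
#' @param X covariate design matrix (NULL for intercept-only).
#' @param B number of permutations (warning below 100).
#' @param seed RNG seed.
#' @param rho correlation parameter of the permuted statistic.
#' @param scheme permutation scheme, see above.
#' @return list with `p_hat`, `Q_obs`, `B`, `mc_se`, `scheme`.
#' @export
permutation_pvalue <- function(G, w, y, X = NULL, B = 1000L, seed = 1L,
                               rho = 0, scheme = c("residual", "label")) {
  scheme <- match.arg(scheme)
  if (B < 100L) warning("B < 100 permutations gives a coarse p-value")
  null <- null_model(y, X)
  A <- sweep(as.matrix(G), 2, w, `*`)
  score_Q <- function(r) {
    s <- drop(crossprod(A, r))
    (1 - rho) * sum(s^2) + rho * sum(s)^2
  }
  Q_obs <- score_Q(null$residuals)
  set.seed(seed)
  exceed <- 0L
  if (scheme == "residual") {
    for (b in seq_len(B)) {
      if (score_Q(sample(null$residuals)) >= Q_obs - 1e-12) {
        exceed <- exceed + 1L
      }
    }
  } else {
    breaks <- unique(stats::quantile(null$fitted, probs = seq(0, 1, 0.1)))
    strata <- if (length(breaks) < 2L) factor(rep(1L, length(y))) else
      cut(null$fitted, breaks = breaks, include.lowest = TRUE)
    idx_by_stratum <- split(seq_along(y), strata)
    for (b in seq_len(B)) {
      perm <- integer(length(y))
      for (s in idx_by_stratum) perm[s] <- s[sample.int(length(s))]
      if (score_Q(y[perm] - null$fitted) >= Q_obs - 1e-12) {
        exceed <- exceed + 1L
      }
    }
  }
  p_hat <- (1 + exceed) / (B + 1)
  list(p_hat = p_hat, Q_obs = Q_obs, B = B,
       mc_se = sqrt(p_hat * (1 - p_hat) / B), scheme = scheme)
}
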