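test_that("the packaged modifier panel has 11 protective and 10 resilient variants", {
  mv <- modifier_variants()
  expect_equal(nrow(mv), 21L)
  expect_equal(sum(mv$klass == "protective"), 11L)
  expect_equal(sum(mv$klass == "resilient"), 10L)
  expect_false(anyDuplicated(mv$rsid) > 0)
})

test_that("carrier frequencies use the right denominators and stay nested", {
  samples <- make_samples(8, 0)
  # diplotypes: 4 e4 carriers of whom 1 e4/e4; modifier carried by 1 of the
  # e4 carriers and by 1 non-carrier
  d <- call_diplotype(c(2L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), rep(0L, 8))
  mg <- make_gm(matrix(c(0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L), 8, 1),
                sample_ids = samples$sample_id, keys = "rs10423769")
  cf <- carrier_frequencies(mg, d, samples)
  e4 <- cf[cf$denominator_kind == "total_e4_carriers", ]
  expect_equal(e4$proportion, 0.25)       # 1 of 4 e4 carriers
  tot <- cf[cf$denominator_kind == "total_population", ]
  expect_equal(tot$denominator_n, 8L)
  expect_equal(tot$n_carriers, 2L)
  # nesting invariant: e4e4 carriers <= e4 carriers <= total carriers
  e44 <- cf[cf$denominator_kind == "total_e4e4", ]
  expect_lte(e44$n_carriers, e4$n_carriers)
  expect_lte(e4$n_carriers, tot$n_carriers)
  expect_warning(
    carrier_frequencies(make_gm(matrix(NA_integer_, 8, 1),
                                sample_ids = samples$sample_id,
                                keys = "rs121918393"), d, samples),
    "no genotype calls")
})

test_that("logistic IRLS reproduces closed forms and matches glm", {
  # saturated 2x2: beta = log cross-product odds ratio
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  fit <- logistic_fit(y, cbind(intercept = 1, dosage = x))
  expect_equal(unname(fit$coef["dosage"]), log((10 * 95) / (90 * 5)),
               tolerance = 1e-6)
  # intercept-only: logit of the case fraction
  f0 <- logistic_fit(y, matrix(1, 200, 1, dimnames = list(NULL, "intercept")))
  expect_equal(unname(f0$coef), qlogis(0.5), tolerance = 1e-8)
  # full agreement with glm on a multi-covariate fit
  set.seed(31)
  X <- cbind(intercept = 1, a = rnorm(300), b = rbinom(300, 2, 0.3))
  yy <- rbinom(300, 1, plogis(0.2 + 0.5 * X[, "a"] - 0.4 * X[, "b"]))
  ours <- logistic_fit(yy, X)
  ref <- glm(yy ~ X[, "a"] + X[, "b"], family = binomial)
  expect_equal(unname(ours$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(ours$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("separation and collinearity are flagged, never silent", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- y                        # perfect separation
  fit <- logistic_fit(y, cbind(intercept = 1, dosage = x))
  expect_false(fit$converged)
  expect_equal(fit$diagnostic, "separation")
  X <- cbind(intercept = 1, a = rnorm(40), b = 0)
  scr <- logistic_fit(y, X)
  expect_equal(scr$dropped_columns, "b")   # constant column screened out
  Xc <- cbind(intercept = 1, a = 1:40, b = 2 * (1:40))
  fitc <- logistic_fit(y, Xc)
  expect_false(fitc$converged)
  expect_equal(fitc$diagnostic, "collinear")
})

test_that("the protective model recovers a planted main effect", {
  co <- simulate_cohort(sim_config(
    seed = 404, n_cases = c(EUR = 1000L), n_controls = c(EUR = 1000L),
    modifiers = data.frame(rsid = "rs10423769", freq = 0.25, main_or = 0.5,
                           interaction_or = 1), rare_per_gene = 0L))
  dose <- co$gm[, grep("chr22", colnames(co$gm))]
  row <- protective_model(dose, co$samples)
  ci <- row$beta + c(-1.96, 1.96) * row$se
  expect_true(ci[1] <= log(0.5) && log(0.5) <= ci[2])
  expect_lt(row$p, 0.05)
  expect_error(protective_model(rep(0, nrow(co$samples)), co$samples),
               "no carriers")
})

test_that("conditional and interaction models isolate e4-specific effects", {
  # effect planted only multiplicatively with e4 carriage
  co <- simulate_cohort(sim_config(
    seed = 405, n_cases = c(EUR = 1500L), n_controls = c(EUR = 1500L),
    modifiers = data.frame(rsid = "rsX", freq = 0.25, main_or = 1,
                           interaction_or = 2.5), rare_per_gene = 0L))
  dose <- co$gm[, grep("chr22", colnames(co$gm))]
  d <- call_diplotype(co$gm[, "chr19:44908684:T:C"],
                      co$gm[, "chr19:44908822:C:T"])
  e3 <- conditional_model(dose, co$samples, d, "e3e3")
  e4 <- conditional_model(dose, co$samples, d, "e4")
  # no effect among e3/e3; clear effect among e4 carriers
  expect_gt(e3$p, 0.05)
  expect_lt(abs(e3$beta), 0.25)
  expect_lt(e4$p, 0.05)
  expect_gt(e4$beta, 0.3)
  expect_lte(conditional_model(dose, co$samples, d, "e4e4")$n_used, e4$n_used)
  ia <- interaction_model(dose, co$samples, d, "e4")
  expect_lt(ia$p, 0.05)
  expect_gt(ia$beta, 0)
})

test_that("EM linkage disequilibrium matches phased truth and detects extremes", {
  # perfect LD without double heterozygotes
  g <- rbinom(500, 2, 0.3)
  expect_equal(ld_r2_em(g, g)$r2, 1)
  # independent sites
  set.seed(52)
  r2 <- ld_r2_em(rbinom(2000, 2, 0.3), rbinom(2000, 2, 0.4))$r2
  expect_lt(r2, 0.01)
  # phased simulation: EM haplotype frequencies vs direct phased counts
  hapf <- c(AB = 0.15, Ab = 0.25, aB = 0.05, ab = 0.55)
  h1 <- sample(names(hapf), 2000, TRUE, hapf)
  h2 <- sample(names(hapf), 2000, TRUE, hapf)
  g1 <- (substr(h1, 1, 1) == "A") + (substr(h2, 1, 1) == "A")
  g2 <- (substr(h1, 2, 2) == "B") + (substr(h2, 2, 2) == "B")
  em <- ld_r2_em(g1, g2)
  truth <- table(factor(c(h1, h2), levels = names(hapf))) / 4000
  expect_lt(max(abs(em$haplotype_freqs - truth)), 0.01)
  # monomorphic site: undefined, reported as NA
  expect_true(is.na(ld_r2_em(rep(0, 100), rbinom(100, 2, 0.3))$r2))
})
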