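make_rare <- function(n, m, maf_range = c(0.002, 0.01), seed = 1) {
  set.seed(seed)
  maf <- runif(m, maf_range[1], maf_range[2])
  G <- sapply(maf, function(f) rbinom(n, 2, f))
  list(G = G, maf = maf, w = dbeta(maf, 1, 25))
}

test_that("rare-variant selection respects the MAF boundary and category rules", {
  v <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                  gene = "GBA1",
                  consequence = c("missense", "synonymous", "missense",
                                  "missense"), stringsAsFactors = FALSE)
  keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  maf <- setNames(c(0.005, 0.004, 0.011, 0.002), keys)
  known <- v[4, ]
  sel <- select_rare_variants("GBA1", v, maf, burden_config(), known = known)
  expect_equal(sel$keys, keys[1])        # 0.011 out (boundary), syn out, known out
  # weight limit: Beta(1,25) density -> 25 as MAF -> 0
  expect_equal(dbeta(1e-12, 1, 25), 25, tolerance = 1e-9)
  expect_equal(sel$weights, dbeta(0.005, 1, 25))
  syn <- select_rare_variants("GBA1", v, maf,
                              burden_config(category = "synonymous_only"))
  expect_equal(syn$keys, keys[2])
  empty <- select_rare_variants("SNCA", v, maf, burden_config())
  expect_null(empty)
})

test_that("the null model exposes score residuals with the expected identities", {
  set.seed(10)
  y <- rbinom(400, 1, 0.35)
  nm <- null_model(y)
  expect_equal(unique(round(nm$fitted, 10)), round(mean(y), 10))
  X <- cbind(intercept = 1, a = rnorm(400))
  nm2 <- null_model(y, X)
  expect_lt(abs(sum(nm2$residuals)), 1e-6)   # score equation for intercept
  expect_true(all(nm2$fitted > 0 & nm2$fitted < 1))
})

test_that("Q_rho reduces to its closed forms at the grid ends", {
  d <- make_rare(600, 10, seed = 3)
  y <- rbinom(600, 1, 0.3)
  nm <- null_model(y)
  s <- drop(crossprod(sweep(d$G, 2, d$w, `*`), nm$residuals))
  q1 <- skat_statistic(d$G, d$w, nm, rho = 1)
  expect_equal(q1$Q, sum(s)^2)              # squared weighted burden score
  q0 <- skat_statistic(d$G, d$w, nm, rho = 0)
  expect_equal(q0$Q, sum(s^2))
  # single variant at rho 0: exact chi-square(1) score test
  g1 <- d$G[, 1, drop = FALSE]
  one <- skat_statistic(g1, d$w[1], nm, rho = 0)
  U <- sum(g1 * nm$residuals)
  V <- sum(nm$weights * (g1 - mean(g1))^2)
  expect_equal(one$p, pchisq(U^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_error(skat_statistic(matrix(0, 600, 2), c(1, 1), nm), "no rare alleles")
})

test_that("the optimal test obeys its combination bounds and fallbacks", {
  d <- make_rare(800, 15, seed = 4)
  y <- rbinom(800, 1, 0.3)
  nm <- null_model(y)
  res <- skato(d$G, d$w, nm)
  expect_lte(res$p_skato, 1)
  expect_gte(res$p_skato, min(res$p_rho))
  expect_equal(res$method, "integration")
  # grid of size one degenerates to that rho's p-value
  cfg1 <- burden_config()
  cfg1$rho_grid <- 0
  single <- skato(d$G, d$w, nm, cfg1)
  expect_equal(single$p_skato, skat_statistic(d$G, d$w, nm, 0)$p,
               tolerance = 1e-12)
})

test_that("duplicating a zero-carrier variant column changes nothing", {
  d <- make_rare(500, 8, seed = 6)
  y <- rbinom(500, 1, 0.3)
  nm <- null_model(y)
  base <- skato(d$G, d$w, nm)
  G2 <- cbind(d$G, 0)
  w2 <- c(d$w, 25)
  aug <- skato(G2, w2, nm)
  expect_equal(aug$p_rho, base$p_rho, tolerance = 1e-8)
  expect_equal(aug$p_skato, base$p_skato, tolerance = 1e-6)
})

test_that("analytic p-values agree with the permutation oracle", {
  d <- make_rare(800, 15, seed = 12)
  set.seed(13)
  age <- rnorm(800)
  y <- rbinom(800, 1, plogis(-0.5 + 0.3 * age))
  X <- cbind(intercept = 1, age = age)
  nm <- null_model(y, X)
  perm <- permutation_pvalue(d$G, d$w, y, X, B = 3000, seed = 99, rho = 0)
  # the exact-moment conditional p matches within Monte-Carlo error
  cond <- skat_perm_moment_pvalue(d$G, d$w, nm, rho = 0)
  expect_lt(abs(cond$p - perm$p_hat), 2 * perm$mc_se + 0.005)
  # the asymptotic mixture p is close but carries finite-sample error
  analytic <- skat_statistic(d$G, d$w, nm, rho = 0)$p
  expect_lt(abs(analytic - perm$p_hat), 0.03)
  # the label-permutation scheme approximates the same null
  lab <- permutation_pvalue(d$G, d$w, y, X, B = 3000, seed = 99, rho = 0,
                            scheme = "label")
  expect_lt(abs(lab$p_hat - perm$p_hat), 0.03)
  # degenerate oracle cases
  expect_warning(permutation_pvalue(d$G, d$w, y, X, B = 50, seed = 1),
                 "coarse")
})

test_that("planted case enrichment is detected with good power", {
  set.seed(21)
  hits <- replicate(40, {
    d <- make_rare(1500, 12, maf_range = c(0.003, 0.01),
                   seed = sample.int(1e6, 1))
    burden <- drop(d$G %*% rep(log(3), 12))
    y <- rbinom(1500, 1, plogis(qlogis(0.25) + burden))
    skato(d$G, d$w, null_model(y))$p_skato < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
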