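test_that("sample call rate flags samples below threshold", {
  gm <- make_gm(matrix(0L, 2, 10))
  gm[1, 1] <- NA
  cr <- sample_call_rate(gm)
  expect_equal(cr$call_rate, c(0.9, 1))
  expect_equal(cr$excluded, c(TRUE, FALSE))
  expect_false(any(sample_call_rate(gm, threshold = 0)$excluded))
  expect_error(sample_call_rate(gm[, 0, drop = FALSE]), "no variants")
})

test_that("heterozygosity F behaves at its closed-form extremes and under HWE", {
  # all-homozygous sample with positive expected het -> F = 1, excluded
  gm <- make_gm(rbind(c(0L, 2L, 0L, 2L), c(1L, 1L, 1L, 1L),
                      c(1L, 1L, 1L, 1L), c(0L, 1L, 1L, 2L)))
  hf <- heterozygosity_F(gm)
  expect_equal(hf$het_F[1], 1)
  expect_true(hf$excluded[1])
  # HWE cohort: F centred near 0, almost nobody flagged
  set.seed(41)
  p <- runif(200, 0.1, 0.9)
  gsim <- make_gm(sapply(p, function(pp) rbinom(500, 2, pp)))
  hsim <- heterozygosity_F(gsim)
  expect_gte(mean(!hsim$excluded), 0.99)
  expect_lt(abs(mean(hsim$het_F)), 0.02)
})

test_that("kinship phi hits its benchmark values and invariances", {
  set.seed(17)
  g <- rbinom(2000, 2, 0.5)
  expect_equal(kinship_phi(g, g), 0.5)          # duplicates
  # parent-offspring gene-dropping: mean about 0.25
  phis <- replicate(40, {
    par1 <- rbinom(2000, 2, 0.5)
    child <- ifelse(par1 == 1L, rbinom(2000, 1, 0.5), par1 / 2L) +
      rbinom(2000, 1, 0.5)
    kinship_phi(par1, child)
  })
  expect_lt(abs(mean(phis) - 0.25), 0.02)
  # unrelated pairs near zero
  un <- replicate(40, kinship_phi(rbinom(2000, 2, 0.5), rbinom(2000, 2, 0.5)))
  expect_lt(abs(mean(un)), 0.03)
  # symmetry and ref/alt relabeling invariance
  a <- rbinom(500, 2, 0.3); b <- rbinom(500, 2, 0.3)
  expect_equal(kinship_phi(a, b), kinship_phi(b, a))
  flip <- sample(c(TRUE, FALSE), 500, TRUE)
  a2 <- ifelse(flip, 2L - a, a); b2 <- ifelse(flip, 2L - b, b)
  expect_equal(kinship_phi(a, b), kinship_phi(a2, b2))
})

test_that("relatedness pruning is greedy, deterministic and order-independent", {
  # single pair: tie-break by lower call rate
  pairs <- data.frame(id_i = "A", id_j = "B", phi = 0.3)
  expect_equal(prune_related(pairs, c(A = 0.99, B = 0.97)), "B")
  # chain A-B, B-C: brute-force minimum vertex cover removes B only
  trio <- data.frame(id_i = c("A", "B"), id_j = c("B", "C"), phi = 0.3)
  expect_equal(prune_related(trio), "B")
  # below threshold: nothing removed
  expect_length(prune_related(data.frame(id_i = "A", id_j = "B", phi = 0.05)), 0)
  # permuting pair order leaves the exclusion set unchanged
  set.seed(3)
  big <- data.frame(id_i = sample(LETTERS[1:8], 12, TRUE),
                    id_j = sample(LETTERS[9:16], 12, TRUE),
                    phi = runif(12, 0, 0.3))
  ex1 <- prune_related(big)
  ex2 <- prune_related(big[sample(nrow(big)), ])
  expect_identical(ex1, ex2)
})

test_that("HWE exact test matches the full-enumeration oracle", {
  # tiny case enumerable by hand: two carriers of each allele
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)   # monomorphic convention
  cases <- list(c(25, 50, 25), c(40, 20, 40), c(5, 1, 5), c(90, 9, 1),
                c(3, 5, 2))
  for (cc in cases) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_oracle(cc[1], cc[2], cc[3]), tolerance = 1e-10)
  }
})

test_that("HWE exact p-values are super-uniform under the null", {
  set.seed(101)
  B <- 10000
  p <- 0.3
  g <- matrix(rbinom(B * 100, 2, p), nrow = B)
  pv <- vapply(seq_len(B), function(i) {
    gi <- g[i, ]
    hwe_exact_test(sum(gi == 0), sum(gi == 1), sum(gi == 2))
  }, 0)
  expect_lte(mean(pv < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / B))
  expect_lte(mean(pv < 1e-4), 1e-4 + 2 * sqrt(1e-4 / B))
})

test_that("differential missingness test agrees with the hypergeometric tail", {
  expect_equal(diff_missingness_test(2, 8, 2, 8), 1)
  expect_equal(diff_missingness_test(0, 10, 0, 12), 1)
  # (5,5) vs (0,10): two-sided exact p from direct enumeration of tables
  # with fixed margins (row total 5 missing, 10 per group)
  p_impl <- diff_missingness_test(5, 5, 0, 10)
  probs <- dhyper(0:5, 10, 10, 5)
  p_oracle <- sum(probs[probs <= probs[6] * (1 + 1e-7)])
  expect_equal(p_impl, p_oracle, tolerance = 1e-8)
  expect_error(diff_missingness_test(0, 0, 1, 9), "non-empty")
})

test_that("variant QC flags each failure mode with a recorded reason", {
  set.seed(8)
  samples <- make_samples(30, 30)
  gm <- make_gm(matrix(rbinom(60 * 4, 2, 0.4), 60, 4),
                sample_ids = samples$sample_id)
  gm[1:40, 2] <- NA                       # low call rate
  gm[31:60, 3] <- rep(c(0L, 2L), 15)      # HWE failure in controls
  gm[1:30, 4] <- NA                       # differential missingness
  qc <- variant_qc(gm, samples, call_rate_min = 0.9)
  expect_false(qc$excluded[1])
  expect_match(qc$exclusion_reasons[2], "low_call_rate")
  expect_match(qc$exclusion_reasons[3], "hwe_controls")
  expect_match(qc$exclusion_reasons[4], "differential_missingness")
  # degenerate cohort aborts
  allcase <- samples; allcase$phenotype <- "AD"
  expect_error(variant_qc(gm, allcase), "degenerate")
})
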