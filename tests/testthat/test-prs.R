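test_that("scoring is a weighted dosage sum with allele-orientation handling", {
  gm <- make_gm(matrix(c(2L, 0L, 1L), 3, 1), keys = "chr1:100:A:G")
  w <- data.frame(chrom = "chr1", pos = 100L, effect_allele = "G",
                  other_allele = "A", beta = log(2), stringsAsFactors = FALSE)
  res <- score_prs(gm, w)
  expect_equal(res$raw_score, c(2, 0, 1) * log(2))
  expect_equal(mean(res$z_score), 0, tolerance = 1e-12)
  expect_equal(sd(res$z_score), 1, tolerance = 1e-12)
  # swapped effect/other alleles flip the dosage to 2 - d
  w_fl <- transform(w, effect_allele = "A", other_allele = "G")
  res_fl <- score_prs(gm, w_fl)
  expect_equal(res_fl$raw_score, c(0, 2, 1) * log(2))
  # alleles matching neither orientation: dropped, and with nothing left, error
  w_bad <- transform(w, effect_allele = "T", other_allele = "C")
  expect_error(suppressMessages(score_prs(gm, w_bad)), "no weight variants")
})

test_that("PRS is linear in the weight panel and imputes missing dosages", {
  set.seed(61)
  gm <- make_gm(matrix(rbinom(60, 2, 0.4), 20, 3),
                keys = c("chr1:1:A:G", "chr1:2:C:T", "chr2:5:G:A"))
  w <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(1L, 2L, 5L),
                  effect_allele = c("G", "T", "A"),
                  other_allele = c("A", "C", "G"),
                  beta = c(0.3, -0.2, 0.1), stringsAsFactors = FALSE)
  full <- score_prs(gm, w)
  part <- score_prs(gm, w[1:2, ])$raw_score + score_prs(gm, w[3, ])$raw_score
  expect_equal(full$raw_score, part)
  gm[1, 1] <- NA
  imp <- score_prs(gm, w[1, , drop = FALSE])
  expect_equal(imp$raw_score[1], mean(gm[-1, 1]) * 0.3)
})

test_that("top-quartile selection follows the nearest-rank tie rule", {
  res <- data.frame(sample_id = sprintf("S%03d", 1:100),
                    raw_score = 1:100)
  expect_length(top_quartile_subset(res), 25L)
  # all tied: everyone selected
  tied <- transform(res, raw_score = 7)
  expect_length(top_quartile_subset(tied), 100L)
  # order invariance
  expect_identical(top_quartile_subset(res),
                   top_quartile_subset(res[sample(100), ]))
  # at least a quarter always selected
  expect_gte(length(top_quartile_subset(res)) / nrow(res), 0.25)
})

test_that("enrichment models run per modifier within the high-PRS stratum", {
  set.seed(71)
  n <- 600
  samples <- make_samples(n / 2, n / 2)
  mg <- make_gm(cbind(rbinom(n, 2, 0.2), 0L), sample_ids = samples$sample_id,
                keys = c("rs449647", "rs121918393"))
  gmw <- make_gm(matrix(rbinom(n * 3, 2, 0.3), n, 3),
                 sample_ids = samples$sample_id,
                 keys = c("chr1:1:A:G", "chr1:2:C:T", "chr2:5:G:A"))
  w <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(1L, 2L, 5L),
                  effect_allele = c("G", "T", "A"),
                  other_allele = c("A", "C", "G"), beta = c(0.4, 0.2, 0.1),
                  stringsAsFactors = FALSE)
  prs <- score_prs(gmw, w)
  subset_ids <- top_quartile_subset(prs)
  d <- call_diplotype(rbinom(n, 2, 0.15), rbinom(n, 2, 0.07))
  a <- modifier_enrichment(subset_ids, mg, samples, prs, d, "A")
  b <- modifier_enrichment(subset_ids, mg, samples, prs, d, "B")
  expect_equal(a$testable, c(TRUE, FALSE))
  expect_equal(a$diagnostic[2], "no_carriers_in_subset")
  expect_true(is.finite(a$p[1]))
  # covariate set B adds exactly the APOE e4-dose term
  expect_true(all(c("testable", "p") %in% names(b)))
  fit_a <- attr(a, "fit")
  expect_equal(b$n_used[1], a$n_used[1])
})

test_that("null enrichment p-values are approximately uniform", {
  set.seed(81)
  pv <- replicate(150, {
    n <- 400
    samples <- make_samples(n / 2, n / 2)
    mg <- make_gm(matrix(rbinom(n, 2, 0.25), n, 1),
                  sample_ids = samples$sample_id, keys = "rs11556505")
    prs <- data.frame(sample_id = samples$sample_id,
                      raw_score = rnorm(n), z_score = NA)
    prs$z_score <- (prs$raw_score - mean(prs$raw_score)) / sd(prs$raw_score)
    ids <- top_quartile_subset(prs)
    modifier_enrichment(ids, mg, samples, prs, covariate_set = "A")$p
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.5) - 0.5), 0.15)
})
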