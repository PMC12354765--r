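test_that("diplotype calling matches hand enumeration of all nine genotype pairs", {
  # hand-derived truth: haplotypes (rs429358, rs7412) are e4=(C,C),
  # e3=(T,C), e2=(T,T), e1=(C,T); inputs count C at rs429358, T at rs7412
  hand <- list(
    "0,0" = "e3/e3", "0,1" = "e2/e3", "0,2" = "e2/e2",
    "1,0" = "e3/e4", "1,1" = "e2/e4", "1,2" = "e1/e2",
    "2,0" = "e4/e4", "2,1" = "e1/e4", "2,2" = "e1/e1")
  grid <- expand.grid(c429358 = 0:2, t7412 = 0:2)
  got <- call_diplotype(grid$c429358, grid$t7412)
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$c429358[i], grid$t7412[i], sep = ",")
    expect_equal(got$diplotype[i], hand[[key]], info = key)
  }
  expect_equal(got$ambiguous, grid$c429358 == 1 & grid$t7412 == 1)
  expect_equal(got$e4_dose, (got$allele1 == "e4") + (got$allele2 == "e4"))
  expect_equal(got$is_e4_carrier, got$e4_dose >= 1)
  expect_equal(got$is_e3e3, got$diplotype == "e3/e3")
  # missing input gives a no-call, not an error
  nc <- call_diplotype(c(NA, 1), c(0, NA))
  expect_false(any(nc$called))
  expect_true(all(is.na(nc$diplotype)))
})

test_that("frequency tables count per stratum and sum to one", {
  samples <- make_samples(10, 0)
  g429358 <- c(2L, rep(0L, 9))          # one e4/e4, nine e3/e3
  d <- call_diplotype(g429358, rep(0L, 10))
  tab <- apoe_freq_table(d, samples)
  expect_equal(tab$proportion[tab$diplotype == "e4/e4"], 0.1)
  sums <- tapply(tab$proportion, paste(tab$ancestry, tab$phenotype), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # no-calls leave denominators
  d2 <- call_diplotype(c(g429358[-10], NA), rep(0L, 10))
  tab2 <- apoe_freq_table(d2, samples)
  expect_equal(unique(tab2$n_called_group), 9L)
})

test_that("pooling sums counts and recomputes proportions", {
  samples <- make_samples(4, 4, ancestry = "AFR")
  d <- call_diplotype(c(2L, 1L, 0L, 0L, 1L, 0L, 0L, 0L), rep(0L, 8))
  t1 <- apoe_freq_table(d, samples)
  pooled <- pool_cohorts(list(t1, t1))
  expect_equal(pooled$n, 2L * t1$n[match(paste(pooled$ancestry,
                                               pooled$phenotype,
                                               pooled$diplotype),
                                         paste(t1$ancestry, t1$phenotype,
                                               t1$diplotype))])
  expect_equal(pooled$proportion,
               t1$proportion[match(paste(pooled$ancestry, pooled$phenotype,
                                         pooled$diplotype),
                                   paste(t1$ancestry, t1$phenotype,
                                         t1$diplotype))])
  # disjoint ancestries concatenate
  samples2 <- make_samples(4, 4, ancestry = "EUR")
  t2 <- apoe_freq_table(d, samples2)
  both <- pool_cohorts(list(t1, t2))
  expect_setequal(unique(both$ancestry), c("AFR", "EUR"))
  expect_error(pool_cohorts(list(t1, t1[, -1])), "schema")
})

test_that("simulated random-mating cohorts reproduce Hardy-Weinberg e4/e4 rates", {
  freqs <- matrix(c(0, 0.05, 0.75, 0.20), 1,
                  dimnames = list("EUR", c("e1", "e2", "e3", "e4")))
  co <- simulate_cohort(sim_config(seed = 2024,
                                   n_cases = c(EUR = 0L),
                                   n_controls = c(EUR = 5000L),
                                   apoe_haplotype_freqs = freqs,
                                   beta_e4 = 0, rare_per_gene = 0L))
  d <- call_diplotype(co$gm[, "chr19:44908684:T:C"],
                      co$gm[, "chr19:44908822:C:T"])
  p_obs <- mean(d$is_e4e4)
  se <- sqrt(0.04 * 0.96 / 5000)
  expect_lt(abs(p_obs - 0.04), 3 * se)
})
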