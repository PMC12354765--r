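make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r$chrom %||% "chr21", pos = r$pos, ref = r$ref %||% "A",
               alt = r$alt %||% "G", gene = r$gene %||% "APP",
               consequence = r$consequence %||% "missense",
               cadd_phred = r$cadd %||% 25, stringsAsFactors = FALSE)
  }))
}

test_that("consequence filter keeps the six classes and routes the rest", {
  v <- make_variants(list(pos = 1, consequence = "missense"),
                     list(pos = 2, consequence = "synonymous"),
                     list(pos = 3, consequence = "splicing"),
                     list(pos = 4, consequence = NA))
  out <- consequence_filter(v)
  expect_equal(out$kept$pos, c(1, 3))
  expect_equal(out$unclassified$pos, 4)
  empty <- consequence_filter(v[0, ])
  expect_equal(nrow(empty$kept), 0L)
})

test_that("group statistics partition carriers by their own ancestry", {
  samples <- rbind(make_samples(100, 0, "EUR"), make_samples(50, 0, "AFR"))
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  g <- rep(0L, 150)
  g[1] <- 1L      # EUR case het
  g[101] <- 2L    # AFR case hom
  gs <- group_stats(g, samples)
  eur <- gs[gs$ancestry == "EUR", ]
  afr <- gs[gs$ancestry == "AFR", ]
  expect_equal(eur$allele_freq, 1 / 200)
  expect_equal(eur$n_carriers_het, 1L)
  expect_equal(afr$n_carriers_hom, 1L)
  expect_equal(afr$allele_freq, 2 / 100)
  # absent variant: all frequencies zero
  gs0 <- group_stats(rep(0L, 150), samples)
  expect_true(all(gs0$allele_freq == 0))
})

test_that("the sieve enforces case-only status and the strict CADD threshold", {
  samples <- make_samples(3, 2)
  v <- make_variants(
    list(pos = 25891796, cadd = 26.9),              # case-only, passes
    list(pos = 25891800, cadd = 20),                # boundary: excluded
    list(pos = 25891810, cadd = 35),                # control carrier
    list(pos = 25891820, cadd = NA),                # missing CADD: logged
    list(pos = 25891830, cadd = 30, consequence = "synonymous"))
  gm <- make_gm(matrix(0L, 5, 5), sample_ids = samples$sample_id,
                keys = variant_key(v$chrom, v$pos, v$ref, v$alt))
  gm[1, 1:2] <- 1L
  gm[c(1, 4), 3] <- 1L   # sample 4 is a control
  gm[1, 4:5] <- 1L
  got <- prioritize(v, gm, samples, dataset = "TEST")
  expect_equal(got$pos, 25891796)
  expect_equal(got$zygosity, "Het")
  expect_equal(attr(got, "dropped_no_cadd"), "chr21:25891820:A:G")
})

test_that("known/novel classification is an exact key match", {
  entries <- data.frame(chrom = "chr14", pos = 73170945L, ref = "C",
                        alt = c("T", "G"), stringsAsFactors = FALSE)
  knowledge <- data.frame(chrom = "chr14", pos = 73170945L, ref = "C",
                          alt = "T", disease_reported = "AD",
                          stringsAsFactors = FALSE)
  got <- classify_known(entries, knowledge)
  expect_equal(got$known, c(TRUE, FALSE))
  expect_equal(got$disease_reported, c("AD", NA))
  none <- classify_known(entries, knowledge[0, ])
  expect_false(any(none$known))
})

test_that("catalog assembly merges on key, flags replication, and is associative", {
  e <- function(ds, pos, gene = "PSEN2", known = FALSE, anc = "EUR") {
    data.frame(dataset = ds, gene = gene, chrom = "chr1", pos = pos,
               ref = "G", alt = "A", known = known, ancestry = anc,
               stringsAsFactors = FALSE)
  }
  ab <- rbind(e("AoU", 226891817, anc = "AAC"), e("UKB", 226891817))
  asm <- assemble_catalog(ab)
  expect_equal(nrow(asm$catalog), 1L)
  expect_true(asm$catalog$replicated_across_biobanks)
  expect_setequal(strsplit(asm$catalog$ancestries_observed_in_cases, ",")[[1]],
                  c("AAC", "EUR"))
  # disjoint variants: sizes add
  two <- rbind(e("AoU", 1), e("UKB", 2))
  expect_equal(nrow(assemble_catalog(two)$catalog), 2L)
  # associativity / processing-order invariance of the merge
  x <- rbind(e("AoU", 1), e("UKB", 1), e("100KGP", 3))
  a1 <- assemble_catalog(x)$catalog
  a2 <- assemble_catalog(x[c(3, 1, 2), ])$catalog
  expect_identical(a1, a2)
  # conflicting gene annotation is an error
  bad <- rbind(e("AoU", 5, gene = "PSEN2"), e("UKB", 5, gene = "GBA1"))
  expect_error(assemble_catalog(bad), "conflicting gene")
})

test_that("prioritization recovers exactly the planted truth set against decoys", {
  co <- simulate_cohort(sim_config(seed = 77, n_cases = c(EUR = 40L),
                                   n_controls = c(EUR = 40L),
                                   rare_per_gene = 0L))
  co <- plant_prioritization_truth(co, k = 5L)
  keys <- variant_key(co$variants$chrom, co$variants$pos, co$variants$ref,
                      co$variants$alt)
  got <- prioritize(co$variants, co$gm[, keys], co$samples, dataset = "SYNTH")
  got_keys <- variant_key(got$chrom, got$pos, got$ref, got$alt)
  expect_setequal(got_keys, co$truth$planted)
  expect_false(any(co$truth$decoys %in% got_keys))
})
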