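# shared fixture builders for the test suite

# small manifest: n_case cases then n_ctrl controls, one ancestry
make_samples <- function(n_case, n_ctrl, ancestry = "EUR", n_pcs = 10) {
  n <- n_case + n_ctrl
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    phenotype = rep(c("AD", "control"), c(n_case, n_ctrl)),
    ancestry = ancestry,
    sex = rep_len(c("female", "male"), n),
    reported_sex = rep_len(c("female", "male"), n),
    age_years = rep(70, n),
    age_kind = rep(c("onset", "at_study"), c(n_case, n_ctrl)),
    dataset = "TEST",
    stringsAsFactors = FALSE)
  for (k in seq_len(n_pcs)) out[[paste0("PC", k)]] <- 0
  out
}

# genotype matrix with named samples/variants
make_gm <- function(mat, sample_ids = NULL, keys = NULL) {
  mat <- as.matrix(mat)
  rownames(mat) <- sample_ids %||% sprintf("S%04d", seq_len(nrow(mat)))
  colnames(mat) <- keys %||% sprintf("chr1:%d:A:G", 1000 + seq_len(ncol(mat)))
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent full-enumeration oracle for the conditional HWE exact test,
# written from the hypergeometric-style counting formula (choose(), not the
# lgamma recurrence the implementation uses)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(h hets | allele count) = 2^h * n! / (naa! h! nbb!) / C(2n, n_a):
  # the closed form normalizes exactly, no renormalization step needed
  prob <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    exp(h * log(2) + lchoose(n, naa) + lchoose(n - naa, h) -
          lchoose(2 * n, n_a))
  }, 0)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs * (1 + 1e-10)])
}

# deterministic small VCF on disk for io tests
write_test_vcf <- function(path, records, samples = c("A", "B", "C")) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}
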