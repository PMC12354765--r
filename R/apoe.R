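#' Call an APOE epsilon diplotype from the two proxy SNP genotypes
#'
#' The epsilon alleles are haplotypes of rs429358 and rs7412:
#' e2 = (T, T), e3 = (T, C), e4 = (C, C), e1 = (C, T), written as the
#' (rs429358, rs7412) base pair. Genotypes are supplied as counts of the
#' rs429358 C allele and the rs7412 T allele. All nine non-missing genotype
#' pairs map deterministically; the double heterozygote is chemically
#' ambiguous between e2/e4 and e1/e3 and is called e2/e4 with
#' `ambiguous = TRUE` (e1 genotypes are vanishingly rare). Any missing input
#' gives a no-call.
#'
#' @param g429358 count of C alleles at rs429358 (0/1/2 or NA).
#' @param g7412 count of T alleles at rs7412 (0/1/2 or NA).
#' @return data.frame with `allele1`, `allele2` (sorted), `diplotype`,
#'   `ambiguous`, `e4_dose`, `is_e4_carrier`, `is_e4e4`, `is_e3e3`,
#'   `called`. Vectorized over inputs.
#' @export
call_diplotype <- function(g429358, g7412) {
  stopifnot(length(g429358) == length(g7412))
  a1 <- rep(NA_character_, length(g429358))
  a2 <- rep(NA_character_, length(g429358))
  amb <- rep(FALSE, length(g429358))
  ok <- !is.na(g429358) & !is.na(g7412)
  # per-site haplotype composition: g429358 C alleles pair with g7412 T
  # alleles; unphased, so only the double heterozygote is ambiguous.
  map <- list(
    # key: paste(C dose, T dose)
    "0 0" = c("e3", "e3"), "0 1" = c("e2", "e3"), "0 2" = c("e2", "e2"),
    "1 0" = c("e3", "e4"), "1 1" = c("e2", "e4"), "1 2" = c("e1", "e2"),
    "2 0" = c("e4", "e4"), "2 1" = c("e1", "e4"), "2 2" = c("e1", "e1"))
  keys <- paste(g429358, g7412)
  for (i in which(ok)) {
    al <- map[[keys[i]]]
    a1[i] <- al[1L]; a2[i] <- al[2L]
    amb[i] <- keys[i] == "1 1"
  }
  e4 <- (a1 == "e4") + (a2 == "e4")
  data.frame(allele1 = a1, allele2 = a2,
             diplotype = ifelse(ok, paste(a1, a2, sep = "/"), NA_character_),
             ambiguous = amb, e4_dose = ifelse(ok, e4, NA_integer_),
             is_e4_carrier = ok & !is.na(e4) & e4 >= 1L,
             is_e4e4 = ok & !is.na(e4) & e4 == 2L,
             is_e3e3 = ok & a1 == "e3" & a2 == "e3",
             called = ok, stringsAsFactors = FALSE)
}

#' Ancestry- and phenotype-stratified APOE genotype frequency table
#'
#' Counts each called diplotype per (ancestry x phenotype) group and the
#' within-group proportion over called samples; no-calls are excluded from
#' denominators. Empty groups are emitted with count 0 and NA proportion.
#'
#' @param diplotypes output of [call_diplotype()] aligned with `samples`.
#' @param samples manifest data.frame (`ancestry`, `phenotype`).
#' @return data.frame with `ancestry`, `phenotype`, `diplotype`, `n`,
#'   `n_called_group`, `proportion`.
#' @export
apoe_freq_table <- function(diplotypes, samples) {
  stopifnot(nrow(diplotypes) == nrow(samples))
  groups <- unique(samples[, c("ancestry", "phenotype")])
  groups <- groups[order(groups$ancestry, groups$phenotype), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- samples$ancestry == groups$ancestry[i] &
      samples$phenotype == groups$phenotype[i]
    d <- diplotypes$diplotype[sel & diplotypes$called]
    n_called <- length(d)
    if (n_called == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        ancestry = groups$ancestry[i], phenotype = groups$phenotype[i],
        diplotype = NA_character_, n = 0L, n_called_group = 0L,
        proportion = NA_real_, stringsAsFactors = FALSE)
      next
    }
    tab <- table(d)
    out[[length(out) + 1L]] <- data.frame(
      ancestry = groups$ancestry[i], phenotype = groups$phenotype[i],
      diplotype = names(tab), n = as.integer(tab),
      n_called_group = n_called,
      proportion = as.integer(tab) / n_called, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pool APOE frequency tables across cohorts
#'
#' Counts are summed per (ancestry x phenotype x diplotype) and proportions
#' recomputed from the pooled counts (never averaged).
#'
#' @param tables list of [apoe_freq_table()] outputs.
#' @return pooled table in the same schema.
#' @export
pool_cohorts <- function(tables) {
  schema <- c("ancestry", "phenotype", "diplotype", "n", "n_called_group",
              "proportion")
  for (t in tables) {
    if (!identical(names(t), schema)) {
      stop("schema mismatch: expected columns ",
           paste(schema, collapse = ", "))
    }
  }
  all <- do.call(rbind, tables)
  all <- all[!is.na(all$diplotype), , drop = FALSE]
  agg <- stats::aggregate(n ~ ancestry + phenotype + diplotype, data = all,
                          FUN = sum)
  denom <- stats::aggregate(n ~ ancestry + phenotype, data = agg, FUN = sum)
  names(denom)[3L] <- "n_called_group"
  out <- merge(agg, denom, by = c("ancestry", "phenotype"), sort = TRUE)
  out$proportion <- out$n / out$n_called_group
  out <- out[order(out$ancestry, out$phenotype, out$diplotype), schema]
  rownames(out) <- NULL
  out
}
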