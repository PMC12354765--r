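#' Keep only the six prioritized consequence classes
#'
#' The sieve retains missense, frameshift, start-loss, stop-loss, stop-gain
#' and splicing variants. Variants with an unannotated / NA consequence are
#' routed to the `unclassified` component rather than silently kept.
#'
#' @param variants data.frame with a `consequence` column.
#' @return list with `kept` and `unclassified` data.frames.
#' @export
consequence_filter <- function(variants) {
  unclassified <- is.na(variants$consequence) |
    !(variants$consequence %in% CONSEQUENCES)
  kept <- !unclassified & variants$consequence %in% PRIORITIZED_CONSEQUENCES
  list(kept = variants[kept, , drop = FALSE],
       unclassified = variants[unclassified, , drop = FALSE])
}

#' Per-ancestry, per-phenotype carrier counts and allele frequencies
#'
#' For one variant, counts heterozygous and homozygous carriers and the
#' alternate-allele frequency in every (ancestry x phenotype) group of
#' QC-passed samples. Groups with zero called samples are reported with
#' `n_called = 0` and NA frequency.
#'
#' @param g genotype vector (0/1/2/NA) aligned with `samples`.
#' @param samples manifest data.frame (`ancestry`, `phenotype`).
#' @return data.frame, one row per observed (ancestry x phenotype) group.
#' @export
group_stats <- function(g, samples) {
  stopifnot(length(g) == nrow(samples))
  groups <- unique(samples[, c("ancestry", "phenotype")])
  groups <- groups[order(groups$ancestry, groups$phenotype), , drop = FALSE]
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- samples$ancestry == groups$ancestry[i] &
      samples$phenotype == groups$phenotype[i]
    gg <- g[sel]
    n_called <- sum(!is.na(gg))
    het <- sum(gg == 1, na.rm = TRUE)
    hom <- sum(gg == 2, na.rm = TRUE)
    data.frame(ancestry = groups$ancestry[i], phenotype = groups$phenotype[i],
               n_called = n_called, n_carriers_het = het, n_carriers_hom = hom,
               allele_freq = if (n_called > 0) (het + 2 * hom) / (2 * n_called)
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Case-only CADD-based variant prioritization
#'
#' Emits a catalog entry for every variant that, within one dataset, has at
#' least one case carrier, zero control carriers, and a CADD phred score
#' strictly greater than the threshold (default 20, the top-1% deleteriousness
#' proxy). Variants with missing CADD cannot pass and are reported in the
#' `dropped_no_cadd` attribute. Zygosity among case carriers is recorded.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `cadd_phred` (plus any display columns).
#' @param gm genotype matrix (samples x variants, columns aligned with
#'   `variant_key` of `variants`).
#' @param samples manifest data.frame aligned with `rownames(gm)`.
#' @param dataset dataset label recorded in the entries.
#' @param cadd_threshold strict CADD cutoff.
#' @return data.frame of catalog entries with per-group statistics attached
#'   as a `group_stats` list-column.
#' @export
prioritize <- function(variants, gm, samples, dataset,
                       cadd_threshold = 20) {
  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  stopifnot(identical(colnames(gm), keys))
  sieve <- consequence_filter(variants)
  keep_conseq <- keys %in% variant_key(sieve$kept$chrom, sieve$kept$pos,
                                       sieve$kept$ref, sieve$kept$alt)
  is_case <- samples$phenotype != "control"
  dropped_no_cadd <- character(0)
  rows <- list()
  for (j in which(keep_conseq)) {
    if (is.na(variants$cadd_phred[j])) {
      dropped_no_cadd <- c(dropped_no_cadd, keys[j])
      next
    }
    if (variants$cadd_phred[j] <= cadd_threshold) next
    g <- gm[, j]
    case_carriers <- sum(g[is_case] > 0, na.rm = TRUE)
    ctrl_carriers <- sum(g[!is_case] > 0, na.rm = TRUE)
    if (case_carriers < 1L || ctrl_carriers > 0L) next
    gs <- group_stats(g, samples)
    case_g <- g[is_case & !is.na(g) & g > 0]
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = dataset,
      gene = variants$gene[j], chrom = variants$chrom[j],
      pos = variants$pos[j], ref = variants$ref[j], alt = variants$alt[j],
      consequence = variants$consequence[j],
      cadd = variants$cadd_phred[j],
      n_case_carriers = case_carriers,
      zygosity = if (all(case_g == 1)) "Het" else "Het/Hom",
      ancestries_observed_in_cases = paste(
        sort(unique(samples$ancestry[is_case & !is.na(g) & g > 0])),
        collapse = ","),
      case_only = TRUE, cadd_pass = TRUE,
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$group_stats <- list(gs)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(dataset = character(0), gene = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), consequence = character(0),
               cadd = numeric(0), n_case_carriers = integer(0),
               zygosity = character(0),
               ancestries_observed_in_cases = character(0),
               case_only = logical(0), cadd_pass = logical(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_no_cadd") <- dropped_no_cadd
  out
}

#' Flag entries matching a table of known disease-causing variants
#'
#' Exact match on the normalized (chrom, pos, ref, alt) key sets
#' `known = TRUE` and copies the reported disease; everything else is novel.
#'
#' @param entries catalog entry data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param knowledge data.frame with the same key columns plus
#'   `disease_reported` (and optionally `source_id`).
#' @return `entries` with `known` and `disease_reported` columns.
#' @export
classify_known <- function(entries, knowledge) {
  ek <- variant_key(entries$chrom, entries$pos, entries$ref, entries$alt)
  if (nrow(knowledge) > 0L) {
    kk <- variant_key(knowledge$chrom, knowledge$pos, knowledge$ref,
                      knowledge$alt)
    idx <- match(ek, kk)
  } else {
    idx <- rep(NA_integer_, length(ek))
  }
  entries$known <- !is.na(idx)
  entries$disease_reported <- ifelse(is.na(idx), NA_character_,
                                     knowledge$disease_reported[idx])
  entries
}

#' Merge per-dataset catalogs and count the summary statistics
#'
#' Entries are merged on the normalized variant key; a variant observed in
#' two or more discovery datasets is flagged `replicated_across_biobanks`.
#' Conflicting gene assignments for one key are an error. The summary counts
#' totals, known/novel splits (overall and per dataset), per-dataset
#' ancestry counts, and non-European case exclusivity, all by counting the
#' merged entries.
#'
#' @param entries data.frame of per-dataset entries; must carry `dataset`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `known`, `ancestry` (or
#'   `ancestries_observed_in_cases`).
#' @return list with `catalog` (one row per unique variant) and `summary`
#'   (named list of counts).
#' @export
assemble_catalog <- function(entries) {
  key <- variant_key(entries$chrom, entries$pos, entries$ref, entries$alt)
  anc_col <- if ("ancestry" %in% names(entries)) entries$ancestry else
    entries$ancestries_observed_in_cases
  by_key <- split(seq_len(nrow(entries)), key)
  rows <- lapply(by_key, function(idx) {
    genes <- unique(entries$gene[idx])
    if (length(genes) > 1L) {
      stop("conflicting gene annotation for ", key[idx[1L]], ": ",
           paste(genes, collapse = " vs "))
    }
    datasets <- sort(unique(entries$dataset[idx]))
    ancs <- sort(unique(unlist(strsplit(anc_col[idx], ","))))
    data.frame(gene = genes, chrom = entries$chrom[idx[1L]],
               pos = entries$pos[idx[1L]], ref = entries$ref[idx[1L]],
               alt = entries$alt[idx[1L]],
               datasets = paste(datasets, collapse = ","),
               n_datasets = length(datasets),
               replicated_across_biobanks = length(datasets) >= 2L,
               known = any(entries$known[idx]),
               ancestries_observed_in_cases = paste(ancs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  catalog <- catalog[order(catalog$gene, catalog$chrom, catalog$pos,
                           catalog$alt), , drop = FALSE]
  rownames(catalog) <- NULL

  datasets <- sort(unique(entries$dataset))
  per_dataset <- lapply(datasets, function(d) {
    sel <- entries$dataset == d
    list(total = sum(sel), known = sum(sel & entries$known),
         novel = sum(sel & !entries$known),
         by_ancestry = table(anc_col[sel]))
  })
  names(per_dataset) <- datasets
  non_eur_only <- sum(vapply(seq_len(nrow(catalog)), function(i) {
    ancs <- strsplit(catalog$ancestries_observed_in_cases[i], ",")[[1L]]
    length(ancs) > 0L && !("EUR" %in% ancs)
  }, logical(1)))
  list(catalog = catalog,
       summary = list(
         n_total = nrow(catalog),
         n_known = sum(catalog$known),
         n_novel = sum(!catalog$known),
         n_replicated = sum(catalog$replicated_across_biobanks),
         non_european_only = non_eur_only,
         per_dataset = per_dataset))
}
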