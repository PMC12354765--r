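#' Read genotypes from a VCF restricted to gene intervals
#'
#' Loads records overlapping any of the supplied 1-based inclusive
#' intervals, splits multi-allelic records into biallelic variants, and
#' decodes GT fields into alt-allele counts. Phase separators are ignored
#' (all analyses use unphased dosages); half-calls and non-diploid GTs
#' become missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param intervals data.frame with `gene`, `chrom`, `start`, `end`;
#'   NULL loads everything.
#' @return list with `gm` (samples x variants matrix of 0/1/2/NA, columns
#'   keyed `chrom:pos:ref:alt`) and `variants` (data.frame with `chrom`,
#'   `pos`, `ref`, `alt`, `gene`).
#' @export
read_vcf <- function(path, intervals = gene_intervals()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 1L) stop("VCF has no genotype columns")
  if (is.null(dim(gt))) gt <- t(gt)
  has_format <- !is.null(colnames(gt)) && colnames(gt)[1L] == "FORMAT"
  if (has_format) {
    fmt <- gt[, 1L]
    gt_field <- vapply(strsplit(fmt, ":", fixed = TRUE), function(f) {
      i <- which(f == "GT")
      if (length(i) != 1L) NA_integer_ else i
    }, integer(1))
    if (anyNA(gt_field)) {
      stop("record without GT field at row(s) ",
           paste(which(is.na(gt_field)), collapse = ", "))
    }
    gt <- gt[, -1L, drop = FALSE]
    for (i in seq_len(nrow(gt))) {
      if (gt_field[i] > 1L) {
        gt[i, ] <- vapply(strsplit(gt[i, ], ":", fixed = TRUE),
                          `[`, "", gt_field[i])
      } else {
        gt[i, ] <- sub(":.*$", "", gt[i, ])
      }
    }
  }
  samples <- colnames(gt)
  if (nrow(fix) == 0L) {
    return(list(gm = matrix(NA_integer_, length(samples), 0,
                            dimnames = list(samples, NULL)),
                variants = data.frame(chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0),
                                      gene = character(0))))
  }
  pos <- as.integer(fix$POS)
  if (!is.null(intervals)) {
    known_contigs <- unique(intervals$chrom)
    bad <- setdiff(unique(fix$CHROM), known_contigs)
    if (length(bad) > 0L && !any(fix$CHROM %in% known_contigs)) {
      stop("no VCF contig matches the intervals; unknown contigs: ",
           paste(bad, collapse = ", "))
    }
  }
  gene <- if (is.null(intervals)) rep(NA_character_, nrow(fix)) else
    assign_gene(fix$CHROM, pos, intervals)
  keep <- if (is.null(intervals)) rep(TRUE, nrow(fix)) else !is.na(gene)
  cols <- list()
  meta <- list()
  for (i in which(keep)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    raw <- gt[i, ]
    raw[is.na(raw)] <- "."
    alleles <- strsplit(unname(raw), "[/|]")
    for (a in seq_along(alts)) {
      dose <- vapply(alleles, function(al) {
        if (length(al) != 2L || any(al == ".") || any(al == "")) {
          return(NA_integer_)
        }
        ai <- suppressWarnings(as.integer(al))
        if (anyNA(ai)) return(NA_integer_)
        sum(ai == a)
      }, integer(1))
      cols[[length(cols) + 1L]] <- dose
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts[a],
        gene = gene[i], stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(meta) > 0L)
    do.call(rbind, c(meta, list(make.row.names = FALSE))) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene = character(0))
  gm <- if (length(cols) > 0L) do.call(cbind, cols) else
    matrix(NA_integer_, length(samples), 0)
  rownames(gm) <- samples
  if (ncol(gm) > 0L) {
    colnames(gm) <- variant_key(variants$chrom, variants$pos, variants$ref,
                                variants$alt)
  }
  list(gm = gm, variants = variants)
}

#' Read and validate a sample manifest TSV
#'
#' @param path tab-separated manifest with the SampleRecord columns.
#' @param enforce_control_age flag controls younger than the eligibility
#'   age (see [validate_samples()]).
#' @return validated data.frame.
#' @export
read_manifest <- function(path, enforce_control_age = FALSE) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_samples(m, enforce_control_age = enforce_control_age)
}

#' Read a variant annotation TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#' `cdna_change`, `protein_change`, `cadd_phred`, `clinical_significance`,
#' plus optional per-ancestry reference-frequency columns `freq_<ANC>`.
#'
#' @param path annotation TSV.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "cadd_phred")
  missing_cols <- setdiff(required, names(a))
  if (length(missing_cols) > 0L) {
    stop("annotation missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(stats::na.omit(unique(a$consequence)), CONSEQUENCES)
  if (length(bad) > 0L) {
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "))
  }
  a
}

#' Write a variant catalog with deterministic layout
#'
#' Rows are sorted by (gene, chrom, pos, alt) and columns written in a
#' fixed order, so repeated writes of the same catalog are byte-identical.
#' `format = "json"` writes the same rows as a JSON array.
#'
#' @param entries catalog data.frame.
#' @param path output file.
#' @param format "tsv" or "json".
#' @return invisibly, the path.
#' @export
write_catalog <- function(entries, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  entries <- entries[, !vapply(entries, is.list, logical(1)), drop = FALSE]
  fixed_first <- intersect(c("dataset", "gene", "chrom", "pos", "ref",
                             "alt"), names(entries))
  cols <- c(fixed_first, setdiff(names(entries), fixed_first))
  entries <- entries[, cols, drop = FALSE]
  if (nrow(entries) > 0L) {
    ord <- order(if ("gene" %in% cols) entries$gene else seq_len(nrow(entries)),
                 entries$chrom, entries$pos, entries$alt)
    entries <- entries[ord, , drop = FALSE]
  }
  rownames(entries) <- NULL
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(entries, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", na = "NA")
  } else {
    jsonlite::write_json(entries, path, dataframe = "rows", na = "string",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a catalog TSV written by [write_catalog()]
#'
#' @param path catalog TSV.
#' @return data.frame.
#' @export
read_catalog <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
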