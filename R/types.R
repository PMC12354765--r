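#' @keywords internal
"_PACKAGE"

#' Controlled vocabularies used throughout the pipeline
#'
#' Eleven genetic-ancestry labels, the eleven dementia genes under study,
#' phenotype groups and the functional consequence classes retained by the
#' prioritization sieve. Ancestry labels are pipeline inputs (assigned
#' upstream by an ancestry-prediction tool), never inferred here.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
ANCESTRIES <- c("EUR", "AFR", "AMR", "AAC", "AJ", "CAS", "EAS", "SAS",
                "MDE", "FIN", "CAH")

#' @rdname vocabularies
#' @export
GENES <- c("APP", "PSEN1", "PSEN2", "TREM2", "MAPT", "GRN", "GBA1",
           "SNCA", "TBK1", "TARDBP", "APOE")

#' @rdname vocabularies
#' @export
PHENOTYPES <- c("AD", "related_dementia", "control")

#' @rdname vocabularies
#' @export
CONSEQUENCES <- c("missense", "frameshift", "start_loss", "stop_loss",
                  "stop_gain", "splicing", "synonymous", "other")

# consequence classes kept by the prioritization sieve
PRIORITIZED_CONSEQUENCES <- c("missense", "frameshift", "start_loss",
                              "stop_loss", "stop_gain", "splicing")

CLIN_SIG <- c("pathogenic", "likely_pathogenic", "VUS", "likely_benign",
              "benign", "unknown")

SEXES <- c("female", "male", "unknown")

#' Construct a normalized variant key string
#'
#' The catalog identity key is `chrom:pos:ref:alt` after left-alignment
#' and trimming; protein-change strings are display-only.
#'
#' @param chrom,pos,ref,alt vectors describing variants.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Validate a sample manifest data frame
#'
#' Checks the controlled vocabularies (ancestry, phenotype, sex), uniqueness
#' of sample ids, PC column consistency, and (optionally) flags controls
#' younger than the eligibility age used for control selection.
#'
#' @param samples data.frame with columns `sample_id`, `phenotype`,
#'   `ancestry`, `sex`, `reported_sex`, `age_years`, `age_kind`, `dataset`
#'   and PC columns `PC1..PCk` (k >= 1).
#' @param enforce_control_age if TRUE, add a logical `control_ineligible`
#'   column flagging controls with `age_years < min_control_age`.
#' @param min_control_age minimum age for eligible controls (years).
#' @return the validated data.frame (invisibly modified with flag column).
#' @export
validate_samples <- function(samples, enforce_control_age = FALSE,
                             min_control_age = 65) {
  required <- c("sample_id", "phenotype", "ancestry", "sex", "age_years")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_anc <- setdiff(unique(samples$ancestry), ANCESTRIES)
  if (length(bad_anc) > 0L) {
    stop("unknown ancestry label(s): ", paste(bad_anc, collapse = ", "),
         "; valid labels are: ", paste(ANCESTRIES, collapse = ", "))
  }
  bad_phe <- setdiff(unique(samples$phenotype), PHENOTYPES)
  if (length(bad_phe) > 0L) {
    stop("unknown phenotype label(s): ", paste(bad_phe, collapse = ", "),
         "; valid labels are: ", paste(PHENOTYPES, collapse = ", "))
  }
  if (any(samples$age_years < 0, na.rm = TRUE)) {
    stop("age_years must be non-negative")
  }
  pc_cols <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  if (length(pc_cols) > 0L && anyNA(samples[pc_cols])) {
    stop("PC columns must be fully populated")
  }
  if (enforce_control_age) {
    samples$control_ineligible <- samples$phenotype == "control" &
      samples$age_years < min_control_age
  }
  samples
}

#' Packaged GRCh38 intervals for the eleven genes
#'
#' Approximate maximal transcript intervals (1-based inclusive). These are
#' configuration defaults: the positions printed in the published variant
#' catalog all fall inside them, but users with their own annotation should
#' supply their own intervals.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
gene_intervals <- function() {
  path <- system.file("extdata", "gene_intervals.tsv", package = "demcatalog")
  iv <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(iv$start <= iv$end), setequal(iv$gene, GENES))
  iv
}

#' Assign variants to genes by interval overlap
#'
#' @param chrom,pos vectors of variant coordinates (1-based).
#' @param intervals data.frame as returned by [gene_intervals()].
#' @return character vector of gene symbols (NA where no interval overlaps).
#' @export
assign_gene <- function(chrom, pos, intervals = gene_intervals()) {
  gene <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- chrom == intervals$chrom[i] &
      pos >= intervals$start[i] & pos <= intervals$end[i]
    gene[hit] <- intervals$gene[i]
  }
  gene
}
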