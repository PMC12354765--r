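#' A reference sequence window
#'
#' Small helper wrapping a sequence string and the 1-based genomic position
#' of its first base, used by [normalize_variant()] for left-alignment.
#'
#' @param seq reference bases (single string, A/C/G/T).
#' @param start 1-based position of the first base of `seq`.
#' @param chrom contig name.
#' @return object of class `ref_window`.
#' @export
ref_window <- function(seq, start, chrom = "chr1") {
  stopifnot(is.character(seq), length(seq) == 1L, start >= 1)
  structure(list(seq = toupper(seq), start = start, chrom = chrom),
            class = "ref_window")
}

ref_base <- function(win, pos) {
  i <- pos - win$start + 1L
  if (i < 1L || i > nchar(win$seq)) {
    stop("position ", pos, " outside reference window [", win$start, ", ",
         win$start + nchar(win$seq) - 1L, "]")
  }
  substr(win$seq, i, i)
}

#' Left-align and trim a variant
#'
#' Canonical normalization: shared trailing bases are trimmed (prepending
#' the upstream reference base whenever an allele would empty, which shifts
#' indels left), then shared leading bases are trimmed while both alleles
#' keep at least one base. SNVs pass through unchanged; the operation is
#' idempotent. The ref allele is checked against the reference window and a
#' mismatch is an error.
#'
#' @param chrom,pos,ref,alt the variant (1-based, non-empty alleles).
#' @param window a [ref_window()] covering `pos` and upstream context.
#' @return list with `chrom`, `pos`, `ref`, `alt`, `key`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, window) {
  stopifnot(nzchar(ref), nzchar(alt))
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref and alt alleles are identical")
  obs <- paste(vapply(seq.int(pos, length.out = nchar(ref)),
                      function(p) ref_base(window, p), ""), collapse = "")
  if (obs != ref) {
    stop("ref allele ", ref, " disagrees with reference sequence ", obs,
         " at ", chrom, ":", pos)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        b <- ref_base(window, pos - 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
      }
      next
    }
    break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       key = variant_key(chrom, pos, ref, alt))
}
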