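#' Construct a harmonized call table
#'
#' The common currency of the package: one row per locus and sample, with up
#' to two ordered alleles given as sequences and/or lengths. Length-only
#' callsets leave the sequence columns NA. Allele order is preserved from
#' the genotype (GT) order of the source VCF; nothing is sorted silently.
#'
#' Genotype classes: `hom_ref` (0/0), `het_ref` (0/1), `hom_alt` (1/1),
#' `het_alt` (1/2, two distinct non-reference alleles), `haploid` (single
#' allele), `missing` (no resolvable genotype).
#'
#' @param locus_id Catalog locus ids (or `"orphan:<chrom>:<start>"` for
#'   records with no catalog assignment).
#' @param sample_id Sample names.
#' @param chrom,reported_start,reported_end Caller-reported coordinates,
#'   0-based half-open.
#' @param ref_len Reference allele length at the caller's coordinates (bp).
#' @param a1_seq,a2_seq Allele sequences (NA when unavailable).
#' @param a1_len,a2_len Allele lengths in bp (a2 NA for haploid calls; both
#'   NA for missing).
#' @param gclass Genotype class (see above).
#' @return A `tr_calls` data.frame.
#' @export
tr_calls <- function(locus_id, sample_id, chrom = NA_character_,
                     reported_start = NA_integer_, reported_end = NA_integer_,
                     ref_len = NA_integer_,
                     a1_seq = NA_character_, a2_seq = NA_character_,
                     a1_len = NA_integer_, a2_len = NA_integer_,
                     gclass = "missing") {
  out <- data.frame(locus_id = as.character(locus_id),
                    sample_id = as.character(sample_id),
                    chrom = as.character(chrom),
                    reported_start = as.integer(reported_start),
                    reported_end = as.integer(reported_end),
                    ref_len = as.integer(ref_len),
                    a1_seq = as.character(a1_seq),
                    a2_seq = as.character(a2_seq),
                    a1_len = as.integer(a1_len),
                    a2_len = as.integer(a2_len),
                    gclass = as.character(gclass),
                    stringsAsFactors = FALSE)
  bad <- with(out, which(!is.na(a1_seq) & !is.na(a1_len) &
                           nchar(a1_seq) != a1_len))
  if (length(bad)) {
    stop("allele 1 sequence/length disagreement at row ", bad[1])
  }
  class(out) <- c("tr_calls", "data.frame")
  out
}

#' Write or read a harmonized call table as TSV
#'
#' Plain tab-separated text with a header; NA encoded as ".".
#'
#' @param calls A [tr_calls()] table.
#' @param path File path.
#' @return `read_calls_tsv` returns a [tr_calls()] table; `write_calls_tsv`
#'   returns `path` invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", na = ".",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", na.strings = ".", header = TRUE,
                          colClasses = "character")
  tr_calls(df$locus_id, df$sample_id, df$chrom,
           as.integer(df$reported_start), as.integer(df$reported_end),
           as.integer(df$ref_len), df$a1_seq, df$a2_seq,
           as.integer(df$a1_len), as.integer(df$a2_len), df$gclass)
}

#' Derive the genotype class of a call
#'
#' Sequence-carrying calls compare each allele to the reference by exact
#' sequence identity; length-only calls compare by length equality (a
#' same-length non-reference allele is indistinguishable from reference in
#' that dialect — a documented limitation of length-only callers).
#'
#' @param a1,a2 Allele sequences or lengths (`a2 = NA` for haploid).
#' @param reference Reference allele sequence or length, matching the allele
#'   representation.
#' @return One of `hom_ref`, `het_ref`, `hom_alt`, `het_alt`, `haploid`,
#'   `missing`.
#' @export
genotype_class <- function(a1, a2, reference) {
  if (is.na(a1) && is.na(a2)) return("missing")
  if (is.na(a2)) return("haploid")
  r1 <- identical_allele(a1, reference)
  r2 <- identical_allele(a2, reference)
  if (r1 && r2) "hom_ref"
  else if (r1 || r2) "het_ref"
  else if (identical_allele(a1, a2)) "hom_alt"
  else "het_alt"
}

identical_allele <- function(x, y) {
  if (is.character(x) || is.character(y)) {
    identical(as.character(x), as.character(y))
  } else {
    isTRUE(x == y)
  }
}
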