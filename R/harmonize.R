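## Heterogeneous TR-VCF dialects are reduced to one internal record shape
## before allele extraction:
##   fix: data.frame(chrom, pos, id, ref, alt, qual, filter, info, format)
##   gt:  character matrix, rows = records, cols = samples
## Three dialects are supported, mirroring the output conventions of current
## long-read TR genotypers:
##   sequence_refalt   - alleles spelled out in REF/ALT (most tools)
##   symbolic_length   - symbolic ALT, lengths in INFO (RUL_REF / RB / END)
##   consensus_appended - REF is "N", per-sample consensus sequences carried
##                        in the sample field; must be reconstructed against
##                        the reference before standard extraction

#' Read a VCF into the internal record table
#'
#' Thin wrapper around [vcfR::read.vcfR()] keeping the fixed columns and the
#' per-sample genotype matrix.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A `tr_vcf` list with elements `fix` (data.frame), `gt` (character
#'   matrix records x samples), `samples` (character vector).
#' @export
tr_vcf_read <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  names(fix) <- tolower(names(fix))
  fix$pos <- as.integer(fix$pos)
  gt <- v@gt
  if (is.null(dim(gt)) || ncol(gt) < 2L) stop("VCF has no sample columns")
  fix$format <- gt[, 1L]
  gt <- gt[, -1L, drop = FALSE]
  structure(list(fix = fix, gt = matrix(gt, nrow = nrow(fix),
                                        dimnames = list(NULL, colnames(gt))),
                 samples = colnames(gt)),
            class = "tr_vcf")
}

#' Write an internal record table as a VCF file
#'
#' @param x A `tr_vcf` list (see [tr_vcf_read()]).
#' @param path Output path (plain text).
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
tr_vcf_write <- function(x, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs))
           },
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Repeat motif\">",
           "##INFO=<ID=RUL_REF,Number=1,Type=Integer,Description=\"Reference repeat length\">",
           "##INFO=<ID=RB,Number=A,Type=Integer,Description=\"Repeat block length per ALT allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=CONS,Number=1,Type=String,Description=\"Comma-separated consensus allele sequences\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  body <- apply(cbind(x$fix$chrom, x$fix$pos, x$fix$id, x$fix$ref, x$fix$alt,
                      x$fix$qual, x$fix$filter, x$fix$info, x$fix$format,
                      x$gt), 1L, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read reference or assembly sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences; names are trimmed
#'   at the first whitespace.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(v) if (length(v) == 2L) v[2] else NA_character_, "")
}

split_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(integer(0))
  parts <- strsplit(gt, "[/|]")[[1]]
  if (any(parts == ".")) return(integer(0))
  idx <- suppressWarnings(as.integer(parts))
  if (anyNA(idx)) return(integer(0))
  idx
}

#' Extract reference and ALT allele lengths from a symbolic-ALT record
#'
#' Length-only callers encode allele sizes in INFO rather than spelling out
#' sequences. The reference length comes from the `RUL_REF` field when
#' present, with fallback to `END - POS + 1`; ALT lengths come from the `RB`
#' field, one entry per ALT allele.
#'
#' @param info INFO string of the record.
#' @param pos 1-based POS of the record.
#' @return List with `ref_length` (bp) and `alt_lengths` (integer vector,
#'   possibly empty). `ref_length` is NA when neither `RUL_REF` nor `END` is
#'   present (the record is unresolvable).
#' @export
extract_lengths_symbolic <- function(info, pos) {
  rul <- suppressWarnings(as.integer(info_field(info, "RUL_REF")))
  if (is.na(rul)) {
    end <- suppressWarnings(as.integer(info_field(info, "END")))
    rul <- if (is.na(end)) NA_integer_ else end - as.integer(pos) + 1L
  }
  rb <- info_field(info, "RB")
  alt_lengths <- if (is.na(rb)) integer(0) else {
    suppressWarnings(as.integer(strsplit(rb, ",", fixed = TRUE)[[1]]))
  }
  list(ref_length = rul, alt_lengths = alt_lengths)
}

#' Harmonize a TR genotype VCF into a call table
#'
#' Resolves per-sample alleles by mapping GT indices onto the record's
#' allele representation for the given dialect, derives genotype classes,
#' and anchors each record to its catalog locus by coordinate overlap.
#' Records that overlap no catalog locus are retained with an
#' `orphan:`-prefixed locus id and are excluded from catalog-anchored
#' analyses downstream. Missing or unresolvable genotypes yield
#' `gclass = "missing"` with no alleles; records whose GT index exceeds the
#' ALT list are skipped and counted in the `n_skipped` attribute.
#'
#' @param vcf A `tr_vcf` (see [tr_vcf_read()]) or a path to a VCF file.
#' @param dialect One of `"sequence_refalt"`, `"symbolic_length"`,
#'   `"consensus_appended"`.
#' @param catalog A [tr_catalog()].
#' @param reference Named character vector of reference chromosome sequences
#'   (required for the consensus dialect; see [read_reference()]).
#' @return A [tr_calls()] table with one row per record and sample, with
#'   attribute `n_skipped`.
#' @export
extract_calls <- function(vcf,
                          dialect = c("sequence_refalt", "symbolic_length",
                                      "consensus_appended"),
                          catalog, reference = NULL) {
  dialect <- match.arg(dialect)
  if (is.character(vcf)) vcf <- tr_vcf_read(vcf)
  if (dialect == "consensus_appended") {
    if (is.null(reference)) {
      stop("the consensus dialect requires the reference sequences")
    }
    vcf <- reconstruct_consensus_vcf(vcf, reference)
    dialect <- "sequence_refalt"
  }
  fix <- vcf$fix
  n_rec <- nrow(fix)
  n_skipped <- 0L
  rows <- vector("list", n_rec * length(vcf$samples))
  k <- 0L
  for (r in seq_len(n_rec)) {
    ref <- toupper(fix$ref[r])
    alts <- if (is.na(fix$alt[r]) || fix$alt[r] %in% c(".", "")) {
      character(0)
    } else toupper(strsplit(fix$alt[r], ",", fixed = TRUE)[[1]])
    start0 <- fix$pos[r] - 1L
    if (dialect == "symbolic_length") {
      lens <- extract_lengths_symbolic(fix$info[r], fix$pos[r])
      if (is.na(lens$ref_length)) { n_skipped <- n_skipped + 1L; next }
      allele_lens <- c(lens$ref_length, lens$alt_lengths)
      end0 <- start0 + lens$ref_length
      alleles <- NULL
    } else {
      alleles <- c(ref, alts)
      alleles[alleles == "*"] <- ""   # spanning deletion -> empty allele
      allele_lens <- nchar(alleles)
      end0 <- start0 + nchar(ref)
    }
    locus <- assign_to_catalog(fix$chrom[r], start0, end0, catalog)
    if (is.na(locus)) {
      locus <- paste0("orphan:", fix$chrom[r], ":", start0, "-", end0)
    }
    fmt <- strsplit(fix$format[r], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    for (s in seq_along(vcf$samples)) {
      sval <- vcf$gt[r, s]
      gt_str <- if (is.na(sval) || is.na(gt_i)) NA_character_ else {
        strsplit(sval, ":", fixed = TRUE)[[1]][gt_i]
      }
      idx <- split_gt(gt_str)
      k <- k + 1L
      if (length(idx) == 0L || length(idx) > 2L) {
        # missing or unsupported ploidy -> missing call
        rows[[k]] <- list(locus, vcf$samples[s], fix$chrom[r], start0, end0,
                          allele_lens[1], NA_character_, NA_character_,
                          NA_integer_, NA_integer_, "missing")
        next
      }
      if (any(idx + 1L > length(allele_lens))) {
        k <- k - 1L
        n_skipped <- n_skipped + 1L
        next
      }
      a_len <- allele_lens[idx + 1L]
      a_seq <- if (is.null(alleles)) c(NA_character_, NA_character_) else {
        c(alleles[idx + 1L], NA_character_)[1:2]
      }
      gclass <- if (is.null(alleles)) {
        genotype_class(a_len[1], if (length(idx) == 2L) a_len[2] else NA,
                       allele_lens[1])
      } else {
        genotype_class(a_seq[1], if (length(idx) == 2L) a_seq[2] else
          NA_character_, alleles[1])
      }
      rows[[k]] <- list(locus, vcf$samples[s], fix$chrom[r], start0, end0,
                        allele_lens[1],
                        if (is.null(alleles)) NA_character_ else a_seq[1],
                        if (is.null(alleles) || length(idx) < 2L)
                          NA_character_ else a_seq[2],
                        a_len[1],
                        if (length(idx) == 2L) a_len[2] else NA_integer_,
                        gclass)
    }
  }
  rows <- rows[seq_len(k)]
  cols <- lapply(seq_len(11L), function(j) {
    unlist(lapply(rows, `[[`, j), use.names = FALSE)
  })
  out <- tr_calls(cols[[1]], cols[[2]], cols[[3]], cols[[4]], cols[[5]],
                  cols[[6]], cols[[7]], cols[[8]], cols[[9]], cols[[10]],
                  cols[[11]])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Normalize a consensus-appended VCF to the sequence REF/ALT dialect
#'
#' Some callers report per-sample consensus allele sequences appended to the
#' sample field, with REF always `"N"` and GTs restricted to 1/1 or 1/2. To
#' make such output comparable, the reference allele is re-extracted from
#' the genome over the record's `[POS, END]` span, consensus alleles equal
#' to it are re-labeled as allele 0, and the remaining alleles are moved to
#' the ALT field with GT indices rewritten accordingly.
#'
#' @param vcf A `tr_vcf` or VCF path whose FORMAT contains a `CONS` field
#'   holding comma-separated consensus sequences per sample.
#' @param reference Named character vector of chromosome sequences.
#' @return A `tr_vcf` in the `sequence_refalt` dialect. Records lacking a
#'   consensus for a genotyped sample are dropped and counted in the
#'   `n_unresolvable` attribute.
#' @export
reconstruct_consensus_vcf <- function(vcf, reference) {
  if (is.character(vcf)) vcf <- tr_vcf_read(vcf)
  fix <- vcf$fix
  keep <- rep(TRUE, nrow(fix))
  n_unres <- 0L
  for (r in seq_len(nrow(fix))) {
    end <- suppressWarnings(as.integer(info_field(fix$info[r], "END")))
    if (is.na(end) || is.null(reference[[fix$chrom[r]]])) {
      keep[r] <- FALSE; n_unres <- n_unres + 1L; next
    }
    ref_seq <- toupper(substr(reference[[fix$chrom[r]]], fix$pos[r], end))
    fmt <- strsplit(fix$format[r], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt); cons_i <- match("CONS", fmt)
    alts <- character(0)
    ok <- TRUE
    new_gt <- vcf$gt[r, ]
    for (s in seq_along(vcf$samples)) {
      sval <- strsplit(vcf$gt[r, s], ":", fixed = TRUE)[[1]]
      idx <- split_gt(sval[gt_i])
      if (length(idx) == 0L) { new_gt[s] <- "./."; next }
      cons <- if (is.na(cons_i) || cons_i > length(sval) ||
                  sval[cons_i] %in% c(".", "")) NULL else {
        toupper(strsplit(sval[cons_i], ",", fixed = TRUE)[[1]])
      }
      if (is.null(cons) || length(cons) < length(unique(idx))) {
        ok <- FALSE; break
      }
      # consensus sequences are listed per distinct GT index, in order
      new_idx <- integer(length(idx))
      for (a in seq_along(idx)) {
        aseq <- cons[match(idx[a], unique(idx))]
        if (identical(aseq, ref_seq)) {
          new_idx[a] <- 0L
        } else {
          hit <- match(aseq, alts)
          if (is.na(hit)) { alts <- c(alts, aseq); hit <- length(alts) }
          new_idx[a] <- hit
        }
      }
      new_gt[s] <- paste(new_idx, collapse = "/")
    }
    if (!ok) { keep[r] <- FALSE; n_unres <- n_unres + 1L; next }
    fix$ref[r] <- ref_seq
    fix$alt[r] <- if (length(alts)) paste(alts, collapse = ",") else "."
    fix$format[r] <- "GT"
    vcf$gt[r, ] <- new_gt
  }
  out <- structure(list(fix = fix[keep, , drop = FALSE],
                        gt = vcf$gt[keep, , drop = FALSE],
                        samples = vcf$samples),
                   class = "tr_vcf")
  attr(out, "n_unresolvable") <- n_unres
  out
}
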