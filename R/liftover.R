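## Projection of reference intervals onto assembly contigs through alignment
## CIGARs. Alignments are held as a plain data.frame so that they can come
## either from SAM files (via Rsamtools) or directly from the simulator:
##   contig, contig_length, ref_chrom, ref_start (0-based), strand (+/-),
##   cigar (string, ops in M=XIDSH)

#' Read primary contig-to-reference alignments from a SAM file
#'
#' Secondary and supplementary records are dropped; only primary alignments
#' enter the projection, matching the single-contig retention rule.
#'
#' @param path SAM file (with `@SQ` header lines).
#' @return Alignment data.frame (see [project_interval()]).
#' @export
read_alignments <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos) &
    bitwAnd(rec$flag, 256L) == 0L & bitwAnd(rec$flag, 2048L) == 0L
  cig <- rec$cigar[keep]
  qlen <- vapply(cig, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(contig = rec$qname[keep],
             contig_length = qlen,
             ref_chrom = as.character(rec$rname[keep]),
             ref_start = rec$pos[keep] - 1L,
             strand = ifelse(bitwAnd(rec$flag[keep], 16L) != 0L, "-", "+"),
             cigar = cig, stringsAsFactors = FALSE)
}

# "50M10I940M" -> list(op = c("M","I","M"), len = c(50,10,940))
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

#' Index alignments for repeated interval projection
#'
#' Parses each alignment's CIGAR once into a table of reference-consuming
#' segments with their query offsets, so that projecting many intervals is
#' a binary search rather than a CIGAR walk per query.
#'
#' @param alignments Alignment data.frame (see [read_alignments()]).
#' @return An `aln_index` list usable wherever `alignments` is accepted.
#' @export
index_alignments <- function(alignments) {
  idx <- lapply(seq_len(nrow(alignments)), function(r) {
    a <- alignments[r, ]
    ops <- parse_cigar(a$cigar)
    q <- 0L
    ref <- a$ref_start
    seg_op <- character(0); seg_ref0 <- seg_rlen <- seg_q0 <- integer(0)
    for (i in seq_along(ops$op)) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op %in% c("M", "=", "X", "D", "N")) {
        seg_op <- c(seg_op, op)
        seg_ref0 <- c(seg_ref0, ref)
        seg_rlen <- c(seg_rlen, len)
        seg_q0 <- c(seg_q0, q)
        ref <- ref + len
      }
      if (op %in% c("M", "=", "X", "I", "S")) q <- q + len
    }
    if (q != a$contig_length) {
      stop("inconsistent CIGAR for contig ", a$contig,
           ": query-consuming ops total ", q, " but contig length is ",
           a$contig_length)
    }
    list(contig = a$contig, contig_length = a$contig_length,
         ref_chrom = a$ref_chrom, ref_start = a$ref_start,
         ref_end = ref, strand = a$strand,
         seg_op = seg_op, seg_ref0 = seg_ref0, seg_rlen = seg_rlen,
         seg_q0 = seg_q0)
  })
  structure(idx, class = "aln_index")
}

# Map one reference position through an indexed alignment onto query
# (aligned-orientation) coordinates. mode "start": the query offset of the
# first aligned base at ref >= p (a position inside a deletion snaps
# right). mode "end": the query offset just after the last aligned base at
# ref < p (snaps left inside deletions).
map_position <- function(ai, p, mode) {
  i <- findInterval(p - if (mode == "end") 1L else 0L, ai$seg_ref0)
  if (i < 1L || i > length(ai$seg_ref0)) return(NA_integer_)
  m_like <- ai$seg_op[i] %in% c("M", "=", "X")
  if (mode == "start") {
    if (m_like) ai$seg_q0[i] + (p - ai$seg_ref0[i]) else ai$seg_q0[i]
  } else {
    if (m_like) ai$seg_q0[i] + (p - 1L - ai$seg_ref0[i]) + 1L else ai$seg_q0[i]
  }
}

#' Project a reference interval onto assembly contigs
#'
#' Walks the alignment CIGAR to map both interval endpoints into contig
#' coordinates: contig insertions shift subsequent positions, deletions
#' collapse endpoints to the nearest aligned contig base on the interior
#' side of the interval. A locus is projected only when exactly one
#' alignment record of one contig fully covers it (`status = "ok"`);
#' otherwise the status reports why (`multi_contig`, `unaligned`,
#' `spans_clip` when the locus pokes into an alignment edge or clipped
#' region). Coordinates are returned on the original contig, strand-aware:
#' for minus-strand alignments the walk happens on the stored (reverse
#' complemented) orientation and is then flipped back.
#'
#' @param alignments Alignment data.frame for one haplotype (see
#'   [read_alignments()]), or the result of [index_alignments()] when
#'   projecting many intervals.
#' @param chrom,start,end Reference interval, 0-based half-open.
#' @return List with `contig`, `start`, `end` (0-based half-open on the
#'   contig), `strand`, `status`.
#' @export
project_interval <- function(alignments, chrom, start, end) {
  if (!inherits(alignments, "aln_index")) {
    alignments <- index_alignments(alignments)
  }
  none <- list(contig = NA_character_, start = NA_integer_,
               end = NA_integer_, strand = NA_character_,
               status = "unaligned")
  chroms <- vapply(alignments, `[[`, "", "ref_chrom")
  rs <- vapply(alignments, `[[`, 0L, "ref_start")
  re <- vapply(alignments, `[[`, 0L, "ref_end")
  cand <- which(chroms == chrom & rs < end & re > start)
  if (!length(cand)) return(none)
  covers <- cand[rs[cand] <= start & re[cand] >= end]
  if (length(covers) == 0L) {
    none$status <- "spans_clip"   # partially covered / endpoint clipped
    return(none)
  }
  if (length(covers) >= 2L) {
    # two alignment records covering the locus, even of the same contig,
    # make the projection ambiguous
    none$status <- "multi_contig"
    return(none)
  }
  ai <- alignments[[covers]]
  qs <- map_position(ai, start, "start")
  qe <- map_position(ai, end, "end")
  if (is.na(qs) || is.na(qe)) {
    none$status <- "spans_clip"
    return(none)
  }
  if (qe < qs) qe <- qs   # interval fully inside a deletion -> empty
  if (ai$strand == "-") {
    tmp <- c(ai$contig_length - qe, ai$contig_length - qs)
    qs <- tmp[1]; qe <- tmp[2]
  }
  list(contig = ai$contig, start = qs, end = qe, strand = ai$strand,
       status = "ok")
}

#' Extract an assembly allele from a projected interval
#'
#' Returns the contig subsequence over the projection, reverse-complemented
#' for minus-strand alignments so alleles are always reported in reference
#' orientation. A zero-length projection (locus fully deleted in the
#' haplotype) yields the empty allele.
#'
#' @param contig_sequences Named character vector of contig sequences (see
#'   [read_reference()]).
#' @param proj Projection with `status = "ok"` from [project_interval()].
#' @return List with `sequence` and `length`.
#' @export
extract_assembly_allele <- function(contig_sequences, proj) {
  stopifnot(identical(proj$status, "ok"))
  seq_full <- contig_sequences[[proj$contig]]
  if (is.null(seq_full)) stop("contig not found: ", proj$contig)
  if (proj$end > nchar(seq_full)) {
    stop("projected interval exceeds contig bounds: ", proj$contig)
  }
  s <- substr(seq_full, proj$start + 1L, proj$end)
  if (identical(proj$strand, "-") && nchar(s) > 0L) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  list(sequence = s, length = nchar(s))
}

#' Build an assembly-derived truth callset over a catalog
#'
#' Projects every catalog locus onto both haplotype assemblies and extracts
#' the two truth alleles. Loci where only one haplotype projects cleanly
#' yield haploid truth calls; loci where neither does are marked missing
#' with the failure statuses recorded.
#'
#' @param catalog A [tr_catalog()].
#' @param hap1,hap2 Lists with elements `alignments` (data.frame) and
#'   `sequences` (named character vector of contigs).
#' @param reference Named character vector of reference chromosome
#'   sequences, used to derive the reference allele for genotype classes.
#' @param sample_id Sample name for the emitted calls.
#' @return A [tr_calls()] table with attribute `statuses` (per-locus
#'   two-column matrix of projection statuses).
#' @export
assembly_truth_calls <- function(catalog, hap1, hap2, reference,
                                 sample_id = "assembly") {
  n <- nrow(catalog)
  a1s <- a2s <- rep(NA_character_, n)
  st <- matrix(NA_character_, n, 2)
  hap1_idx <- if (inherits(hap1$alignments, "aln_index")) hap1$alignments
    else index_alignments(hap1$alignments)
  hap2_idx <- if (inherits(hap2$alignments, "aln_index")) hap2$alignments
    else index_alignments(hap2$alignments)
  for (i in seq_len(n)) {
    for (h in 1:2) {
      hap <- if (h == 1L) hap1 else hap2
      hidx <- if (h == 1L) hap1_idx else hap2_idx
      pr <- project_interval(hidx, catalog$chrom[i],
                             catalog$start[i], catalog$end[i])
      st[i, h] <- pr$status
      if (pr$status == "ok") {
        al <- extract_assembly_allele(hap$sequences, pr)
        if (h == 1L) a1s[i] <- al$sequence else a2s[i] <- al$sequence
      }
    }
  }
  # shift a lone hap2 allele into the first slot for haploid truth
  swap <- is.na(a1s) & !is.na(a2s)
  a1s[swap] <- a2s[swap]; a2s[swap] <- NA_character_
  ref_len <- catalog$end - catalog$start
  gcl <- vapply(seq_len(n), function(i) {
    if (is.na(a1s[i])) return("missing")
    ref_allele <- toupper(substr(reference[[catalog$chrom[i]]],
                                 catalog$start[i] + 1L, catalog$end[i]))
    genotype_class(a1s[i], a2s[i], ref_allele)
  }, character(1))
  out <- tr_calls(catalog$locus_id, sample_id, catalog$chrom, catalog$start,
                  catalog$end, ref_len, a1s, a2s,
                  ifelse(is.na(a1s), NA_integer_, nchar(a1s)),
                  ifelse(is.na(a2s), NA_integer_, nchar(a2s)),
                  gclass = gcl)
  attr(out, "statuses") <- st
  out
}
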