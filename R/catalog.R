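#' Construct a tandem-repeat locus catalog
#'
#' A catalog is the positional anchor for every comparison in the package: a
#' set of TR loci, each an interval on the reference plus the repeated motif.
#' Internally all coordinates are 0-based half-open; conversion from other
#' dialects happens only at I/O boundaries (see [read_catalog()]).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions (bp).
#' @param end Integer vector, 0-based exclusive end positions (bp).
#' @param motif Character vector of repeat unit sequences (A/C/G/T;
#'   lowercase accepted and uppercased).
#' @param locus_id Optional stable identifiers; defaults to
#'   `chrom:start-end`.
#'
#' @return A `tr_catalog`: a data.frame with columns `chrom`, `start`,
#'   `end`, `motif`, `motif_length`, `locus_id`, sorted by (chrom, start),
#'   with unique locus ids.
#' @export
tr_catalog <- function(chrom, start, end, motif, locus_id = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  motif <- toupper(as.character(motif))
  if (length(chrom) == 0L) {
    cat_df <- data.frame(chrom = character(), start = integer(),
                         end = integer(), motif = character(),
                         motif_length = integer(), locus_id = character(),
                         stringsAsFactors = FALSE)
    class(cat_df) <- c("tr_catalog", "data.frame")
    return(cat_df)
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("invalid locus interval (end <= start) at entry ", bad[1],
         ": ", chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]])
  }
  bad_motif <- which(!grepl("^[ACGT]+$", motif))
  if (length(bad_motif)) {
    stop("motif must be a non-empty A/C/G/T string at entry ", bad_motif[1],
         ": '", motif[bad_motif[1]], "'")
  }
  if (is.null(locus_id)) {
    locus_id <- paste0(chrom, ":", start, "-", end)
  }
  if (anyDuplicated(locus_id)) {
    stop("duplicate locus_id: ", locus_id[duplicated(locus_id)][1])
  }
  cat_df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                       motif = motif, motif_length = nchar(motif),
                       locus_id = as.character(locus_id),
                       stringsAsFactors = FALSE)
  cat_df <- cat_df[order(cat_df$chrom, cat_df$start), , drop = FALSE]
  rownames(cat_df) <- NULL
  class(cat_df) <- c("tr_catalog", "data.frame")
  cat_df
}

#' Read a TR locus catalog from a BED-style file
#'
#' Expects at least four tab-separated columns: chromosome, start, end, motif.
#' Genotypers disagree on the catalog coordinate dialect (some use 1-based
#' starts); `convention` names the dialect of the file, and the returned
#' catalog is always expressed 0-based half-open.
#'
#' @param path Path to the BED file (no header).
#' @param convention `"zero_based_half_open"` (BED standard) or
#'   `"one_based_inclusive"` (start is shifted down by 1 on read).
#' @return A [tr_catalog()].
#' @export
read_catalog <- function(path,
                         convention = c("zero_based_half_open",
                                        "one_based_inclusive")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("catalog file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed catalog line ", which(nf < 4L)[1],
         ": expected >= 4 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  motif <- vapply(fields, `[[`, "", 4L)
  if (anyNA(start) || anyNA(end)) {
    stop("malformed catalog line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates")
  }
  if (convention == "one_based_inclusive") start <- start - 1L
  out <- tr_catalog(chrom, start, end, motif)
  attr(out, "source_convention") <- convention
  out
}

#' Write a catalog as a 4-column BED file
#'
#' @param catalog A [tr_catalog()].
#' @param path Output path.
#' @param convention Coordinate dialect to emit (see [read_catalog()]).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path,
                          convention = c("zero_based_half_open",
                                         "one_based_inclusive")) {
  convention <- match.arg(convention)
  start <- catalog$start
  if (convention == "one_based_inclusive") start <- start + 1L
  writeLines(paste(catalog$chrom, start, catalog$end, catalog$motif,
                   sep = "\t"), path)
  invisible(path)
}

#' Sample an isolated-locus benchmark catalog
#'
#' Reproduces the catalog-construction procedure used for benchmarking:
#' restrict to non-overlapping loci separated by a minimum inter-locus gap,
#' sample up to a fixed number of loci per motif length, then add back a
#' mandatory set (e.g. disease-associated loci) unconditionally.
#'
#' @param full A [tr_catalog()] to sample from.
#' @param min_separation Minimum gap in bp between retained loci on the same
#'   chromosome, measured end-of-one to start-of-next. Default 25.
#' @param per_motif_size Maximum sampled loci per motif length. Default 1000.
#' @param mandatory Optional [tr_catalog()] of loci always included (not
#'   subject to the separation filter or the per-motif cap).
#' @param seed Integer seed making the sampling reproducible.
#' @return A [tr_catalog()] of sampled plus mandatory loci.
#' @export
sample_benchmark_catalog <- function(full, min_separation = 25L,
                                     per_motif_size = 1000L,
                                     mandatory = NULL, seed = 1L) {
  if (nrow(full) == 0L) stop("cannot sample from an empty catalog")
  stopifnot(min_separation >= 0L, per_motif_size >= 1L)
  iso <- isolated_loci(full, min_separation)
  # cap per motif length, uniform random within each length class
  keep <- withr_seed(seed, {
    unlist(lapply(split(seq_len(nrow(iso)), iso$motif_length), function(idx) {
      if (length(idx) <= per_motif_size) idx
      else sort(sample(idx, per_motif_size))
    }), use.names = FALSE)
  })
  sampled <- iso[sort(keep), , drop = FALSE]
  if (!is.null(mandatory) && nrow(mandatory) > 0L) {
    extra <- mandatory[!(mandatory$locus_id %in% sampled$locus_id), ,
                       drop = FALSE]
    sampled <- rbind(as.data.frame(sampled), as.data.frame(extra))
  }
  out <- tr_catalog(sampled$chrom, sampled$start, sampled$end, sampled$motif,
                    sampled$locus_id)
  out
}

# Greedy left-to-right scan keeping loci that do not overlap and sit at least
# `gap` bp after the previously kept locus on the same chromosome.
isolated_loci <- function(catalog, gap) {
  keep <- logical(nrow(catalog))
  last_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(catalog))) {
    if (catalog$chrom[i] != last_chrom) {
      last_end <- -Inf
      last_chrom <- catalog$chrom[i]
    }
    if (catalog$start[i] - last_end >= gap || is.infinite(last_end)) {
      keep[i] <- TRUE
      last_end <- catalog$end[i]
    }
  }
  catalog[keep, , drop = FALSE]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Assign an interval to its overlapping catalog locus
#'
#' Genotypers may widen or narrow locus coordinates in their output; every
#' caller-reported interval is mapped back to the catalog locus it overlaps
#' by at least 1 bp. When a query overlaps several catalog loci the one with
#' the larger overlap wins; ties go to the smaller start.
#'
#' @param chrom,start,end Query interval(s), 0-based half-open. Vectorized.
#' @param catalog A [tr_catalog()].
#' @return Character vector of locus ids (NA where no catalog locus
#'   overlaps).
#' @export
assign_to_catalog <- function(chrom, start, end, catalog) {
  q <- split(seq_along(chrom), chrom)
  out <- rep(NA_character_, length(chrom))
  for (chr in names(q)) {
    idx <- q[[chr]]
    sub <- catalog[catalog$chrom == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = start[idx] + 1L, end = end[idx]),
      IRanges::IRanges(start = sub$start + 1L, end = sub$end))
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(end[idx][qh], sub$end[sh]) - pmax(start[idx][qh], sub$start[sh])
    # larger overlap first, then smaller catalog start
    ord <- order(qh, -ov, sub$start[sh])
    first <- !duplicated(qh[ord])
    out[idx[qh[ord][first]]] <- sub$locus_id[sh[ord][first]]
  }
  out
}
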