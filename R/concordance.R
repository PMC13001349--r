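#' Levenshtein distance between allele sequences
#'
#' Minimum number of single-nucleotide insertions, deletions and
#' substitutions transforming one sequence into the other. Vectorized over
#' pairs; empty sequences are allowed (a fully deleted allele has length 0).
#'
#' @param a,b Character vectors of equal length (recycled if length 1).
#' @return Integer vector of edit distances.
#' @export
tr_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- mapply(function(x, y) {
    if (is.na(x) || is.na(y)) return(NA_integer_)
    as.integer(utils::adist(x, y))
  }, a, b, USE.NAMES = FALSE)
  as.integer(out)
}

# Deviation between one tool allele and one truth allele under a metric.
# Inputs are sequences (character) or lengths (numeric); the length metric
# accepts either, the edit metric requires sequences.
allele_deviation <- function(x, y, metric) {
  if (metric == "edit") {
    if (!is.character(x) || !is.character(y)) {
      stop("edit metric requires allele sequences")
    }
    return(tr_levenshtein(x, y))
  }
  lx <- if (is.character(x)) nchar(x) else as.numeric(x)
  ly <- if (is.character(y)) nchar(y) else as.numeric(y)
  abs(lx - ly)
}

#' Pair called alleles with truth alleles to minimize total deviation
#'
#' For a diploid call vs a diploid truth both orderings (direct and crossed)
#' are evaluated and the one with the smaller total deviation is kept; ties
#' go to the direct ordering. With one allele on one side, the single allele
#' pairs with the counterpart of minimal deviation and the remaining allele
#' is flagged unpaired.
#'
#' @param tool,truth Alleles for one locus: character vector of sequences or
#'   numeric vector of lengths, 1 or 2 entries each.
#' @param metric `"length"` (absolute length difference, bp) or `"edit"`
#'   (Levenshtein distance; requires sequences).
#' @return List with `pairing` (for each tool allele, the index of its truth
#'   partner), `deviations` (per paired tool allele), `total`,
#'   `unpaired_truth` / `unpaired_tool` (index or NA), and `crossed`.
#' @export
pair_alleles <- function(tool, truth, metric = c("length", "edit")) {
  metric <- match.arg(metric)
  tool <- tool[!is.na(tool)]
  truth <- truth[!is.na(truth)]
  nt <- length(tool); nr <- length(truth)
  if (nt == 0L || nr == 0L) stop("pair_alleles: empty allele list")
  if (nt > 2L || nr > 2L) stop("pair_alleles: more than 2 alleles per side")
  d <- function(i, j) allele_deviation(tool[i], truth[j], metric)
  if (nt == 2L && nr == 2L) {
    direct <- d(1, 1) + d(2, 2)
    crossed <- d(1, 2) + d(2, 1)
    if (crossed < direct) {
      list(pairing = c(2L, 1L), deviations = c(d(1, 2), d(2, 1)),
           total = crossed, unpaired_truth = NA_integer_,
           unpaired_tool = NA_integer_, crossed = TRUE)
    } else {
      list(pairing = c(1L, 2L), deviations = c(d(1, 1), d(2, 2)),
           total = direct, unpaired_truth = NA_integer_,
           unpaired_tool = NA_integer_, crossed = FALSE)
    }
  } else if (nt == 1L && nr == 2L) {
    devs <- c(d(1, 1), d(1, 2))
    j <- which.min(devs)            # tie -> first truth allele
    list(pairing = j, deviations = devs[j], total = devs[j],
         unpaired_truth = setdiff(1:2, j), unpaired_tool = NA_integer_,
         crossed = FALSE)
  } else if (nt == 2L && nr == 1L) {
    devs <- c(d(1, 1), d(2, 1))
    i <- which.min(devs)
    list(pairing = ifelse(seq_len(2) == i, 1L, NA_integer_),
         deviations = devs[i], total = devs[i],
         unpaired_truth = NA_integer_, unpaired_tool = setdiff(1:2, i),
         crossed = FALSE)
  } else {
    dev <- d(1, 1)
    list(pairing = 1L, deviations = dev, total = dev,
         unpaired_truth = NA_integer_, unpaired_tool = NA_integer_,
         crossed = FALSE)
  }
}

#' Deviation (concordance) classes
#'
#' Length deviations between a called and a truth allele are categorized in
#' order: Match (no deviation), Off by 1 bp (exactly 1 bp), Off by motif
#' (deviation no greater than the motif length of the locus), Mismatch
#' (deviation exceeding the motif length). Because the rules apply in order,
#' a 1 bp deviation at a homopolymer locus is OFF_BY_1, not OFF_BY_MOTIF.
#'
#' @param deviation Non-negative numeric vector (bp).
#' @param motif_length Positive integer vector (recycled).
#' @return Character vector over MATCH, OFF_BY_1, OFF_BY_MOTIF, MISMATCH.
#' @export
classify_deviation <- function(deviation, motif_length) {
  stopifnot(all(deviation >= 0, na.rm = TRUE),
            all(motif_length >= 1, na.rm = TRUE))
  n <- max(length(deviation), length(motif_length))
  deviation <- rep_len(deviation, n)
  motif_length <- rep_len(motif_length, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(deviation) & !is.na(motif_length)
  out[ok & deviation > motif_length] <- "MISMATCH"
  out[ok & deviation <= motif_length] <- "OFF_BY_MOTIF"
  out[ok & deviation == 1] <- "OFF_BY_1"
  out[ok & deviation == 0] <- "MATCH"
  out
}

deviation_class_levels <- c("MATCH", "OFF_BY_1", "OFF_BY_MOTIF", "MISMATCH")

# worst class across a locus's alleles (MATCH < OFF_BY_1 < OFF_BY_MOTIF <
# MISMATCH); NA entries (haploid second allele) are ignored
worst_class <- function(...) {
  m <- cbind(...)
  sev <- matrix(match(m, deviation_class_levels), nrow = nrow(m))
  deviation_class_levels[apply(sev, 1, max, na.rm = TRUE)]
}

#' Build a per-locus concordance report
#'
#' Joins a harmonized callset with a truth callset (assembly-derived or
#' simulated) by locus and sample, pairs alleles to minimize total deviation,
#' and attaches per-allele length deviations, Levenshtein distances (when
#' both sides carry sequences), the locus concordance class (worst allele),
#' and the stratification bins.
#'
#' Truth loci with no corresponding call, or where the call is missing, are
#' retained with `called = FALSE` so that missing rates can be reported;
#' they carry no concordance class.
#'
#' @param calls,truth Harmonized call tables (see [tr_calls()]).
#' @param catalog A [tr_catalog()] supplying motif lengths.
#' @param metric Pairing metric passed to [pair_alleles()]; use `"length"`
#'   for length-only callsets.
#' @param extended_expansion_bins Use the expansion binning that splits the
#'   top category into 500-1000 and >1000 bp instead of ending at >500 bp;
#'   both conventions are in circulation.
#' @return A data.frame with one row per truth locus and sample.
#' @export
concordance_records <- function(calls, truth, catalog,
                                metric = c("length", "edit"),
                                extended_expansion_bins = FALSE) {
  metric <- match.arg(metric)
  mot <- stats::setNames(catalog$motif_length, catalog$locus_id)
  ref_len_cat <- stats::setNames(catalog$end - catalog$start,
                                 catalog$locus_id)
  key <- function(df) paste(df$locus_id, df$sample_id, sep = "\r")
  calls <- calls[calls$locus_id %in% truth$locus_id, , drop = FALSE]
  cmap <- match(key(truth), key(calls))
  n <- nrow(truth)
  out <- data.frame(
    locus_id = truth$locus_id, sample_id = truth$sample_id,
    motif_length = unname(mot[truth$locus_id]),
    truth_gclass = truth$gclass,
    truth_len1 = truth$a1_len, truth_len2 = truth$a2_len,
    called = FALSE, dev1 = NA_real_, dev2 = NA_real_,
    lev1 = NA_integer_, lev2 = NA_integer_,
    locus_class = NA_character_, allele_count_mismatch = FALSE,
    stringsAsFactors = FALSE)
  get_seq <- function(df, j) {
    if (is.null(df$a1_seq)) c(NA_character_, NA_character_)
    else c(df$a1_seq[j], df$a2_seq[j])
  }
  for (i in seq_len(n)) {
    j <- cmap[i]
    if (is.na(j) || identical(calls$gclass[j], "missing")) next
    tool_len <- c(calls$a1_len[j], calls$a2_len[j])
    truth_len <- c(truth$a1_len[i], truth$a2_len[i])
    tool_seq <- get_seq(calls, j)[!is.na(tool_len)]
    truth_seq <- get_seq(truth, i)[!is.na(truth_len)]
    tool_len <- tool_len[!is.na(tool_len)]
    truth_len <- truth_len[!is.na(truth_len)]
    if (!length(tool_len) || !length(truth_len)) next
    seqs_ok <- !anyNA(tool_seq) && !anyNA(truth_seq)
    pr <- if (metric == "edit") {
      pair_alleles(tool_seq, truth_seq, metric = "edit")
    } else {
      pair_alleles(tool_len, truth_len, metric = "length")
    }
    paired_tool <- which(!is.na(pr$pairing))
    paired_truth <- pr$pairing[paired_tool]
    # per-allele length deviation always in bp, whatever the pairing metric
    devs <- abs(tool_len[paired_tool] - truth_len[paired_truth])
    out$called[i] <- TRUE
    out$dev1[i] <- devs[1]
    if (length(devs) > 1L) out$dev2[i] <- devs[2]
    if (seqs_ok) {
      levs <- tr_levenshtein(tool_seq[paired_tool], truth_seq[paired_truth])
      out$lev1[i] <- levs[1]
      if (length(levs) > 1L) out$lev2[i] <- levs[2]
    }
    out$allele_count_mismatch[i] <-
      !is.na(pr$unpaired_truth) || !is.na(pr$unpaired_tool)
  }
  called_idx <- which(out$called)
  if (length(called_idx)) {
    cls1 <- classify_deviation(out$dev1[called_idx],
                               out$motif_length[called_idx])
    cls2 <- classify_deviation(out$dev2[called_idx],
                               out$motif_length[called_idx])
    out$locus_class[called_idx] <- worst_class(cls1, cls2)
  }
  ref_len <- unname(ref_len_cat[out$locus_id])
  long_truth <- pmax(out$truth_len1, out$truth_len2, na.rm = TRUE)
  out$allele_length_bin <- bin_values(long_truth, bins_allele_length())
  out$expansion <- pmax(long_truth - ref_len, 0)
  out$expansion_bin <- ifelse(out$expansion > 0,
                              bin_values(out$expansion,
                                         bins_expansion(extended_expansion_bins)),
                              NA_character_)
  out$motif_length_bin <- motif_bin(out$motif_length)
  out
}

# lower-inclusive, upper-exclusive bins; final bin open
bins_allele_length <- function() {
  list(breaks = c(0, 50, 100, 200, 500, 1000, Inf),
       labels = c("<50", "50-100", "100-200", "200-500", "500-1000", ">1000"))
}
bins_expansion <- function(extended = FALSE) {
  if (extended) {
    list(breaks = c(0, 50, 100, 200, 500, 1000, Inf),
         labels = c("<50", "50-100", "100-200", "200-500", "500-1000",
                    ">1000"))
  } else {
    list(breaks = c(0, 50, 100, 200, 500, Inf),
         labels = c("<50", "50-100", "100-200", "200-500", ">500"))
  }
}
bin_values <- function(x, bins) {
  as.character(cut(x, breaks = bins$breaks, labels = bins$labels,
                   right = FALSE, include.lowest = TRUE))
}
motif_bin <- function(motif_length) {
  ifelse(motif_length > 10, ">10", as.character(motif_length))
}

#' Length-concordance accuracy
#'
#' Fraction of called loci whose concordance class falls in the accepted
#' set. The default accepts Match and Off-by-1bp; adding `"OFF_BY_MOTIF"`
#' reproduces the more permissive motif-tolerant analysis. Loci without a
#' call are excluded from the denominator (the missing rate is reported
#' separately by [stratify_records()]).
#'
#' @param records Output of [concordance_records()].
#' @param accepted Character subset of the deviation classes.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(records, accepted = c("MATCH", "OFF_BY_1")) {
  stopifnot(all(accepted %in% deviation_class_levels))
  called <- records[records$called, , drop = FALSE]
  if (nrow(called) == 0L) stop("accuracy: no called loci")
  mean(called$locus_class %in% accepted)
}

#' Sequence-level accuracy at length-concordant loci
#'
#' Restricts to loci where the called and truth allele lengths match on both
#' alleles and reports the fraction with Levenshtein distance 0 on both,
#' plus the distribution of total per-locus edit distances among those
#' length-concordant loci.
#'
#' @param records Output of [concordance_records()] with sequences.
#' @return List with `fraction`, `n`, and `distribution` (table of total
#'   per-locus Levenshtein distance).
#' @export
sequence_accuracy <- function(records) {
  lc <- records[records$called & records$dev1 == 0 &
                  (is.na(records$dev2) | records$dev2 == 0) &
                  !is.na(records$lev1), , drop = FALSE]
  if (nrow(lc) == 0L) stop("sequence_accuracy: no length-concordant loci with sequences")
  total_lev <- lc$lev1 + ifelse(is.na(lc$lev2), 0L, lc$lev2)
  list(fraction = mean(total_lev == 0), n = nrow(lc),
       distribution = table(total_lev))
}

#' Stratified accuracy table
#'
#' Per-bin call counts, missing counts and accuracy along one of the
#' report's stratification axes.
#'
#' @param records Output of [concordance_records()].
#' @param axis One of `"gclass"`, `"allele_length"`, `"motif_length"`,
#'   `"expansion"`.
#' @param accepted Accepted classes, as in [accuracy()].
#' @return data.frame with columns `bin`, `n_called`, `n_missing`,
#'   `accuracy`.
#' @export
stratify_records <- function(records,
                             axis = c("gclass", "allele_length",
                                      "motif_length", "expansion"),
                             accepted = c("MATCH", "OFF_BY_1")) {
  axis <- match.arg(axis)
  col <- switch(axis, gclass = "truth_gclass",
                allele_length = "allele_length_bin",
                motif_length = "motif_length_bin",
                expansion = "expansion_bin")
  grp <- records[[col]]
  keep <- !is.na(grp)
  res <- lapply(split(which(keep), grp[keep]), function(idx) {
    sub <- records[idx, , drop = FALSE]
    n_called <- sum(sub$called)
    data.frame(n_called = n_called, n_missing = sum(!sub$called),
               accuracy = if (n_called) accuracy(sub, accepted) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- cbind(bin = names(res), out)
  rownames(out) <- NULL
  out
}

#' Genotype-class distribution of a callset
#'
#' Proportions of the four diploid genotype classes (0/0, 0/1, 1/1, 1/2)
#' among diploid calls; missing and haploid calls are counted separately and
#' excluded from the proportions.
#'
#' @param calls A harmonized call table (see [tr_calls()]).
#' @return List with `proportions` (named over hom_ref, het_ref, hom_alt,
#'   het_alt, summing to 1), `n_missing`, `n_haploid`.
#' @export
genotype_distribution <- function(calls) {
  diploid <- c("hom_ref", "het_ref", "hom_alt", "het_alt")
  g <- calls$gclass
  nd <- sum(g %in% diploid)
  props <- if (nd) {
    vapply(diploid, function(k) sum(g == k) / nd, numeric(1))
  } else stats::setNames(rep(NA_real_, 4), diploid)
  list(proportions = props, n_missing = sum(g == "missing"),
       n_haploid = sum(g == "haploid"))
}
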