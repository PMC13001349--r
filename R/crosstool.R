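## Pairwise consistency between callsets over catalog-synchronized loci.
## The catalog is the positional reference: each callset was already
## anchored to catalog loci during harmonization, so synchronization reduces
## to aligning the call tables on (locus_id, sample_id) and recording how
## each caller treated the locus boundaries.

#' Synchronize callsets on the catalog
#'
#' Produces one row per catalog locus, sample and callset, with the call's
#' alleles (absent cells where the callset did not produce a usable call)
#' and a flag describing whether the caller widened, narrowed, or kept the
#' catalog boundaries.
#'
#' @param callsets Named list of [tr_calls()] tables.
#' @param catalog A [tr_catalog()].
#' @return Long data.frame with columns `locus_id`, `sample_id`, `callset`,
#'   `a1_seq`, `a2_seq`, `a1_len`, `a2_len`, `called`, `boundary`.
#' @export
synchronize <- function(callsets, catalog) {
  stopifnot(is.list(callsets), !is.null(names(callsets)))
  samples <- sort(unique(unlist(lapply(callsets, function(x) x$sample_id))))
  grid <- expand.grid(locus_id = catalog$locus_id, sample_id = samples,
                      callset = names(callsets), stringsAsFactors = FALSE)
  cstart <- stats::setNames(catalog$start, catalog$locus_id)
  cend <- stats::setNames(catalog$end, catalog$locus_id)
  out <- vector("list", length(callsets))
  for (ci in seq_along(callsets)) {
    cs <- callsets[[ci]]
    sub <- grid[grid$callset == names(callsets)[ci], , drop = FALSE]
    j <- match(paste(sub$locus_id, sub$sample_id),
               paste(cs$locus_id, cs$sample_id))
    called <- !is.na(j) & !is.na(cs$a1_len[j])
    width_lo <- cs$reported_start[j] < cstart[sub$locus_id]
    width_hi <- cs$reported_end[j] > cend[sub$locus_id]
    narrow <- cs$reported_start[j] > cstart[sub$locus_id] |
      cs$reported_end[j] < cend[sub$locus_id]
    boundary <- ifelse(!called, NA_character_,
                ifelse((width_lo | width_hi) & narrow, "mixed",
                ifelse(width_lo | width_hi, "widened",
                ifelse(narrow, "narrowed", "unchanged"))))
    sub$a1_seq <- ifelse(called, cs$a1_seq[j], NA_character_)
    sub$a2_seq <- ifelse(called, cs$a2_seq[j], NA_character_)
    sub$a1_len <- ifelse(called, cs$a1_len[j], NA_integer_)
    sub$a2_len <- ifelse(called, cs$a2_len[j], NA_integer_)
    sub$called <- called
    sub$boundary <- boundary
    out[[ci]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# distance between two synchronized cells: list(len, lev or NA)
cell_distance <- function(a, b) {
  ta <- c(a$a1_len, a$a2_len); tb <- c(b$a1_len, b$a2_len)
  ta <- ta[!is.na(ta)]; tb <- tb[!is.na(tb)]
  pr_len <- pair_alleles(ta, tb, metric = "length")
  sa <- c(a$a1_seq, a$a2_seq); sb <- c(b$a1_seq, b$a2_seq)
  sa <- sa[!is.na(sa)]; sb <- sb[!is.na(sb)]
  lev <- if (length(sa) == length(ta) && length(sb) == length(tb) &&
             length(sa) > 0L && length(sb) > 0L) {
    pair_alleles(sa, sb, metric = "edit")$total
  } else NA_real_
  list(len = pr_len$total, lev = lev)
}

#' Pairwise consistency matrix between callsets
#'
#' For every pair of callsets, pairs alleles at each commonly called locus
#' to minimize total deviation and averages the per-locus distances over
#' loci and samples. The per-locus distance is the sum of the two paired
#' per-allele distances (configurable to the per-allele mean). Levenshtein
#' means are reported only where both sides carry sequences.
#'
#' @param callsets Named list of [tr_calls()] tables.
#' @param catalog A [tr_catalog()].
#' @param mode `"all_common"` restricts every comparison to loci called by
#'   all callsets; `"pairwise_common"` uses each pair's own common loci.
#' @param per_locus `"sum"` (default) or `"mean"` over the paired alleles.
#' @return List with `table` (long data.frame of pair summaries) and
#'   `len_matrix` / `lev_matrix` (square matrices; `combined` holds the
#'   conventional layout with mean Levenshtein in the upper triangle and
#'   mean absolute length difference in the lower).
#' @export
pairwise_matrix <- function(callsets, catalog,
                            mode = c("all_common", "pairwise_common"),
                            per_locus = c("sum", "mean")) {
  mode <- match.arg(mode)
  per_locus <- match.arg(per_locus)
  if (length(callsets) < 2L) stop("need at least two callsets")
  sync <- synchronize(callsets, catalog)
  ids <- names(callsets)
  key <- paste(sync$locus_id, sync$sample_id)
  called_by <- tapply(sync$called, list(key, sync$callset), isTRUE)
  all_common_keys <- rownames(called_by)[rowSums(called_by) == ncol(called_by)]
  n <- length(ids)
  len_m <- lev_m <- matrix(0, n, n, dimnames = list(ids, ids))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    si <- sync[sync$callset == ids[i], , drop = FALSE]
    sj <- sync[sync$callset == ids[j], , drop = FALSE]
    ki <- paste(si$locus_id, si$sample_id)
    common <- if (mode == "all_common") all_common_keys else {
      intersect(ki[si$called], paste(sj$locus_id, sj$sample_id)[sj$called])
    }
    mi <- match(common, ki)
    mj <- match(common, paste(sj$locus_id, sj$sample_id))
    if (!length(common)) {
      rows[[length(rows) + 1]] <- data.frame(
        a = ids[i], b = ids[j], n_common = 0L, mean_len = NA_real_,
        mean_lev = NA_real_, stringsAsFactors = FALSE)
      len_m[i, j] <- len_m[j, i] <- NA_real_
      lev_m[i, j] <- lev_m[j, i] <- NA_real_
      next
    }
    lens <- levs <- numeric(length(common))
    for (k in seq_along(common)) {
      d <- cell_distance(si[mi[k], ], sj[mj[k], ])
      div <- if (per_locus == "mean") 2 else 1
      lens[k] <- d$len / div
      levs[k] <- if (is.na(d$lev)) NA_real_ else d$lev / div
    }
    mean_len <- mean(lens)
    mean_lev <- if (all(is.na(levs))) NA_real_ else mean(levs, na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      a = ids[i], b = ids[j], n_common = length(common),
      mean_len = mean_len, mean_lev = mean_lev, stringsAsFactors = FALSE)
    len_m[i, j] <- len_m[j, i] <- mean_len
    lev_m[i, j] <- lev_m[j, i] <- mean_lev
  }
  combined <- len_m
  combined[upper.tri(combined)] <- lev_m[upper.tri(lev_m)]
  list(table = do.call(rbind, rows), len_matrix = len_m,
       lev_matrix = lev_m, combined = combined)
}

#' Loci where most callsets disagree with the truth
#'
#' @param callsets Named list of [tr_calls()] tables, one of which is the
#'   truth (e.g. assembly-derived).
#' @param catalog A [tr_catalog()].
#' @param truth Name of the truth callset in `callsets`.
#' @param k Minimum number of non-truth callsets that must disagree
#'   (nonzero distance to truth) for a locus to be reported.
#' @param metric `"length"` or `"edit"`.
#' @return Character vector of locus ids.
#' @export
discordant_loci <- function(callsets, catalog, truth, k,
                            metric = c("length", "edit")) {
  metric <- match.arg(metric)
  stopifnot(truth %in% names(callsets))
  others <- setdiff(names(callsets), truth)
  if (k > length(others)) stop("k exceeds the number of non-truth callsets")
  sync <- synchronize(callsets, catalog)
  tsync <- sync[sync$callset == truth, , drop = FALSE]
  keys <- paste(tsync$locus_id, tsync$sample_id)
  n_disagree <- stats::setNames(integer(length(keys)), keys)
  for (cs in others) {
    ssync <- sync[sync$callset == cs, , drop = FALSE]
    m <- match(keys, paste(ssync$locus_id, ssync$sample_id))
    for (q in seq_along(keys)) {
      if (!isTRUE(tsync$called[q]) || is.na(m[q]) ||
          !isTRUE(ssync$called[m[q]])) next
      d <- cell_distance(tsync[q, ], ssync[m[q], ])
      val <- if (metric == "edit" && !is.na(d$lev)) d$lev else d$len
      if (val > 0) n_disagree[q] <- n_disagree[q] + 1L
    }
  }
  unique(tsync$locus_id[n_disagree >= k])
}
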