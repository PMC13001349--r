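## Trio Mendelian consistency for TR genotypes. Each diploid genotype is
## encoded as the feature vector [L1, L2, dL1, dL2] where Li are the two
## allele lengths in bp and dLi = Li - Lref are deviations from the locus
## reference allele length. Transmission candidates take one allele from
## each parent; with both child orderings this yields eight candidate
## pairings, and the minimum Manhattan distance between the candidate and
## the child vector is the locus inheritance distance. When all members
## share Lref the dL terms duplicate the L terms, so the distance is always
## even and half of it equals the total per-allele length discrepancy in bp.

#' Minimum-distance transmission search for one trio locus
#'
#' Enumerates the four parental transmission combinations (one allele from
#' each parent) and both orderings of the child's allele pair, computes the
#' Manhattan distance between each candidate feature vector and the child's,
#' and returns the minimum. Ties are resolved to the first candidate in
#' enumeration order (father allele index, then mother allele index, then
#' child ordering).
#'
#' @param child,father,mother Numeric length-2 vectors of allele lengths
#'   (bp).
#' @param lref Reference allele length at the locus (bp).
#' @return List with `distance` (Manhattan, bp-units), `half_distance`, and
#'   `pairing` (named vector: father allele index, mother allele index,
#'   child ordering 1 = as given, 2 = swapped).
#' @export
inheritance_distance <- function(child, father, mother, lref) {
  stopifnot(length(child) == 2L, length(father) == 2L, length(mother) == 2L,
            !anyNA(c(child, father, mother)))
  fv <- function(l1, l2) c(l1, l2, l1 - lref, l2 - lref)
  best <- Inf
  best_pair <- c(f = NA_integer_, m = NA_integer_, o = NA_integer_)
  for (f in 1:2) for (m in 1:2) for (o in 1:2) {
    ch <- if (o == 1L) child else child[2:1]
    d <- sum(abs(fv(father[f], mother[m]) - fv(ch[1], ch[2])))
    if (d < best) {
      best <- d
      best_pair <- c(f = f, m = m, o = o)
    }
  }
  list(distance = best, half_distance = best / 2, pairing = best_pair)
}

#' Classify a trio locus by its inheritance distance
#'
#' Uses the half-distance h (total per-allele discrepancy in bp): h = 0 is
#' MATCH (the child's alleles are exactly explained by one allele from each
#' parent); h equal to the one-off cutoff (default 1 bp) is ONE_OFF; h
#' within one motif length is MLEN_OFF; anything larger is MISMATCH.
#'
#' @param distance Manhattan inheritance distance (bp-units).
#' @param motif_length Motif length of the locus (bp).
#' @param one_off_max Upper bound of the ONE_OFF band in bp of
#'   half-distance; default 1 (one allele off by exactly 1 bp).
#' @return One of `"MATCH"`, `"ONE_OFF"`, `"MLEN_OFF"`, `"MISMATCH"`.
#' @export
classify_mendelian <- function(distance, motif_length, one_off_max = 1) {
  h <- distance / 2
  ifelse(h == 0, "MATCH",
         ifelse(h <= one_off_max, "ONE_OFF",
                ifelse(h <= motif_length, "MLEN_OFF", "MISMATCH")))
}

mendel_class_levels <- c("MATCH", "ONE_OFF", "MLEN_OFF", "MISMATCH")

is_autosome <- function(chrom) {
  !grepl("^(chr)?([XYM]|MT)$", chrom, ignore.case = TRUE)
}

#' Trio Mendelian-consistency evaluation over a catalog
#'
#' Merges the three callsets by catalog locus id, keeps autosomal loci where
#' all members have a diploid call, runs the transmission search at each,
#' and classifies the result. Lref is taken from the child callset's
#' reference allele length; when the members disagree on it (coordinate
#' widening by the caller), the catalog reference length is substituted and
#' the substitution counted.
#'
#' @param child,father,mother [tr_calls()] tables.
#' @param catalog A [tr_catalog()].
#' @param one_off_max Passed to [classify_mendelian()].
#' @return List with `loci` (per-locus data.frame: distance, half-distance,
#'   class, child gclass, motif bin), `summary` (per-stratum class counts
#'   and good rate), `good_rate` (overall), `n_excluded_missing`,
#'   `n_lref_substituted`.
#' @export
trio_report <- function(child, father, mother, catalog, one_off_max = 1) {
  mot <- stats::setNames(catalog$motif_length, catalog$locus_id)
  cat_ref <- stats::setNames(catalog$end - catalog$start, catalog$locus_id)
  auto <- catalog$locus_id[is_autosome(catalog$chrom)]
  pick <- function(calls) {
    calls <- calls[calls$locus_id %in% auto, , drop = FALSE]
    calls[match(auto, calls$locus_id), , drop = FALSE]
  }
  ch <- pick(child); fa <- pick(father); mo <- pick(mother)
  diploid <- function(df) {
    !is.na(df$locus_id) & !is.na(df$a1_len) & !is.na(df$a2_len)
  }
  usable <- diploid(ch) & diploid(fa) & diploid(mo)
  n_excluded <- sum(!usable)
  if (!any(usable)) stop("trio_report: no shared diploid autosomal loci")
  idx <- which(usable)
  n_sub <- 0L
  res <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lid <- auto[i]
    lrefs <- c(ch$ref_len[i], fa$ref_len[i], mo$ref_len[i])
    lref <- ch$ref_len[i]
    if (is.na(lref) || length(unique(stats::na.omit(lrefs))) > 1L) {
      lref <- unname(cat_ref[lid])
      n_sub <- n_sub + 1L
    }
    id <- inheritance_distance(c(ch$a1_len[i], ch$a2_len[i]),
                               c(fa$a1_len[i], fa$a2_len[i]),
                               c(mo$a1_len[i], mo$a2_len[i]), lref)
    res[[k]] <- data.frame(locus_id = lid, distance = id$distance,
                           half_distance = id$half_distance,
                           stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, res)
  loci$motif_length <- unname(mot[loci$locus_id])
  loci$mclass <- classify_mendelian(loci$distance, loci$motif_length,
                                    one_off_max)
  loci$child_gclass <- ch$gclass[idx]
  loci$motif_bin <- motif_bin(loci$motif_length)
  strat <- function(key) {
    do.call(rbind, lapply(split(loci, loci[[key]]), function(sub) {
      counts <- table(factor(sub$mclass, levels = mendel_class_levels))
      data.frame(stratum = sub[[key]][1], n = nrow(sub),
                 t(as.matrix(counts)),
                 good_rate = sum(counts[c("MATCH", "ONE_OFF", "MLEN_OFF")]) /
                   nrow(sub),
                 stringsAsFactors = FALSE)
    }))
  }
  summary <- rbind(cbind(axis = "gclass", strat("child_gclass")),
                   cbind(axis = "motif_bin", strat("motif_bin")))
  rownames(summary) <- NULL
  good <- mean(loci$mclass %in% c("MATCH", "ONE_OFF", "MLEN_OFF"))
  list(loci = loci, summary = summary, good_rate = good,
       n_excluded_missing = n_excluded, n_lref_substituted = n_sub)
}

#' Expected de novo TR mutations per generation in a catalog
#'
#' Small interpretation aid for trio results: with a per-locus, per-
#' generation de novo mutation rate on the order of 1e-5, a catalog of ~43k
#' loci is expected to harbour fewer than one true de novo mutation per
#' generation, so essentially all Mendelian inconsistencies observed at that
#' scale are genotyping errors.
#'
#' @param n_loci Number of catalog loci.
#' @param rate_per_locus Per-locus per-generation mutation rate.
#' @return Expected number of de novo mutations (`n_loci * rate`).
#' @export
expected_de_novo <- function(n_loci, rate_per_locus = 1e-5) {
  stopifnot(n_loci >= 0, rate_per_locus >= 0)
  n_loci * rate_per_locus
}
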