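# Independent oracles: each re-derives the quantity under test by a
# different algorithmic route (row-vectorized Wagner-Fischer DP, exhaustive
# enumeration, linear scan) and is kept free of the package's internals.

# Wagner-Fischer edit distance, row by row; the within-row dependency of
# insertions is resolved with the cummin trick so the oracle stays fast in
# pure R while remaining an independent DP implementation.
lev_oracle <- function(a, b) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  prev <- 0:n
  for (i in seq_len(m)) {
    sub_cost <- prev[1:n] + (av[i] != bv)
    del_cost <- prev[2:(n + 1)] + 1
    tmp <- c(prev[1] + 1, pmin(sub_cost, del_cost))
    # row[j] = min_{k<=j} (tmp[k] + (j-k)) for the insertion chain
    row <- cummin(tmp - 0:n) + 0:n
    prev <- row
  }
  prev[n + 1]
}

# Exhaustive minimum-deviation pairing over all orderings.
pair_oracle <- function(tool, truth, dist_fun) {
  nt <- length(tool); nr <- length(truth)
  if (nt == 2L && nr == 2L) {
    direct <- dist_fun(tool[1], truth[1]) + dist_fun(tool[2], truth[2])
    crossed <- dist_fun(tool[1], truth[2]) + dist_fun(tool[2], truth[1])
    min(direct, crossed)
  } else if (nt == 1L) {
    min(vapply(seq_len(nr), function(j) dist_fun(tool[1], truth[j]),
               numeric(1)))
  } else {
    min(vapply(seq_len(nt), function(i) dist_fun(tool[i], truth[1]),
               numeric(1)))
  }
}

len_dist <- function(x, y) abs(nchar_or_num(x) - nchar_or_num(y))
nchar_or_num <- function(x) if (is.character(x)) nchar(x) else x

# All eight candidate transmissions, written out directly.
trio_oracle <- function(child, father, mother, lref) {
  fv <- function(l1, l2) c(l1, l2, l1 - lref, l2 - lref)
  best <- Inf
  for (f in father) for (m in mother) {
    for (ch in list(child, rev(child))) {
      d <- sum(abs(fv(f, m) - fv(ch[1], ch[2])))
      best <- min(best, d)
    }
  }
  best
}

# Brute-force best-overlap assignment with the smaller-start tie-break.
assign_oracle <- function(chrom, start, end, catalog) {
  best <- NA_character_
  best_ov <- 0L
  for (i in seq_len(nrow(catalog))) {
    if (catalog$chrom[i] != chrom) next
    ov <- min(end, catalog$end[i]) - max(start, catalog$start[i])
    if (ov >= 1L && ov > best_ov) {
      best <- catalog$locus_id[i]
      best_ov <- ov
    }
    # catalog is start-sorted, so the first max wins ties automatically
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
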