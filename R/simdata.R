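## Seed-reproducible synthetic truth worlds: a reference genome with planted
## perfect repeats, a catalog, diploid haplotypes with known length/sequence
## mutations, exact alignment CIGARs derived from the edit list, trio
## transmissions, and error-injected callsets in each VCF dialect. Every
## injected perturbation is recorded in a ledger so downstream metrics can
## be checked for exact recovery. Error injection is count-deterministic
## (floor(p * N) loci chosen by a seeded shuffle), not Bernoulli, so
## recovery assertions are exact rather than statistical.

#' Simulation configuration
#'
#' Defaults describe a compact but realistic test genome: isolated perfect
#' STR loci (motifs 1-6 bp) separated by >= 25 bp of non-repetitive flank,
#' and a mutation model in which ~8.5% of haplotype alleles differ from the
#' reference (so that around 84% of diploid genotypes are homozygous
#' reference, matching the invariant-majority structure of real TR
#' catalogs).
#'
#' @param seed Integer master seed.
#' @param n_chromosomes Number of reference chromosomes (`chr1..chrN`).
#' @param motif_lengths Integer vector of motif lengths to plant.
#' @param loci_per_motif Loci planted per motif length.
#' @param flank Flank length between consecutive loci (bp, >= 25).
#' @param units_range Range of reference repeat unit counts, `c(min, max)`.
#' @param p_variant Probability that a haplotype allele differs from the
#'   reference allele.
#' @param expansion_units Possible unit-count changes (magnitude) for a
#'   variant allele; sign is random (contractions never delete past one
#'   remaining unit unless `allow_full_deletion`).
#' @param p_interruption Probability that a variant allele additionally
#'   carries one internal substitution.
#' @param p_flank_indel Probability that the flank preceding a locus
#'   carries a 1-3 bp indel in a haplotype (exercises CIGAR walking).
#' @param minus_strand_frac Fraction of haplotype contigs stored reverse
#'   complemented (aligned on the minus strand).
#' @param allow_full_deletion Allow a contraction to delete the whole
#'   allele.
#' @param chrom_names Optional explicit chromosome names (e.g. to include
#'   `chrX` for autosome-filter behavior).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, motif_lengths = 1:6,
                       loci_per_motif = 25L, flank = 30L,
                       units_range = c(4L, 12L), p_variant = 0.085,
                       expansion_units = 1:3, p_interruption = 0,
                       p_flank_indel = 0, minus_strand_frac = 0,
                       allow_full_deletion = FALSE, chrom_names = NULL) {
  stopifnot(flank >= 25L, all(motif_lengths >= 1L), loci_per_motif >= 1L,
            p_variant >= 0, p_variant <= 1, p_interruption >= 0,
            p_interruption <= 1, p_flank_indel >= 0, p_flank_indel <= 1,
            minus_strand_frac >= 0, minus_strand_frac <= 1)
  if (is.null(chrom_names)) {
    chrom_names <- paste0("chr", seq_len(n_chromosomes))
  }
  structure(list(seed = as.integer(seed), chrom_names = chrom_names,
                 motif_lengths = as.integer(motif_lengths),
                 loci_per_motif = as.integer(loci_per_motif),
                 flank = as.integer(flank),
                 units_range = as.integer(units_range),
                 p_variant = p_variant,
                 expansion_units = as.integer(expansion_units),
                 p_interruption = p_interruption,
                 p_flank_indel = p_flank_indel,
                 minus_strand_frac = minus_strand_frac,
                 allow_full_deletion = allow_full_deletion),
            class = "sim_config")
}

# sample() that treats a length-1 vector as a single value, not a range
pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_motif <- function(len) {
  repeat {
    m <- rand_dna(len)
    # reject motifs that are themselves repeats of a shorter unit, so the
    # planted motif length is the true repeat unit length
    if (len == 1L) return(m)
    sub <- vapply(seq_len(len - 1L), function(k) {
      len %% k == 0L && strrep(substr(m, 1L, k), len %/% k) == m
    }, logical(1))
    if (!any(sub)) return(m)
  }
}

# flank whose boundary bases never extend the adjacent repeats cyclically:
# the base after a repeat must differ from the motif's first character, the
# base before a repeat from its last character
rand_flank <- function(n, prev_motif = NULL, next_motif = NULL) {
  f <- strsplit(rand_dna(n), "")[[1]]
  if (!is.null(prev_motif)) {
    first_prev <- substr(prev_motif, 1L, 1L)
    while (f[1] == first_prev) f[1] <- sample(c("A", "C", "G", "T"), 1)
  }
  if (!is.null(next_motif)) {
    last_next <- substr(next_motif, nchar(next_motif), nchar(next_motif))
    while (f[n] == last_next) f[n] <- sample(c("A", "C", "G", "T"), 1)
  }
  paste(f, collapse = "")
}

#' Build a synthetic truth world
#'
#' Plants perfect repeats into freshly generated reference chromosomes and
#' returns the reference sequences plus the matching catalog. Loci of each
#' configured motif length are distributed round-robin across chromosomes,
#' separated by non-repetitive flank.
#'
#' @param config A [sim_config()].
#' @return A `tr_world` list with `config`, `reference` (named character
#'   vector), `catalog`, and `ref_units` (named unit counts per locus).
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    specs <- expand.grid(motif_len = config$motif_lengths,
                         i = seq_len(config$loci_per_motif))
    specs <- specs[sample(nrow(specs)), , drop = FALSE]
    specs$chrom <- rep_len(config$chrom_names, nrow(specs))
    chrom_seq <- stats::setNames(rep("", length(config$chrom_names)),
                                 config$chrom_names)
    loci <- list()
    for (chr in config$chrom_names) {
      sub <- specs[specs$chrom == chr, , drop = FALSE]
      pos <- 0L
      parts <- character(0)
      prev_motif <- NULL
      for (r in seq_len(nrow(sub))) {
        motif <- rand_motif(sub$motif_len[r])
        units <- pick(seq(config$units_range[1], config$units_range[2]))
        fl <- rand_flank(config$flank, prev_motif, motif)
        allele <- strrep(motif, units)
        parts <- c(parts, fl, allele)
        start <- pos + config$flank
        end <- start + nchar(allele)
        loci[[length(loci) + 1]] <- data.frame(
          chrom = chr, start = start, end = end, motif = motif,
          units = units, stringsAsFactors = FALSE)
        pos <- end
        prev_motif <- motif
      }
      parts <- c(parts, rand_flank(config$flank, prev_motif, NULL))
      chrom_seq[chr] <- paste(parts, collapse = "")
    }
    ldf <- do.call(rbind, loci)
    catalog <- tr_catalog(ldf$chrom, ldf$start, ldf$end, ldf$motif)
    # re-sorts by (chrom, start); carry unit counts alongside
    key <- paste0(ldf$chrom, ":", ldf$start, "-", ldf$end)
    ref_units <- stats::setNames(ldf$units, key)[catalog$locus_id]
    structure(list(config = config, reference = chrom_seq,
                   catalog = catalog, ref_units = ref_units),
              class = "tr_world")
  })
}

ref_allele_seq <- function(world, locus_row) {
  substr(world$reference[[locus_row$chrom]], locus_row$start + 1L,
         locus_row$end)
}

# Continue the repeat pattern cyclically to extend an allele by `k` bases
# (rotation-aware so that any extension point yields a perfect repeat).
extend_repeat <- function(allele, motif, k) {
  phase <- nchar(allele) %% nchar(motif)
  tail <- paste(rep(motif, ceiling((phase + k) / nchar(motif)) + 1L),
                collapse = "")
  paste0(allele, substr(tail, phase + 1L, phase + k))
}

#' Simulate one diploid sample of a truth world
#'
#' Draws two haplotypes under the configured mutation model, building each
#' haplotype contig base-by-base alongside the exact CIGAR of its alignment
#' to the reference (insertions and deletions appear exactly where the
#' edits were planted; all aligned stretches are emitted as M operations).
#' Optionally stores contigs reverse complemented with minus-strand
#' alignment records.
#'
#' @param world A `tr_world` from [build_world()].
#' @param sample_id Sample name.
#' @param seed Seed for this sample's mutations.
#' @return A `tr_sample` list: `sample_id`, `truth` (per-locus data.frame
#'   with both haplotype allele sequences and lengths), `haplotypes` (list
#'   of two lists with `sequences` and `alignments`).
#' @export
sim_sample <- function(world, sample_id, seed) {
  cfg <- world$config
  cat_df <- world$catalog
  withr_seed(seed, {
    haps <- vector("list", 2L)
    allele_seqs <- matrix(NA_character_, nrow(cat_df), 2L)
    for (h in 1:2) {
      contigs <- character(0)
      alns <- list()
      for (chr in cfg$chrom_names) {
        sub <- which(cat_df$chrom == chr)
        ref_seq <- world$reference[[chr]]
        contig_parts <- character(0)
        ops <- character(0)   # e.g. "30M", built then collapsed
        ref_pos <- 0L
        add_M <- function(n) if (n > 0L) ops <<- c(ops, paste0(n, "M"))
        for (i in sub) {
          # flank between ref_pos and locus start
          flank_len <- cat_df$start[i] - ref_pos
          flank_seq <- substr(ref_seq, ref_pos + 1L, cat_df$start[i])
          if (stats::runif(1) < cfg$p_flank_indel && flank_len >= 15L) {
            k <- sample(1:3, 1)
            at <- flank_len %/% 2L
            if (stats::runif(1) < 0.5) {  # insertion of k random bases
              ins <- rand_dna(k)
              contig_parts <- c(contig_parts,
                                substr(flank_seq, 1L, at), ins,
                                substr(flank_seq, at + 1L, flank_len))
              add_M(at); ops <- c(ops, paste0(k, "I")); add_M(flank_len - at)
            } else {                      # deletion of k flank bases
              contig_parts <- c(contig_parts,
                                substr(flank_seq, 1L, at),
                                substr(flank_seq, at + k + 1L, flank_len))
              add_M(at); ops <- c(ops, paste0(k, "D"))
              add_M(flank_len - at - k)
            }
          } else {
            contig_parts <- c(contig_parts, flank_seq)
            add_M(flank_len)
          }
          ref_pos <- cat_df$start[i]
          # the locus allele
          ref_allele <- substr(ref_seq, cat_df$start[i] + 1L, cat_df$end[i])
          ref_len <- nchar(ref_allele)
          motif <- cat_df$motif[i]
          mlen <- nchar(motif)
          units <- world$ref_units[cat_df$locus_id[i]]
          if (stats::runif(1) < cfg$p_variant) {
            du <- pick(cfg$expansion_units)
            max_contract <- if (cfg$allow_full_deletion) units else units - 1L
            sign <- if (stats::runif(1) < 0.5 && du <= max_contract) -1L else 1L
            if (sign > 0L) {
              allele <- extend_repeat(ref_allele, motif, du * mlen)
              add_M(1L)
              ops <- c(ops, paste0(du * mlen, "I"))
              add_M(ref_len - 1L)
              # contig carries ref first base, insertion, rest of ref allele
              contig_allele <- allele
            } else if (du == units) {
              allele <- ""
              ops <- c(ops, paste0(ref_len, "D"))
              contig_allele <- ""
            } else {
              cut <- du * mlen
              allele <- paste0(substr(ref_allele, 1L, 1L),
                               substr(ref_allele, cut + 2L, ref_len))
              add_M(1L)
              ops <- c(ops, paste0(cut, "D"))
              add_M(ref_len - 1L - cut)
              contig_allele <- allele
            }
            if (nchar(allele) > 0L && stats::runif(1) < cfg$p_interruption) {
              p <- sample(nchar(allele), 1)
              old <- substr(allele, p, p)
              new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
              substr(allele, p, p) <- new
              contig_allele <- allele
            }
          } else {
            allele <- ref_allele
            contig_allele <- ref_allele
            add_M(ref_len)
          }
          contig_parts <- c(contig_parts, contig_allele)
          allele_seqs[i, h] <- allele
          ref_pos <- cat_df$end[i]
        }
        tail_len <- nchar(ref_seq) - ref_pos
        contig_parts <- c(contig_parts,
                          substr(ref_seq, ref_pos + 1L, nchar(ref_seq)))
        add_M(tail_len)
        contig_seq <- paste(contig_parts, collapse = "")
        cigar <- collapse_cigar(ops)
        contig <- paste(sample_id, paste0("h", h), chr, sep = "_")
        strand <- if (stats::runif(1) < cfg$minus_strand_frac) "-" else "+"
        if (strand == "-") {
          # SAM convention: the CIGAR stays in reference order and applies
          # to the reverse-complemented query, so only the stored sequence
          # flips
          contig_seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(contig_seq)))
        }
        contigs[contig] <- contig_seq
        alns[[length(alns) + 1]] <- data.frame(
          contig = contig, contig_length = nchar(contig_seq),
          ref_chrom = chr, ref_start = 0L, strand = strand, cigar = cigar,
          stringsAsFactors = FALSE)
      }
      haps[[h]] <- list(sequences = contigs, alignments = do.call(rbind, alns))
    }
    truth <- data.frame(locus_id = cat_df$locus_id,
                        a1_seq = allele_seqs[, 1], a2_seq = allele_seqs[, 2],
                        a1_len = nchar(allele_seqs[, 1]),
                        a2_len = nchar(allele_seqs[, 2]),
                        stringsAsFactors = FALSE)
    structure(list(sample_id = sample_id, truth = truth, haplotypes = haps),
              class = "tr_sample")
  })
}

collapse_cigar <- function(ops) {
  if (!length(ops)) return("")
  len <- as.integer(sub("[MID]$", "", ops))
  op <- sub("^\\d+", "", ops)
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (!length(op)) return("")
  out_op <- character(0); out_len <- integer(0)
  for (i in seq_along(op)) {
    if (length(out_op) && out_op[length(out_op)] == op[i]) {
      out_len[length(out_len)] <- out_len[length(out_len)] + len[i]
    } else {
      out_op <- c(out_op, op[i]); out_len <- c(out_len, len[i])
    }
  }
  paste0(out_len, out_op, collapse = "")
}

#' Truth callset of a simulated sample
#'
#' @param world A `tr_world`.
#' @param sample A `tr_sample` from [sim_sample()].
#' @return A [tr_calls()] table at catalog coordinates with truth genotype
#'   classes.
#' @export
truth_calls <- function(world, sample) {
  cat_df <- world$catalog
  tr <- sample$truth
  gcl <- vapply(seq_len(nrow(tr)), function(i) {
    ref_allele <- ref_allele_seq(world, cat_df[i, ])
    genotype_class(tr$a1_seq[i], tr$a2_seq[i], ref_allele)
  }, character(1))
  tr_calls(cat_df$locus_id, sample$sample_id, cat_df$chrom, cat_df$start,
           cat_df$end, cat_df$end - cat_df$start,
           tr$a1_seq, tr$a2_seq, tr$a1_len, tr$a2_len, gcl)
}

#' Error profile for callset emission
#'
#' Probabilities are converted to exact counts (`floor(p * N)`), and the
#' affected loci are chosen by a seeded shuffle, so injected-error recovery
#' is exact. Counts can also be given directly via the `n_*` arguments,
#' which take precedence.
#'
#' @param p_missing,p_off_by_1,p_off_by_motif,p_mismatch,p_seq_sub
#'   Per-class probabilities in `[0, 1]`.
#' @param n_missing,n_off_by_1,n_off_by_motif,n_mismatch,n_seq_sub Exact
#'   counts (override probabilities).
#' @return An `error_profile` list.
#' @export
error_profile <- function(p_missing = 0, p_off_by_1 = 0, p_off_by_motif = 0,
                          p_mismatch = 0, p_seq_sub = 0,
                          n_missing = NULL, n_off_by_1 = NULL,
                          n_off_by_motif = NULL, n_mismatch = NULL,
                          n_seq_sub = NULL) {
  p <- c(p_missing, p_off_by_1, p_off_by_motif, p_mismatch, p_seq_sub)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(list(p_missing = p_missing, p_off_by_1 = p_off_by_1,
                 p_off_by_motif = p_off_by_motif, p_mismatch = p_mismatch,
                 p_seq_sub = p_seq_sub, n_missing = n_missing,
                 n_off_by_1 = n_off_by_1, n_off_by_motif = n_off_by_motif,
                 n_mismatch = n_mismatch, n_seq_sub = n_seq_sub),
            class = "error_profile")
}

profile_counts <- function(profile, n) {
  cnt <- function(n_exact, p) if (!is.null(n_exact)) n_exact else floor(p * n)
  c(missing = cnt(profile$n_missing, profile$p_missing),
    off_by_1 = cnt(profile$n_off_by_1, profile$p_off_by_1),
    off_by_motif = cnt(profile$n_off_by_motif, profile$p_off_by_motif),
    mismatch = cnt(profile$n_mismatch, profile$p_mismatch),
    seq_sub = cnt(profile$n_seq_sub, profile$p_seq_sub))
}

# Apply one named perturbation to an allele sequence; returns the perturbed
# sequence (length changes follow the repeat pattern so sequences remain
# realistic) and the signed magnitude in bp.
perturb_allele <- function(seq, motif, class, extra = 0L) {
  mlen <- nchar(motif)
  mag <- switch(class,
                off_by_1 = 1L,
                off_by_motif = mlen,
                mismatch = mlen + 1L + extra,
                seq_sub = 0L)
  if (class == "seq_sub") {
    p <- max(1L, nchar(seq) %/% 2L)
    old <- substr(seq, p, p)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(seq, p, p) <- new
    return(list(seq = seq, magnitude = 0L))
  }
  if (nchar(seq) - mag >= 1L && stats::runif(1) < 0.5) {
    list(seq = substr(seq, 1L, nchar(seq) - mag), magnitude = -mag)
  } else {
    list(seq = extend_repeat(seq, motif, mag), magnitude = mag)
  }
}

#' Emit an error-injected callset in a chosen VCF dialect
#'
#' Starts from the sample's truth alleles, injects exactly the configured
#' number of perturbations per error class at shuffle-selected loci
#' (off-by-motif perturbations are restricted to loci with motif length
#' >= 2 so the injected class is unambiguous), writes a VCF in the chosen
#' dialect, and returns the injection ledger.
#'
#' @param world A `tr_world`.
#' @param sample A `tr_sample`.
#' @param dialect `"sequence_refalt"`, `"symbolic_length"` or
#'   `"consensus_appended"`.
#' @param profile An [error_profile()].
#' @param path Output VCF path.
#' @param seed Seed for locus selection and perturbation signs.
#' @return Invisibly, a list with `path`, `ledger` (data.frame: locus_id,
#'   class, magnitude, allele) and `calls` (the perturbed [tr_calls()]
#'   truth-side table).
#' @export
emit_callset <- function(world, sample, dialect, profile = error_profile(),
                         path = tempfile(fileext = ".vcf"), seed = 1L) {
  cat_df <- world$catalog
  calls <- truth_calls(world, sample)
  n <- nrow(cat_df)
  counts <- profile_counts(profile, n)
  withr_seed(seed, {
    shuffled <- sample(n)
    # off_by_motif needs motif >= 2 to stay distinguishable from off_by_1;
    # pick its loci first from the eligible part of the shuffle
    eligible_mm <- shuffled[cat_df$motif_length[shuffled] >= 2L]
    sel <- list()
    sel$off_by_motif <- utils::head(eligible_mm, counts["off_by_motif"])
    remaining <- setdiff(shuffled, sel$off_by_motif)
    for (cls in c("missing", "off_by_1", "mismatch", "seq_sub")) {
      sel[[cls]] <- utils::head(remaining, counts[cls])
      remaining <- setdiff(remaining, sel[[cls]])
    }
    total_err <- sum(lengths(sel))
    if (total_err > n) stop("error profile selects more loci than exist")
    ledger <- list()
    for (cls in names(sel)) {
      for (i in sel[[cls]]) {
        if (cls == "missing") {
          calls$a1_seq[i] <- calls$a2_seq[i] <- NA_character_
          calls$a1_len[i] <- calls$a2_len[i] <- NA_integer_
          calls$gclass[i] <- "missing"
          ledger[[length(ledger) + 1]] <- data.frame(
            locus_id = cat_df$locus_id[i], class = cls, magnitude = NA_integer_,
            allele = NA_integer_, stringsAsFactors = FALSE)
          next
        }
        pb <- perturb_allele(calls$a1_seq[i], cat_df$motif[i], cls,
                             extra = sample(0:3, 1))
        calls$a1_seq[i] <- pb$seq
        calls$a1_len[i] <- nchar(pb$seq)
        ref_allele <- ref_allele_seq(world, cat_df[i, ])
        calls$gclass[i] <- genotype_class(calls$a1_seq[i], calls$a2_seq[i],
                                          ref_allele)
        ledger[[length(ledger) + 1]] <- data.frame(
          locus_id = cat_df$locus_id[i], class = cls,
          magnitude = pb$magnitude, allele = 1L, stringsAsFactors = FALSE)
      }
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else {
      data.frame(locus_id = character(), class = character(),
                 magnitude = integer(), allele = integer(),
                 stringsAsFactors = FALSE)
    }
    write_dialect_vcf(world, calls, sample$sample_id, dialect, path)
    invisible(list(path = path, ledger = ledger, calls = calls))
  })
}

write_dialect_vcf <- function(world, calls, sample_id, dialect, path) {
  cat_df <- world$catalog
  n <- nrow(cat_df)
  fix <- data.frame(chrom = cat_df$chrom, pos = cat_df$start + 1L,
                    id = cat_df$locus_id, ref = ".", alt = ".", qual = ".",
                    filter = ".", info = ".", format = "GT",
                    stringsAsFactors = FALSE)
  gt <- matrix(".", n, 1L, dimnames = list(NULL, sample_id))
  for (i in seq_len(n)) {
    ref_allele <- ref_allele_seq(world, cat_df[i, ])
    info_common <- paste0("END=", cat_df$end[i], ";MOTIF=", cat_df$motif[i])
    a <- c(calls$a1_seq[i], calls$a2_seq[i])
    miss <- is.na(calls$a1_len[i])
    if (dialect == "sequence_refalt") {
      fix$ref[i] <- ref_allele
      fix$info[i] <- info_common
      if (miss) { gt[i, 1] <- "./."; next }
      # a fully deleted allele is represented by the spanning-deletion
      # symbol "*", which the extractor maps back to the empty sequence
      a <- ifelse(!is.na(a) & a == "", "*", a)
      alts <- unique(a[!is.na(a) & a != ref_allele])
      fix$alt[i] <- if (length(alts)) paste(alts, collapse = ",") else "."
      idx <- match(a[!is.na(a)], c(fix$ref[i], alts)) - 1L
      gt[i, 1] <- paste(idx, collapse = "/")
    } else if (dialect == "symbolic_length") {
      fix$ref[i] <- "N"
      ref_len <- nchar(ref_allele)
      lens <- nchar(a[!is.na(a)])
      alt_lens <- unique(lens[lens != ref_len])
      # exercise both reference-length paths: RUL_REF on even loci, END
      # fallback on odd ones
      fix$info[i] <- if (i %% 2L == 0L) {
        paste0("RUL_REF=", ref_len, ";", info_common)
      } else info_common
      if (miss) { gt[i, 1] <- "./."; fix$alt[i] <- "."; next }
      if (length(alt_lens)) {
        fix$alt[i] <- paste(paste0("<TR", seq_along(alt_lens), ">"),
                            collapse = ",")
        fix$info[i] <- paste0(fix$info[i], ";RB=",
                              paste(alt_lens, collapse = ","))
      } else fix$alt[i] <- "."
      idx <- match(lens, c(ref_len, alt_lens)) - 1L
      gt[i, 1] <- paste(idx, collapse = "/")
    } else if (dialect == "consensus_appended") {
      fix$ref[i] <- "N"
      fix$alt[i] <- "."
      fix$info[i] <- info_common
      fix$format[i] <- "GT:CONS"
      if (miss) { gt[i, 1] <- "./.:."; next }
      aa <- a[!is.na(a)]
      # consensus alleles use a sentinel for full deletions
      aa_out <- ifelse(aa == "", "*", aa)
      if (length(aa) == 2L && aa[1] != aa[2]) {
        gt[i, 1] <- paste0("1/2:", aa_out[1], ",", aa_out[2])
      } else {
        gt[i, 1] <- paste0(if (length(aa) == 2L) "1/1" else "1", ":",
                           aa_out[1])
      }
    } else stop("unknown dialect: ", dialect)
  }
  x <- structure(list(fix = fix, gt = gt, samples = sample_id),
                 class = "tr_vcf")
  tr_vcf_write(x, path, contigs = vapply(world$reference, nchar, integer(1)))
  invisible(path)
}

#' Simulate a trio with controlled Mendelian violations
#'
#' Parents are drawn independently from the world's mutation model; the
#' child inherits one allele from each parent (random haplotype per locus).
#' Violations are then injected into the child's *callset* at
#' shuffle-selected autosomal loci: ONE_OFF perturbs one child allele by
#' exactly 1 bp, MLEN_OFF by more than 1 bp but within one motif length
#' (motif >= 2 loci only), MISMATCH by more than one motif length. Each
#' injection is verified against the transmission search so the forced
#' class is exact, and recorded in the ledger.
#'
#' @param world A `tr_world`.
#' @param n_one_off,n_mlen_off,n_mismatch Exact violation counts.
#' @param seed Seed for parental sampling, transmission and injection.
#' @return List with `father`, `mother`, `child` ([tr_calls()] tables),
#'   `ledger` (locus_id, forced_class, magnitude).
#' @export
make_trio <- function(world, n_one_off = 0L, n_mlen_off = 0L,
                      n_mismatch = 0L, seed = 1L) {
  father <- sim_sample(world, "father", seed = seed + 101L)
  mother <- sim_sample(world, "mother", seed = seed + 202L)
  cat_df <- world$catalog
  n <- nrow(cat_df)
  withr_seed(seed, {
    f_pick <- sample(1:2, n, replace = TRUE)
    m_pick <- sample(1:2, n, replace = TRUE)
    child_a1 <- ifelse(f_pick == 1L, father$truth$a1_seq, father$truth$a2_seq)
    child_a2 <- ifelse(m_pick == 1L, mother$truth$a1_seq, mother$truth$a2_seq)
    child <- tr_calls(cat_df$locus_id, "child", cat_df$chrom, cat_df$start,
                      cat_df$end, cat_df$end - cat_df$start,
                      child_a1, child_a2, nchar(child_a1), nchar(child_a2),
                      gclass = NA_character_)
    for (i in seq_len(n)) {
      child$gclass[i] <- genotype_class(child$a1_seq[i], child$a2_seq[i],
                                        ref_allele_seq(world, cat_df[i, ]))
    }
    fl <- c(father$truth$a1_len, father$truth$a2_len)
    auto <- which(is_autosome(cat_df$chrom))
    shuffled <- sample(auto)
    want <- c(ONE_OFF = n_one_off, MLEN_OFF = n_mlen_off,
              MISMATCH = n_mismatch)
    ledger <- list()
    used <- integer(0)
    for (cls in names(want)) {
      need <- want[[cls]]
      for (i in shuffled) {
        if (need == 0L) break
        if (i %in% used) next
        mlen <- cat_df$motif_length[i]
        if (cls == "MLEN_OFF" && mlen < 2L) next
        mags <- switch(cls,
                       ONE_OFF = 1L,
                       MLEN_OFF = seq(2L, mlen),
                       MISMATCH = mlen + 1L + 0:3)
        forced <- force_child_class(world, father, mother, child, i, cls,
                                    mags)
        if (is.null(forced)) next
        child$a1_seq[i] <- forced$a1_seq
        child$a2_seq[i] <- forced$a2_seq
        child$a1_len[i] <- nchar(forced$a1_seq)
        child$a2_len[i] <- nchar(forced$a2_seq)
        child$gclass[i] <- genotype_class(child$a1_seq[i], child$a2_seq[i],
                                          ref_allele_seq(world, cat_df[i, ]))
        ledger[[length(ledger) + 1]] <- data.frame(
          locus_id = cat_df$locus_id[i], forced_class = cls,
          magnitude = forced$magnitude, stringsAsFactors = FALSE)
        used <- c(used, i)
        need <- need - 1L
      }
      if (need > 0L) {
        stop("could not place ", need, " ", cls, " violations; ",
             "world too small or motifs too short")
      }
    }
    ledger <- if (length(ledger)) do.call(rbind, ledger) else {
      data.frame(locus_id = character(), forced_class = character(),
                 magnitude = integer(), stringsAsFactors = FALSE)
    }
    list(father = truth_calls(world, father),
         mother = truth_calls(world, mother),
         child = child, ledger = ledger)
  })
}

# Try magnitudes/signs/alleles until the transmission search confirms the
# forced Mendelian class at locus i; NULL when impossible at this locus.
force_child_class <- function(world, father, mother, child, i, cls, mags) {
  cat_row <- world$catalog[i, ]
  motif <- cat_row$motif
  lref <- cat_row$end - cat_row$start
  fa <- c(father$truth$a1_len[i], father$truth$a2_len[i])
  mo <- c(mother$truth$a1_len[i], mother$truth$a2_len[i])
  for (mag in mags) for (sgn in c(1L, -1L)) for (al in 1:2) {
    a1 <- child$a1_seq[i]; a2 <- child$a2_seq[i]
    tgt <- if (al == 1L) a1 else a2
    new_len <- nchar(tgt) + sgn * mag
    if (new_len < 1L) next
    new_seq <- if (sgn > 0L) extend_repeat(tgt, motif, mag) else {
      substr(tgt, 1L, new_len)
    }
    if (al == 1L) a1 <- new_seq else a2 <- new_seq
    d <- inheritance_distance(c(nchar(a1), nchar(a2)), fa, mo, lref)
    if (classify_mendelian(d$distance, nchar(motif)) == cls) {
      return(list(a1_seq = a1, a2_seq = a2, magnitude = sgn * mag))
    }
  }
  NULL
}

#' Build a pathogenic-expansion fixture with planted detectability
#'
#' Generates a disease table over synthetic loci plus a callset and truth
#' table in which every row's detectability under the inheritance-mode
#' rules is planted by construction: detectable rows receive the required
#' number of alleles at or above threshold, undetectable rows stay strictly
#' below, and carriers of recessive conditions receive exactly one expanded
#' allele.
#'
#' @param plan data.frame with columns `sample_id`, `gene`, `status`
#'   (pathogenic / premutation / carrier / unaffected), `inheritance`,
#'   `detectable` (logical; ignored for carriers, which are planted with
#'   one expanded allele).
#' @param seed Seed for motif and threshold generation.
#' @return List with `diseases` (disease table), `calls` ([tr_calls()]),
#'   `truths` (truth table for [sensitivity()]).
#' @export
make_disease_fixture <- function(plan, seed = 1L) {
  withr_seed(seed, {
    genes <- unique(plan[, c("gene", "inheritance")])
    n_g <- nrow(genes)
    diseases <- data.frame(
      chrom = "chr1",
      start = seq(1000L, by = 5000L, length.out = n_g),
      gene = genes$gene, stringsAsFactors = FALSE)
    diseases$motif <- vapply(seq_len(n_g), function(i) rand_motif(3L), "")
    diseases$pathogenic_min <- sample(seq(120L, 300L, by = 3L), n_g,
                                      replace = TRUE)
    diseases$intermediate_min <- diseases$pathogenic_min - 30L
    diseases$inheritance <- genes$inheritance
    diseases$end <- diseases$start + 60L
    rows <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      d <- diseases[diseases$gene == plan$gene[i], , drop = FALSE]
      thr <- if (plan$status[i] == "premutation") d$intermediate_min else
        d$pathogenic_min
      above <- thr + sample(10:60, 1)
      below <- thr - sample(10:60, 1)
      short <- sample(30:60, 1)
      lens <- if (plan$status[i] == "carrier") {
        c(above, short)
      } else if (!isTRUE(plan$detectable[i])) {
        if (d$inheritance == "recessive") c(above, below) else c(below, short)
      } else if (d$inheritance == "recessive") {
        c(above, above + 3L)
      } else {
        c(above, short)
      }
      rows[[i]] <- data.frame(
        locus_id = paste0(d$chrom, ":", d$start, "-", d$end),
        sample_id = plan$sample_id[i], chrom = d$chrom,
        reported_start = d$start + sample(-40:40, 1),
        a1_len = lens[1], a2_len = lens[2], stringsAsFactors = FALSE)
    }
    calls_df <- do.call(rbind, rows)
    calls <- tr_calls(calls_df$locus_id, calls_df$sample_id, calls_df$chrom,
                      calls_df$reported_start,
                      calls_df$reported_start + 60L, 60L,
                      a1_len = calls_df$a1_len, a2_len = calls_df$a2_len,
                      gclass = "het_alt")
    truths <- plan[, c("sample_id", "gene", "status")]
    truths$sex <- NA_character_
    list(diseases = diseases, calls = calls, truths = truths)
  })
}
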