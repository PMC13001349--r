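aln_df <- function(cigar, ref_start = 0L, strand = "+", contig = "c1",
                   chrom = "chr1") {
  ops <- trbench:::parse_cigar(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  data.frame(contig = contig, contig_length = qlen, ref_chrom = chrom,
             ref_start = ref_start, strand = strand, cigar = cigar,
             stringsAsFactors = FALSE)
}

test_that("projection through M/I/D CIGARs shifts coordinates as expected", {
  # identity alignment maps every interval to itself
  p <- project_interval(aln_df("1000M"), "chr1", 100, 150)
  expect_equal(p[c("start", "end", "status")],
               list(start = 100L, end = 150L, status = "ok"))
  # an insertion upstream of the interval shifts the query by +10
  p <- project_interval(aln_df("50M10I940M"), "chr1", 100, 150)
  expect_equal(c(p$start, p$end), c(110L, 160L))
  # a deletion upstream shifts the query by -10
  p <- project_interval(aln_df("50M10D940M"), "chr1", 100, 150)
  expect_equal(c(p$start, p$end), c(90L, 140L))
})

test_that("endpoints inside deletions snap inward and full deletions project empty", {
  # deletion spans ref [50, 80); interval [60, 70) is entirely inside it
  a <- aln_df("50M30D920M")
  p <- project_interval(a, "chr1", 60, 70)
  expect_equal(p$status, "ok")
  expect_equal(p$start, p$end)
  expect_equal(p$start, 50L)
  # start inside the deletion snaps right to the first aligned base
  p <- project_interval(a, "chr1", 60, 100)
  expect_equal(c(p$start, p$end), c(50L, 70L))
  # end inside the deletion snaps left to the last aligned base
  p <- project_interval(a, "chr1", 30, 70)
  expect_equal(c(p$start, p$end), c(30L, 50L))
})

test_that("coverage failures are reported by status", {
  a2 <- rbind(aln_df("200M"), aln_df("200M", contig = "c2"))
  expect_equal(project_interval(a2, "chr1", 10, 50)$status, "multi_contig")
  # two records of the same contig covering the locus are also ambiguous
  a3 <- rbind(aln_df("200M"), aln_df("200M", ref_start = 0L))
  expect_equal(project_interval(a3, "chr1", 10, 50)$status, "multi_contig")
  expect_equal(project_interval(aln_df("200M"), "chr2", 10, 50)$status,
               "unaligned")
  expect_equal(project_interval(aln_df("200M"), "chr1", 500, 600)$status,
               "unaligned")
  # locus poking past the aligned span
  expect_equal(project_interval(aln_df("200M"), "chr1", 150, 260)$status,
               "spans_clip")
  # clipped contig edge: alignment covers ref [100, 300)
  a <- aln_df("20S200M", ref_start = 100L)
  expect_equal(project_interval(a, "chr1", 90, 120)$status, "spans_clip")
  expect_equal(project_interval(a, "chr1", 150, 170)$start, 70L)
})

test_that("malformed or inconsistent CIGARs raise errors", {
  expect_error(trbench:::parse_cigar("10M5"), "malformed")
  bad <- data.frame(contig = "c1", contig_length = 50L, ref_chrom = "chr1",
                    ref_start = 0L, strand = "+", cigar = "100M",
                    stringsAsFactors = FALSE)
  expect_error(index_alignments(bad), "inconsistent CIGAR")
})

test_that("projection is monotone and identity on nested intervals", {
  w <- tw_small
  s <- tw_small_sample
  idx <- index_alignments(s$haplotypes[[1]]$alignments)
  set.seed(5)
  chr_len <- nchar(w$reference[["chr1"]])
  for (k in 1:50) {
    b_start <- sample(0:(chr_len - 60), 1)
    b_end <- b_start + sample(20:60, 1)
    a_start <- b_start + sample(0:5, 1)
    a_end <- max(a_start + 1, b_end - sample(0:5, 1))
    pa <- project_interval(idx, "chr1", a_start, a_end)
    pb <- project_interval(idx, "chr1", b_start, b_end)
    if (pa$status == "ok" && pb$status == "ok") {
      expect_gte(pa$start, pb$start)
      expect_lte(pa$end, pb$end)
    }
  }
})

test_that("strand-aware extraction returns alleles in reference orientation", {
  w <- build_world(sim_config(seed = 13, loci_per_motif = 6,
                              p_variant = 0.4, minus_strand_frac = 1))
  s <- sim_sample(w, "s1", seed = 14)
  tc <- assembly_truth_calls(w$catalog, s$haplotypes[[1]],
                             s$haplotypes[[2]], w$reference, "s1")
  expect_true(all(attr(tc, "statuses") == "ok"))
  expect_identical(tc$a1_seq, s$truth$a1_seq)
  expect_identical(tc$a2_seq, s$truth$a2_seq)
})

test_that("SAM records round-trip through Rsamtools into the alignment table", {
  s <- tw_small_sample
  w <- tw_small
  aln <- s$haplotypes[[1]]$alignments
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(w$reference),
                   nchar(w$reference)))
  seqs <- vapply(aln$contig,
                 function(cn) s$haplotypes[[1]]$sequences[[cn]], "")
  recs <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*", aln$contig,
                  ifelse(aln$strand == "-", 16L, 0L), aln$ref_chrom,
                  aln$ref_start + 1L, aln$cigar, seqs)
  writeLines(c(hdr, recs), sam)
  back <- read_alignments(sam)
  back <- back[match(aln$contig, back$contig), ]
  expect_equal(back$cigar, aln$cigar, ignore_attr = TRUE)
  expect_equal(back$ref_start, aln$ref_start, ignore_attr = TRUE)
  expect_equal(back$strand, aln$strand, ignore_attr = TRUE)
  expect_equal(back$contig_length, aln$contig_length, ignore_attr = TRUE)
})
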