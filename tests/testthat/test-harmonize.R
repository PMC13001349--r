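mini_vcf <- function(lines, samples = "S1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
               "##INFO=<ID=RUL_REF,Number=1,Type=Integer,Description=\"x\">",
               "##INFO=<ID=RB,Number=A,Type=Integer,Description=\"x\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "##FORMAT=<ID=CONS,Number=1,Type=String,Description=\"x\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), path)
  path
}

test_that("GT indices map onto REF/ALT sequences with correct genotype classes", {
  cat0 <- tr_catalog("chr1", 100, 106, "CAG")
  v <- mini_vcf(c(
    "chr1\t101\t.\tCAGCAG\tCAGCAGCAG\t.\t.\tEND=106\tGT\t0/1",
    "chr1\t101\t.\tCAGCAG\tCAG,CAGCAGCAG\t.\t.\tEND=106\tGT\t1/2",
    "chr1\t101\t.\tCAGCAG\t.\t.\t.\tEND=106\tGT\t./."))
  # three records at one locus is artificial but exercises each GT shape
  calls <- extract_calls(v, "sequence_refalt", cat0)
  expect_equal(calls$gclass, c("het_ref", "het_alt", "missing"))
  expect_equal(calls$a1_seq[1], "CAGCAG")
  expect_equal(calls$a2_seq[1], "CAGCAGCAG")
  expect_equal(calls$a1_len[2], 3L)
  expect_true(is.na(calls$a1_len[3]))
  # allele order follows GT order: 1/0 keeps the alternate first
  v2 <- mini_vcf("chr1\t101\t.\tCAGCAG\tCAGCAGCAG\t.\t.\tEND=106\tGT\t1/0")
  c2 <- extract_calls(v2, "sequence_refalt", cat0)
  expect_equal(c2$a1_seq, "CAGCAGCAG")
  expect_equal(c2$gclass, "het_ref")
})

test_that("out-of-range GT indices skip the record and are counted", {
  cat0 <- tr_catalog("chr1", 100, 106, "CAG")
  v <- mini_vcf(c(
    "chr1\t101\t.\tCAGCAG\tCAGCAGCAG\t.\t.\tEND=106\tGT\t0/2",
    "chr1\t101\t.\tCAGCAG\tCAGCAGCAG\t.\t.\tEND=106\tGT\t0/1"))
  calls <- extract_calls(v, "sequence_refalt", cat0)
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_skipped"), 1L)
})

test_that("records without catalog overlap are kept as orphans", {
  cat0 <- tr_catalog("chr1", 5000, 5012, "CAG")
  v <- mini_vcf("chr1\t101\t.\tCAGCAG\tCAGCAGCAG\t.\t.\tEND=106\tGT\t0/1")
  calls <- extract_calls(v, "sequence_refalt", cat0)
  expect_match(calls$locus_id, "^orphan:")
})

test_that("symbolic records resolve lengths from RUL_REF with END fallback", {
  expect_equal(extract_lengths_symbolic("RUL_REF=30;END=1100", 1071)$ref_length,
               30L)
  expect_equal(extract_lengths_symbolic("END=1100", 1071)$ref_length, 30L)
  expect_true(is.na(extract_lengths_symbolic("FOO=1", 1071)$ref_length))
  expect_equal(extract_lengths_symbolic("RB=45,60;END=1100", 1071)$alt_lengths,
               c(45L, 60L))

  cat0 <- tr_catalog("chr1", 1070, 1100, "CAG")
  v <- mini_vcf(c(
    "chr1\t1071\t.\tN\t<TR1>,<TR2>\t.\t.\tEND=1100;RB=45,60\tGT\t1/2",
    "chr1\t1071\t.\tN\t<TR1>\t.\t.\tRUL_REF=30;END=1100;RB=45\tGT\t0/1",
    "chr1\t1071\t.\tN\t.\t.\t.\t.\tGT\t0/0"))
  calls <- extract_calls(v, "symbolic_length", cat0)
  # third record has neither RUL_REF nor END: unresolvable, skipped
  expect_equal(nrow(calls), 2L)
  expect_equal(attr(calls, "n_skipped"), 1L)
  expect_equal(calls$a1_len, c(45L, 30L))
  expect_equal(calls$a2_len, c(60L, 45L))
  expect_equal(calls$gclass, c("het_alt", "het_ref"))
  expect_true(all(is.na(calls$a1_seq)))
})

test_that("consensus-appended records are rebuilt against the reference", {
  ref <- c(chr1 = paste0(strrep("T", 100), strrep("CAG", 4), strrep("A", 50)))
  cat0 <- tr_catalog("chr1", 100, 112, "CAG")
  v <- mini_vcf(c(
    "chr1\t101\t.\tN\t.\t.\t.\tEND=112\tGT:CONS\t1/1:CAGCAGCAGCAG",
    "chr1\t101\t.\tN\t.\t.\t.\tEND=112\tGT:CONS\t1/2:CAGCAGCAGCAG,CAGCAG",
    "chr1\t101\t.\tN\t.\t.\t.\tEND=112\tGT:CONS\t1/2:CAGCAG,CAGCAGCAG"))
  rec <- reconstruct_consensus_vcf(v, ref)
  expect_equal(rec$fix$ref, rep("CAGCAGCAGCAG", 3))
  expect_equal(unname(rec$gt[, 1]), c("0/0", "0/1", "1/2"))
  calls <- extract_calls(rec, "sequence_refalt", cat0)
  expect_equal(calls$gclass, c("hom_ref", "het_ref", "het_alt"))
  # sample with genotype but no consensus sequence: record unresolvable
  v2 <- mini_vcf("chr1\t101\t.\tN\t.\t.\t.\tEND=112\tGT:CONS\t1/1:.")
  rec2 <- reconstruct_consensus_vcf(v2, ref)
  expect_equal(nrow(rec2$fix), 0L)
  expect_equal(attr(rec2, "n_unresolvable"), 1L)
})

test_that("every dialect round-trips the simulator truth exactly", {
  w <- tw_small
  s <- tw_small_sample
  tc <- tw_small_truth
  for (d in c("sequence_refalt", "symbolic_length", "consensus_appended")) {
    f <- tempfile(fileext = ".vcf")
    emit_callset(w, s, d, error_profile(), path = f, seed = 3)
    calls <- extract_calls(f, d, w$catalog, reference = w$reference)
    expect_equal(attr(calls, "n_skipped"), 0L)
    m <- match(tc$locus_id, calls$locus_id)
    expect_false(anyNA(m))
    expect_equal(calls$a1_len[m], tc$a1_len, info = d)
    expect_equal(calls$a2_len[m], tc$a2_len, info = d)
    if (d != "symbolic_length") {
      expect_equal(calls$a1_seq[m], tc$a1_seq, info = d)
      expect_equal(calls$a2_seq[m], tc$a2_seq, info = d)
      expect_equal(calls$gclass[m], tc$gclass, info = d)
    }
  }
})
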