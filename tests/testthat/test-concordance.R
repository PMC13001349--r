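test_that("edit distance matches a DP oracle and its metric identities", {
  expect_equal(tr_levenshtein("CAGCAG", "CAGCAG"), 0L)
  expect_equal(tr_levenshtein("CAG", ""), 3L)
  expect_equal(tr_levenshtein("GCTA", "ACTG"), 2L)
  set.seed(31)
  n <- 300
  a <- vapply(sample(0:60, n, replace = TRUE), random_dna, "")
  b <- vapply(sample(0:60, n, replace = TRUE), random_dna, "")
  want <- mapply(lev_oracle, a, b, USE.NAMES = FALSE)
  expect_equal(tr_levenshtein(a, b), as.integer(want))
  # symmetry and triangle inequality on a subset
  c_ <- vapply(sample(0:60, 50, replace = TRUE), random_dna, "")
  expect_equal(tr_levenshtein(a[1:50], b[1:50]),
               tr_levenshtein(b[1:50], a[1:50]))
  expect_true(all(tr_levenshtein(a[1:50], b[1:50]) <=
                    tr_levenshtein(a[1:50], c_) +
                    tr_levenshtein(c_, b[1:50])))
  expect_equal(tr_levenshtein(a, a), rep(0L, n))
  expect_equal(tr_levenshtein(a, ""), nchar(a))
})

test_that("allele pairing minimizes total deviation with direct-order ties", {
  pr <- pair_alleles(c(10, 20), c(20, 10), metric = "length")
  expect_true(pr$crossed)
  expect_equal(pr$total, 0)
  pr <- pair_alleles(c("CAG", "CAGCAG"), c("CAGCAG", "CAG"), metric = "edit")
  expect_true(pr$crossed)
  expect_equal(pr$total, 0L)
  # equal totals under both orderings: direct chosen
  pr <- pair_alleles(c(12, 12), c(10, 15), metric = "length")
  expect_false(pr$crossed)
  expect_equal(pr$total, 5)
  expect_equal(pr$pairing, c(1L, 2L))
  # haploid call against diploid truth: min-deviation partner, other flagged
  pr <- pair_alleles(11, c(20, 10), metric = "length")
  expect_equal(pr$pairing, 2L)
  expect_equal(pr$unpaired_truth, 1L)
  expect_error(pair_alleles(numeric(0), c(1, 2)), "empty")
})

test_that("pairing equals exhaustive enumeration on random allele sets", {
  set.seed(17)
  for (k in 1:2000) {
    nt <- sample(1:2, 1); nr <- sample(1:2, 1)
    tool <- sample(0:40, nt, replace = TRUE)
    truth <- sample(0:40, nr, replace = TRUE)
    expect_equal(pair_alleles(tool, truth, "length")$total,
                 pair_oracle(tool, truth, len_dist))
    tool_s <- vapply(sample(0:15, nt, replace = TRUE), random_dna, "")
    truth_s <- vapply(sample(0:15, nr, replace = TRUE), random_dna, "")
    expect_equal(pair_alleles(tool_s, truth_s, "edit")$total,
                 pair_oracle(tool_s, truth_s, lev_oracle))
  }
})

test_that("deviation classes follow the ordered Match / Off-by-1 / Off-by-motif / Mismatch rules", {
  expect_equal(classify_deviation(0, 3), "MATCH")
  expect_equal(classify_deviation(1, 1), "OFF_BY_1")  # homopolymer: rule order
  expect_equal(classify_deviation(3, 3), "OFF_BY_MOTIF")
  expect_equal(classify_deviation(4, 3), "MISMATCH")
  expect_equal(classify_deviation(c(0, 1, 2, 7), 6),
               c("MATCH", "OFF_BY_1", "OFF_BY_MOTIF", "MISMATCH"))
})

test_that("accuracy counts accepted classes over called loci and is monotone in the accepted set", {
  rec <- data.frame(
    called = rep(TRUE, 1000),
    locus_class = rep(c("MATCH", "OFF_BY_1", "OFF_BY_MOTIF", "MISMATCH"),
                      c(900, 50, 30, 20)))
  expect_equal(accuracy(rec), 0.95)
  expect_equal(accuracy(rec, c("MATCH", "OFF_BY_1", "OFF_BY_MOTIF")), 0.98)
  expect_equal(accuracy(rec, "MATCH"), 0.90)
  a1 <- accuracy(rec, "MATCH")
  a2 <- accuracy(rec)
  a3 <- accuracy(rec, c("MATCH", "OFF_BY_1", "OFF_BY_MOTIF"))
  expect_true(a1 <= a2 && a2 <= a3)
  expect_error(accuracy(rec[0, ]), "no called loci")
})

test_that("injected errors are recovered class-for-class from a simulated callset", {
  w <- tw_small
  s <- tw_small_sample
  tc <- tw_small_truth
  n <- nrow(w$catalog)
  prof <- error_profile(n_missing = 3, n_off_by_1 = 5, n_off_by_motif = 4,
                        n_mismatch = 2, n_seq_sub = 6)
  ec <- emit_callset(w, s, "sequence_refalt", prof, seed = 8)
  expect_equal(unname(table(ec$ledger$class)[c("missing", "off_by_1",
                                               "off_by_motif", "mismatch",
                                               "seq_sub")]),
               c(3L, 5L, 4L, 2L, 6L), ignore_attr = TRUE)
  rec <- concordance_records(ec$calls, tc, w$catalog, metric = "edit")
  expect_equal(sum(!rec$called), 3L)
  tab <- table(rec$locus_class)
  expect_equal(unname(tab["OFF_BY_1"]), 5L, ignore_attr = TRUE)
  expect_equal(unname(tab["OFF_BY_MOTIF"]), 4L, ignore_attr = TRUE)
  expect_equal(unname(tab["MISMATCH"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(tab["MATCH"]), n - 3L - 5L - 4L - 2L, ignore_attr = TRUE)

  # sequence substitutions leave lengths intact but show up as edits
  sa <- sequence_accuracy(rec)
  expect_equal(sa$n, n - 3L - 5L - 4L - 2L)
  expect_equal(sa$fraction, 1 - 6 / sa$n)
  expect_equal(unname(sa$distribution["1"]), 6L, ignore_attr = TRUE)
})

test_that("stratification uses lower-inclusive bins and reports per-bin counts", {
  rec <- data.frame(
    called = TRUE, locus_class = "MATCH",
    truth_gclass = c("hom_ref", "het_ref", "het_ref"),
    allele_length_bin = trbench:::bin_values(c(100, 49, 1500),
                                             trbench:::bins_allele_length()),
    motif_length_bin = trbench:::motif_bin(c(3, 11, 10)),
    expansion_bin = trbench:::bin_values(c(30, 70, 600),
                                         trbench:::bins_expansion()))
  expect_equal(rec$allele_length_bin, c("100-200", "<50", ">1000"))
  expect_equal(rec$motif_length_bin, c("3", ">10", "10"))
  expect_equal(rec$expansion_bin, c("<50", "50-100", ">500"))
  tab <- stratify_records(rec, "gclass")
  expect_equal(tab$n_called[tab$bin == "het_ref"], 2L)
  expect_equal(tab$accuracy, c(1, 1))
})

test_that("genotype distribution covers the four diploid classes and sums to one", {
  calls <- tr_calls(paste0("L", 1:6), "s",
                    a1_len = c(10, 10, 12, 12, 11, NA),
                    a2_len = c(10, 12, 12, 13, NA, NA),
                    gclass = c("hom_ref", "het_ref", "hom_alt", "het_alt",
                               "haploid", "missing"))
  gd <- genotype_distribution(calls)
  expect_equal(sum(gd$proportions), 1)
  expect_equal(unname(gd$proportions), rep(0.25, 4))
  expect_equal(gd$n_missing, 1L)
  expect_equal(gd$n_haploid, 1L)
  all_ref <- tr_calls("L1", "s", a1_len = 10, a2_len = 10,
                      gclass = "hom_ref")
  expect_equal(unname(genotype_distribution(all_ref)$proportions),
               c(1, 0, 0, 0))
})
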