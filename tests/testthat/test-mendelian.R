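test_that("transmission search finds the minimum-distance pairing", {
  # exact transmission: father 10, mother 12
  r <- inheritance_distance(c(10, 12), c(10, 11), c(12, 14), lref = 10)
  expect_equal(r$distance, 0)
  expect_equal(unname(r$pairing), c(1L, 1L, 1L))
  # child allele 13 is 1 bp from the closest transmittable combination
  r <- inheritance_distance(c(10, 13), c(10, 11), c(12, 14), lref = 10)
  expect_equal(r$distance, 2)
  expect_equal(r$half_distance, 1)
  # both child alleles 20 and 18 bp away from the only combination (10, 12)
  r <- inheritance_distance(c(30, 30), c(10, 10), c(12, 12), lref = 10)
  expect_equal(r$distance, 2 * (20 + 18))
})

test_that("transmission search equals the 8-candidate brute force on random trios", {
  set.seed(23)
  for (k in 1:3000) {
    lref <- sample(5:40, 1)
    child <- sample(0:60, 2, replace = TRUE)
    father <- sample(0:60, 2, replace = TRUE)
    mother <- sample(0:60, 2, replace = TRUE)
    r <- inheritance_distance(child, father, mother, lref)
    expect_equal(r$distance, trio_oracle(child, father, mother, lref))
    # shared Lref makes the distance structurally even
    expect_equal(r$distance %% 2, 0)
  }
})

test_that("Mendelian classes follow the half-distance thresholds", {
  expect_equal(classify_mendelian(0, 6), "MATCH")
  expect_equal(classify_mendelian(2, 6), "ONE_OFF")
  expect_equal(classify_mendelian(10, 6), "MLEN_OFF")   # h = 5 <= motif 6
  expect_equal(classify_mendelian(14, 6), "MISMATCH")   # h = 7 > motif 6
  # the one-off band is configurable
  expect_equal(classify_mendelian(4, 6, one_off_max = 2), "ONE_OFF")
})

test_that("perfect transmission scores good rate 1 and violations are recovered exactly", {
  w <- build_world(sim_config(seed = 19, loci_per_motif = 30,
                              motif_lengths = 1:6, p_variant = 0.15))
  trio0 <- make_trio(w, seed = 4)
  rep0 <- trio_report(trio0$child, trio0$father, trio0$mother, w$catalog)
  expect_equal(rep0$good_rate, 1)
  expect_true(all(rep0$loci$mclass == "MATCH"))

  trio <- make_trio(w, n_one_off = 8, n_mlen_off = 5, n_mismatch = 12,
                    seed = 6)
  rep1 <- trio_report(trio$child, trio$father, trio$mother, w$catalog)
  tab <- table(rep1$loci$mclass)
  expect_equal(unname(tab["ONE_OFF"]), 8L, ignore_attr = TRUE)
  expect_equal(unname(tab["MLEN_OFF"]), 5L, ignore_attr = TRUE)
  expect_equal(unname(tab["MISMATCH"]), 12L, ignore_attr = TRUE)
  expect_equal(rep1$good_rate, 1 - 12 / nrow(rep1$loci))
  # the ledger names exactly the forced loci
  got <- rep1$loci[rep1$loci$mclass != "MATCH", c("locus_id", "mclass")]
  want <- trio$ledger[order(trio$ledger$locus_id), ]
  got <- got[order(got$locus_id), ]
  expect_equal(got$locus_id, want$locus_id)
  expect_equal(got$mclass, want$forced_class)
})

test_that("good rate degrades as the injected perturbation magnitude grows", {
  w <- build_world(sim_config(seed = 29, loci_per_motif = 20,
                              motif_lengths = 3:6, p_variant = 0.1))
  g <- vapply(list(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)), function(v) {
    trio <- make_trio(w, v[1], v[2], v[3], seed = 11)
    trio_report(trio$child, trio$father, trio$mother, w$catalog)$good_rate
  }, numeric(1))
  # one-off and within-motif violations stay "good"; over-motif ones do not
  expect_equal(g[1], 1)
  expect_equal(g[2], 1)
  expect_lt(g[3], 1)
})

test_that("sex chromosomes are excluded from trio evaluation", {
  w <- build_world(sim_config(seed = 31, loci_per_motif = 10,
                              chrom_names = c("chr1", "chrX")))
  trio <- make_trio(w, seed = 3)
  rep <- trio_report(trio$child, trio$father, trio$mother, w$catalog)
  in_x <- w$catalog$locus_id[w$catalog$chrom == "chrX"]
  expect_gt(length(in_x), 0)
  expect_false(any(rep$loci$locus_id %in% in_x))
})

test_that("a reference-only caller attains perfect Mendelian consistency (documented blindness)", {
  w <- build_world(sim_config(seed = 37, loci_per_motif = 10,
                              p_variant = 0.5))
  ref_calls <- function(sample_id) {
    cat_df <- w$catalog
    ref_seq <- vapply(seq_len(nrow(cat_df)), function(i) {
      substr(w$reference[[cat_df$chrom[i]]], cat_df$start[i] + 1L,
             cat_df$end[i])
    }, "")
    tr_calls(cat_df$locus_id, sample_id, cat_df$chrom, cat_df$start,
             cat_df$end, cat_df$end - cat_df$start, ref_seq, ref_seq,
             nchar(ref_seq), nchar(ref_seq), "hom_ref")
  }
  rep <- trio_report(ref_calls("c"), ref_calls("f"), ref_calls("m"),
                     w$catalog)
  expect_equal(rep$good_rate, 1)
})

test_that("expected de novo burden scales with catalog size and rate", {
  expect_equal(expected_de_novo(43009, 1e-5), 0.43009)
  expect_lt(expected_de_novo(43009, 1e-5), 1)
  expect_equal(expected_de_novo(0), 0)
})
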