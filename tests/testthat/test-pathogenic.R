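disease_row <- function(inheritance = "dominant", pathogenic = 120,
                        intermediate = 90, gene = "G1") {
  data.frame(chrom = "chr1", start = 1000L, end = 1060L, gene = gene,
             motif = "CAG", pathogenic_min = pathogenic,
             intermediate_min = intermediate, inheritance = inheritance,
             stringsAsFactors = FALSE)
}

test_that("disease tables load with bp or motif-count thresholds", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1060\tG1\tCAG\t120\t90\tdominant",
               "chr2\t5000\t5030\tG2\tGGC\t60\t.\trecessive"), f)
  d <- read_disease_table(f)
  expect_equal(d$pathogenic_min, c(120, 60))
  expect_true(is.na(d$intermediate_min[2]))
  d2 <- read_disease_table(f, unit = "motifs")
  expect_equal(d2$pathogenic_min, c(360, 180))
  writeLines("chr1\t1000\t1060\tG1\tCAG\t80\t90\tdominant", f)
  expect_error(read_disease_table(f), "exceeds")
  writeLines("chr1\t1000\t1060\tG1\tCAG\t120\t90\tsomatic", f)
  expect_error(read_disease_table(f))
})

test_that("records match disease loci within the positional tolerance, nearest first", {
  d <- rbind(disease_row(gene = "G1"),
             within(disease_row(gene = "G2"), start <- 1030L))
  expect_equal(match_disease_locus("chr1", 1030, d, 50), 2L)  # exact hit
  expect_equal(match_disease_locus("chr1", 1010, d, 50), 1L)  # nearest
  expect_equal(match_disease_locus("chr1", 1051, disease_row(), 50),
               NA_integer_)
  expect_equal(match_disease_locus("chr1", 1050, disease_row(), 50), 1L)
  expect_equal(match_disease_locus("chr2", 1000, d, 50), NA_integer_)
})

test_that("inheritance modes set the number of expanded alleles required", {
  expect_true(detect_expansion(c(57, 126), disease_row("dominant")))
  expect_false(detect_expansion(c(57, 119), disease_row("dominant")))
  expect_false(detect_expansion(c(1250, 33),
                                disease_row("recessive", pathogenic = 1200)))
  expect_true(detect_expansion(c(1250, 1300),
                               disease_row("recessive", pathogenic = 1200)))
  # hemizygous male at an X-linked locus: one allele suffices even when two
  # are reported
  expect_true(detect_expansion(c(600, 15), disease_row("x_linked",
                                                       pathogenic = 600),
                               sex = "male"))
  # carrier rule relaxes recessive to one allele
  expect_true(detect_expansion(c(1250, 33),
                               disease_row("recessive", pathogenic = 1200),
                               carrier = TRUE))
  # premutation threshold path
  expect_true(detect_expansion(c(100, 10), disease_row(), "intermediate"))
  d_noint <- disease_row()
  d_noint$intermediate_min <- NA
  expect_error(detect_expansion(c(100, 10), d_noint, "intermediate"),
               "intermediate")
  # dominant rule is never stricter than the recessive rule
  set.seed(3)
  for (k in 1:50) {
    lens <- sample(10:300, 2)
    dom <- detect_expansion(lens, disease_row("dominant"))
    rec <- detect_expansion(lens, disease_row("recessive"))
    expect_true(dom >= rec)
  }
})

test_that("threshold adjustment by motif units is exact and guarded", {
  expect_equal(adjust_threshold(24, 4, 3), 36)
  expect_equal(adjust_threshold(36, 0, 3), 36)
  expect_equal(adjust_threshold(36, -2, 3), 30)
  expect_error(adjust_threshold(5, -2, 3), "below zero")
})

test_that("sensitivity equals the planted detectable fraction on fixtures", {
  plan <- data.frame(
    sample_id = paste0("p", 1:9),
    gene = c("G1", "G1", "G2", "G2", "G3", "G3", "G2", "G1", "G3"),
    status = c("pathogenic", "pathogenic", "pathogenic", "carrier",
               "pathogenic", "premutation", "pathogenic", "unaffected",
               "pathogenic"),
    inheritance = c("dominant", "dominant", "recessive", "recessive",
                    "x_linked", "x_linked", "recessive", "dominant",
                    "x_linked"),
    detectable = c(TRUE, FALSE, TRUE, NA, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  fx <- make_disease_fixture(plan, seed = 5)
  sens <- sensitivity(fx$calls, fx$truths, fx$diseases)
  # unaffected excluded; carrier detected under the one-allele rule
  expect_equal(sens$n_expected, 8L)
  expect_equal(sens$n_detected, 6L)
  expect_equal(sens$sensitivity, 6 / 8)
  expect_equal(nrow(sens$detections), 8L)
  # under the strict two-allele rule the carrier is missed
  sens2 <- sensitivity(fx$calls, fx$truths, fx$diseases,
                       carrier_rule = "two_allele")
  expect_equal(sens2$n_detected, 5L)
  # raising thresholds never gains detections
  harder <- fx$diseases
  harder$pathogenic_min <- harder$pathogenic_min + 1000L
  harder$intermediate_min <- harder$intermediate_min + 1000L
  sens3 <- sensitivity(fx$calls, fx$truths, harder)
  expect_lte(sens3$n_detected, sens$n_detected)
  # an uncalled disease locus counts as a miss
  sens4 <- sensitivity(fx$calls[-1, ], fx$truths, fx$diseases)
  expect_equal(sens4$n_detected, sens$n_detected -
                 as.integer(sens$detections$detected[1]))
  expect_error(sensitivity(fx$calls,
                           fx$truths[fx$truths$status == "unaffected", ],
                           fx$diseases),
               "empty")
})
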