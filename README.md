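# trbench

Multi-metric evaluation of tandem-repeat (TR) genotype callsets.

## The problem

Tandem repeats — loci where a motif of 1 bp (homopolymers, STRs) to tens of
bp (VNTRs) is repeated head-to-tail — are among the most variable and most
error-prone regions of the genome to genotype, and dozens of loci harbour
pathogenic expansions. Long-read TR genotypers all work from a locus
catalog (BED intervals plus motif), but they disagree on almost everything
else: coordinate conventions, VCF encodings (explicit REF/ALT sequences,
symbolic length-only records, per-sample consensus sequences bolted onto
the sample field), and boundary handling. No single accuracy number
captures their behaviour, because the obvious benchmarks have orthogonal
blind spots: most TR loci are invariant, so a caller that always emits the
reference allele scores high against assemblies *and* achieves perfect trio
Mendelian consistency while missing every pathogenic expansion.

`trbench` implements a complementary battery of evaluation metrics for R:

1. **Assembly concordance** — catalog coordinates are projected onto
   haplotype-resolved assembly contigs by walking alignment CIGARs
   (liftover), truth alleles are extracted per haplotype, called and truth
   alleles are paired to minimize total deviation, and each locus is
   classified as `MATCH` (0 bp deviation), `OFF_BY_1` (exactly 1 bp),
   `OFF_BY_MOTIF` (≤ one motif length) or `MISMATCH` (> motif length), in
   that order. Accuracy is the fraction of called loci in an accepted class
   set (default `{MATCH, OFF_BY_1}`), stratified by genotype class, allele
   length, motif length, and expansion size. At length-concordant loci,
   sequence accuracy is the fraction with Levenshtein distance 0.
2. **Trio Mendelian consistency** — each diploid genotype becomes a feature
   vector `[L1, L2, ΔL1, ΔL2]` (allele lengths and their deviations from
   `Lref = len(REF)`); all four parental transmissions × both child allele
   orderings give eight candidate pairings, and the minimum Manhattan
   distance is the inheritance distance. Half-distance `h` classifies the
   locus: `h = 0` MATCH, `h = 1` ONE_OFF, `h ≤ motif` MLEN_OFF, else
   MISMATCH; `(MATCH + ONE_OFF + MLEN_OFF) / total` is the "good" rate.
3. **Cross-tool consistency** — callsets synchronized on the catalog;
   per-pair mean absolute length difference and mean Levenshtein distance
   over commonly called loci.
4. **Pathogenic-expansion sensitivity** — calls within ±50 bp of a disease
   locus start are tested against bp thresholds under inheritance-mode
   rules (dominant ≥1 expanded allele, recessive ≥2, X-linked hemizygous
   males ≥1).

Because real benchmark inputs (assemblies, trios, clinical cohorts) are
large, the package ships a synthetic truth-world generator: planted perfect
repeats with isolated flanks, diploid haplotypes under a configurable
mutation model, exact alignment CIGARs derived from the planted edit list,
trio transmissions with forced violation classes, and error-injected
callsets in all three VCF dialects, each with an exact injection ledger.
Every evaluation stage is therefore testable end-to-end with known truth.

## Worked example

Simulate a 300-locus world, emit a callset with known injected errors,
derive truth from the simulated assemblies, and score it:

```r
library(trbench)

cfg    <- sim_config(seed = 1, loci_per_motif = 50, motif_lengths = 1:6)
world  <- build_world(cfg)
sample1 <- sim_sample(world, "HG_sim", seed = 2)

ec <- emit_callset(world, sample1, "sequence_refalt",
                   error_profile(n_off_by_1 = 12, n_off_by_motif = 6,
                                 n_mismatch = 4, n_missing = 3),
                   seed = 3)

truth <- assembly_truth_calls(world$catalog, sample1$haplotypes[[1]],
                              sample1$haplotypes[[2]], world$reference,
                              "HG_sim")
calls <- extract_calls(ec$path, "sequence_refalt", world$catalog)
rec   <- concordance_records(calls, truth, world$catalog, metric = "edit")
table(rec$locus_class, useNA = "ifany")
#>        MATCH     MISMATCH     OFF_BY_1 OFF_BY_MOTIF         <NA>
#>          275            4           12            6            3
accuracy(rec)                                          # 0.9663
accuracy(rec, c("MATCH", "OFF_BY_1", "OFF_BY_MOTIF"))  # 0.9865
```

The injected 12/6/4/3 errors come back class-for-class; the three `NA`
rows are the dropped (missing) calls, excluded from the accuracy
denominator. Sequence accuracy at the 275 length-matched loci is 100%
(no substitutions were injected). A trio with five forced over-motif
violations scores accordingly:

```r
trio <- make_trio(world, n_mismatch = 5, seed = 4)
rep  <- trio_report(trio$child, trio$father, trio$mother, world$catalog)
rep$good_rate        # 0.9833 over 300 loci: 295 MATCH, 5 MISMATCH
```

A thin command-line front end wraps the same functions
(`exec/trbench`): `trbench simulate`, `harmonize`, `concordance`,
`mendelian`, `crosstool`, `pathogenic`, `catalog-sample`.

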