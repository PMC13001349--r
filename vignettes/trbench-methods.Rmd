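---
title: "Evaluating tandem-repeat genotype callsets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating tandem-repeat genotype callsets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbench)
```

# Scope and model

`trbench` scores tandem-repeat (TR) genotype callsets against four
complementary references: haplotype-resolved assemblies, trio inheritance,
other callsets, and clinical expansion thresholds. All four share one data
model. A *catalog* anchors every comparison: TR loci as 0-based half-open
intervals plus the repeat motif. A *harmonized call* is, per locus and
sample, an ordered pair of alleles given as sequences and/or lengths with a
genotype class (0/0, 0/1, 1/1, 1/2, haploid, missing). Harmonization is
what makes the rest possible, because TR genotypers emit three materially
different VCF dialects: explicit REF/ALT sequences; symbolic ALT records
with lengths in INFO fields (`RUL_REF` for the reference allele length,
falling back to `END − POS + 1`, and `RB` per ALT allele); and per-sample
consensus sequences with `REF = "N"` and all genotypes 1/1 or 1/2, which
must be rebuilt against the reference genome (consensus alleles equal to
the reference substring are re-labelled allele 0, the rest become ALT
entries) before they can be compared to anything.

Internally every coordinate is 0-based half-open; conversion happens only
at I/O boundaries (`read_catalog(convention =)`), because some genotypers
use 1-based catalog starts and mixing conventions mid-pipeline is the
classic source of off-by-one drift. Allele order is preserved exactly as
the genotype (GT) field lists it — nothing is sorted silently.

# Assembly concordance

Truth alleles come from projecting catalog intervals onto assembly contigs
through alignment CIGARs. The projection rules are:

* A locus is projected only when exactly one primary alignment record of
  one contig fully covers it. Two covering records — even of the same
  contig — are ambiguous (`multi_contig`); partial coverage is
  `spans_clip`; no overlap is `unaligned`. Only `ok` loci yield truth
  alleles; a locus can be `ok` on one haplotype only, giving a haploid
  truth genotype.
* Insertions in the contig shift subsequent positions; endpoints that land
  inside deletions snap *inward* (start right, end left), so the projected
  interval never includes contig sequence that is not aligned within the
  locus. A locus wholly deleted in the haplotype projects to an empty
  interval and an empty (0 bp) truth allele.
* Minus-strand alignments are walked in reference order (the SAM
  convention: the CIGAR applies to the reverse-complemented query) and the
  result is flipped back to contig storage coordinates; extracted alleles
  are reverse-complemented so they are always reported in reference
  orientation.

Called and truth alleles are then paired to minimize total pairwise
deviation — Levenshtein distance when sequences are available, absolute
length difference otherwise. For diploid-vs-diploid the direct and crossed
orderings are compared and ties go to the direct ordering; this tie-break
is load-bearing: when one allele is perturbed by `m` bp, the crossed total
can equal but never beat the direct total (triangle inequality), so the
per-allele deviations are attributed to the perturbed allele and class
counts recover injected errors exactly. One-vs-two pairings keep the
minimum-deviation partner and flag the locus `allele_count_mismatch`.

Deviations are classified in order: `MATCH` (0), `OFF_BY_1` (exactly 1),
`OFF_BY_MOTIF` (≤ motif length), `MISMATCH` (> motif length); the ordering
means a 1 bp error at a homopolymer is `OFF_BY_1`, not `OFF_BY_MOTIF`. The
locus-level class is the *worst* allele class. The two-allele aggregation
is not dictated by the metric definitions; worst-case is the conservative
choice and makes reported accuracy a lower bound. Accuracy is computed
over *called* loci; loci with no call are reported as a separate missing
rate rather than silently deflating (or inflating) accuracy. Sequence
accuracy is evaluated only where both allele lengths match, as the
fraction of loci with edit distance 0, alongside the distribution of edit
distances.

Stratification bins are lower-inclusive, upper-exclusive with an open top
bin (allele length: <50, 50–100, 100–200, 200–500, 500–1000, >1000 bp;
motif length: 1–10 individually and >10; expansion: <50, 50–100, 100–200,
200–500, >500 bp, with an extended variant adding a 500–1000/>1000 split
via `concordance_records(extended_expansion_bins = TRUE)` since both
binnings appear in practice).

# Trio Mendelian consistency

Each diploid genotype becomes the feature vector `[L1, L2, ΔL1, ΔL2]` with
`ΔLi = Li − Lref` and `Lref` the reference allele length. Enumerating one
allele from each parent and both child orderings gives eight candidates;
the minimum Manhattan distance between candidate and child vectors is the
inheritance distance. When all members share `Lref` the Δ terms duplicate
the L terms, so the distance is structurally even and the half-distance
`h = distance/2` equals the total per-allele discrepancy in bp. Classes:
`h = 0` MATCH, `h = 1` ONE_OFF, `1 < h ≤ motif` MLEN_OFF, else MISMATCH.

Two ambiguities required decisions. First, whether ONE_OFF should admit
both alleles off by 1 bp each (`h = 2`): the implementation defaults to
`h = 1` exactly — one allele off by one base, the other exact — and
exposes the cutoff (`one_off_max`) rather than hard-coding the stricter
reading. Second, `Lref` is taken from the child callset's reference allele
length; when trio members disagree on it (a caller widened coordinates for
one member), the catalog reference length is substituted and the
substitution counted, keeping the evenness invariant intact.

Only autosomal loci with diploid calls in all three members are evaluated;
sex chromosomes are excluded because hemizygous X/Y inheritance needs
different logic. Merging is by catalog locus id after overlap assignment,
which absorbs caller-specific coordinate drift into one mechanism instead
of special-casing tools that must be merged by variant ID.

The metric has a documented blindness, asserted as a test rather than
hidden: a degenerate caller that reports the reference genotype everywhere
achieves a perfect good rate. It is also why the package carries the
analytic helper `expected_de_novo()`: at a ~1e-5 per-locus per-generation
de novo rate, a 43k-locus catalog expects ~0.43 true de novo mutations per
generation, so at that scale essentially every observed inconsistency is a
genotyping error.

# Cross-tool consistency and pathogenic sensitivity

Cross-tool comparison synchronizes callsets on the catalog (recording
whether each caller widened, narrowed or kept the boundaries), pairs
alleles per locus with the same minimum-deviation machinery, and averages
per-locus distances over loci and samples. The default locus set is
`all_common` (loci called by every callset); `pairwise_common` (each
pair's own intersection) is offered because both conventions are used in
practice and they differ whenever callsets drop different loci. The
per-locus value defaults to the *sum* of the two paired allele distances,
with the per-allele mean available — the choice is surfaced, not resolved,
since reported means differ by a factor of two between the conventions.
Length-only callsets simply have no Levenshtein column rather than a zero.

Pathogenic evaluation matches calls to disease loci by start position
within a ±50 bp window (nearest start wins), compares allele lengths to bp
thresholds (motif-count tables are converted at load time, since public
threshold tables mix conventions), and applies inheritance-mode rules:
dominant ≥1 expanded allele, recessive ≥2, X-linked hemizygous males ≥1
regardless of reported allele count. Premutation carriers are tested
against the intermediate threshold, everyone else against the pathogenic
threshold. Carriers of recessive conditions default to the one-allele rule
(a carrier has one expanded allele to find); `carrier_rule =
"two_allele"` holds them to the full recessive rule instead. Threshold
harmonization across locus definitions (e.g. adding four motif units to
sizes quoted under a narrower repeat definition) is a single generic
operation, `adjust_threshold()`.

# The synthetic truth world

The generator builds what the evaluation consumes, with truth known by
construction:

* **Reference and catalog.** Perfect repeats (motif lengths 1–6 bp by
  default, 4–12 units) planted in random flank of 30 bp, honouring the
  ≥25 bp isolation used for benchmark catalogs. Flank boundary bases are
  resampled so they cannot extend the adjacent repeat cyclically, and
  motifs that are themselves repeats of a shorter unit are rejected, so
  the planted locus boundaries are unambiguous.
* **Haplotypes and alignments.** Each haplotype allele differs from
  reference with probability `p_variant` (default 0.085, chosen so that
  ~84% of diploid genotypes are homozygous reference, matching the
  invariant-majority structure of real TR catalogs); changes are whole
  motif units (1–3 by default), optionally with an internal substitution,
  optional 1–3 bp flank indels, and optional full deletions. The CIGAR is
  built alongside the sequence from the planted edit list, with plain `M`
  ops only — downstream code must not assume an `=`/`X` distinction — and
  a configurable fraction of contigs is stored reverse-complemented.
* **Callsets.** Error injection is count-deterministic: exactly
  `floor(p·N)` loci per error class, chosen by a seeded shuffle, so
  recovery assertions are exact rather than statistical. Off-by-motif
  injections are restricted to motif ≥2 loci (at homopolymers a 1 bp
  change is `OFF_BY_1` by rule order, which would blur the ledger).
  Injected length changes extend or truncate along the repeat pattern so
  perturbed sequences stay realistic. Fully deleted alleles are emitted as
  the `*` spanning-deletion symbol, which the extractor maps back to the
  empty allele — representing them with padded REF bases would silently
  add 1 bp to every harmonized allele at such records.
* **Trios.** The child inherits one allele from each parent (random
  haplotype per locus, no recombination model — loci are treated as
  independent). Forced violations perturb a child allele and are verified
  against the transmission search before being ledgered, because a naive
  perturbation can be coincidentally explainable by the other parental
  allele; unplaceable violations are an error, never silently dropped.
* **Disease fixtures.** Thresholds and calls are planted strictly above or
  below thresholds per status, so sensitivity equals the planted
  detectable fraction exactly.

What the generator does *not* emulate, and what green tests therefore do
not show: read-level error processes (homopolymer noise scaling with
length, strand bias, coverage dropout), somatic mosaicism, motif
composition effects, variation clusters of closely spaced polymorphic
loci, and real assembly errors. Exact-recovery results validate the
*metric machinery*; they are not a claim about any real genotyper's
accuracy.

# Numerical and degenerate-input choices

* Overlap assignment ties (equal overlap with two catalog loci) go to the
  smaller start; determinism is required, the choice itself is arbitrary.
* `pair_alleles` ties go to the direct ordering (see above); 1-vs-2 ties
  go to the first allele in given order.
* The transmission search breaks ties to the first candidate in
  enumeration order (father allele, mother allele, child ordering).
* Empty sequences are legal alleles throughout (`tr_levenshtein("CAG", "")
  = 3`); a zero-length projection is a 0 bp allele, not a failure.
* Records with GT indices beyond the ALT list are skipped and counted, not
  guessed at; genotypes of ploidy >2 are treated as missing.
* Records overlapping no catalog locus are retained with an
  `orphan:`-prefixed id and excluded from catalog-anchored analyses.
* Length-only callsets decide reference-ness by length equality; a
  same-length non-reference allele is indistinguishable in that dialect —
  a documented limitation mirrored from the callers themselves.
* Catalog sampling is uniform random within each motif-length class under
  a fixed seed (whether stratification by chromosome is wanted is
  catalog-dependent; uniform is the simplest defensible default), with the
  inter-locus gap measured end-to-start, the most literal reading of a
  minimum separation.

# Problem sizes

The shipped tests and the acceptance script use worlds of 48–5,000 loci:
1,000 random sequence pairs (lengths ≤200 bp) for the edit-distance
oracle, 10,000 random cases each for the pairing and transmission oracles,
a 1,000-locus world with a planted 900/50/30/20 class split for
concordance recovery, a 5,000-locus four-chromosome mixed-strand world
with flank indels and full deletions for liftover, and a 360-locus trio
with 135 forced violations. These sizes were chosen as the smallest that
exercise every code path with comfortable combinatorial diversity;
everything scales linearly in locus count.

# Known limitations

Ploidy is at most 2 everywhere. Phasing is ignored (`/` and `|` genotypes
are treated alike). The liftover consumes primary alignments only and
treats a locus split across two alignment records of one contig as
unprojectable rather than attempting to stitch records. VCF output of the
harmonizer targets the sequence-REF/ALT dialect, not the VCF 4.4 TR
extensions. Runtime-wise the per-locus loops are plain R and comfortable
into the tens of thousands of loci; millions of loci would warrant a
compiled core.
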