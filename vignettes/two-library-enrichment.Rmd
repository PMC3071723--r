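---
title: "Exact two-library enrichment analysis: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact two-library enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twolibde)
```

## The statistical model

`twolibde` addresses the oldest form of RNA expression comparison by
sequencing: two libraries, one per condition, no biological replicates,
expression measured as the number of reads per assembled contig. Write
`x` and `y` for a contig's read counts in libraries A and B, and `N_A`,
`N_B` for the library sizes. Under the null hypothesis that both libraries
sample the same transcript pool, each library's count is Poisson with a
shared per-contig rate scaled by its library size. Conditioning on the
observed total `t = x + y` removes the unknown rate:

$$Y \mid t \;\sim\; \mathrm{Binomial}\!\left(t,\; q\right),
\qquad q = \frac{N_B}{N_A + N_B}.$$

The conditional point mass equals the classic two-library (Audic–Claverie)
statistic,

$$p(y \mid x) \;=\; \left(\frac{N_B}{N_A}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1 + N_B/N_A\right)^{x+y}},$$

and `ac_point_probability()` evaluates exactly this quantity. P-values
(`ac_pvalue()`) are binomial tails: one-sided, the smaller of
`P(Y ≤ y)` and `P(Y ≥ y)`; two-sided (the default), twice the smaller
tail, capped at 1. Because the distribution is discrete, the test is
*conservative*: under the null, `P(p < α) ≤ α` at every `α`. The test
suite and the acceptance script verify this empirically at study scale.

### Assumptions

* Counts per contig arise from independent sampling of a large read pool —
  appropriate for shotgun cDNA reads, questionable if one transcript
  dominates a library.
* Library sizes are fixed and known. Two bases are supported: all
  sequenced reads, or reads assembled into contigs
  (`library_sizes(..., basis =)`). The default is `reads_in_contigs`,
  since the per-contig counts being tested are themselves reads in
  contigs; the choice moves `q` by well under 1% at realistic assembly
  rates and does not change calls materially.
* No replicate-to-replicate dispersion. With biological replicates this
  test is anti-conservative and a dispersion-aware model (edgeR, DESeq2)
  should be used instead; that is a non-goal here.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.001 | raw p-value cutoff defining "enriched" |
| `sidedness` | two_sided | tail-doubling test; one-sided available |
| `robust_min_fold` | 100 | normalized fold threshold of the robust filter |
| `robust_min_reads` | 100 | read-support threshold (larger count must exceed it) |
| `robust_rule` | either | fold, reads, or the union of both filters |
| `include_exclusive` | FALSE | whether one-library-only contigs get tested |
| `p_adjust` | none | optional Benjamini–Hochberg before the cutoff |

The defaults mirror the thresholds conventional in two-library 454
studies: a raw 0.001 cutoff without multiple-testing correction, and a
"robust" validation set defined by magnitude on top of significance.
Because published descriptions of the robust set vary between a fold
criterion and a read-support criterion, both are implemented and the
default takes their union, with `robust_by` recording which criterion
fired for each contig.

Two deliberate conventions: a contig whose normalized rates tie exactly
(`x/N_A = y/N_B`) has `direction = "none"` and is never called enriched,
whatever its p-value; and fold enrichment is reported as
`max(r_A, r_B) / min(r_A, r_B)` with `Inf` (rendered `inf` in files) when
exactly one count is zero.

### Exclusive contigs

Contigs with reads in only one library are a partition class of their
own (`a_only` / `b_only`), not test results: with `include_exclusive =
FALSE` (default) they carry `p_value = NA`, matching the accounting
convention in which only *mixed* contigs are tested. Setting
`include_exclusive = TRUE` sends them through the same conditional
binomial (their p-value is then `2 · q^t` or `2 · (1-q)^t`-type tail).
The one place the package itself turns this on is `power_curve()`: at
high true fold a genuinely enriched contig frequently lands *all* its
reads in one library, and leaving those untested would make measured
power decrease with effect size — the opposite of what a power curve must
report.

## The synthetic-data generator

`simulation_config()` states the world the package is tested in:

* **Scale.** 45,538 contigs; 742,771 (A) and 721,543 (B) reads — the
  scale of a four-run 454 study of a small fish transcriptome.
* **Abundance.** `flat` (all contigs share one rate) is the idealized
  limit of a DSN-normalized library and the default for calibration runs;
  `lognormal` with `sigma_log10 = 0.5` gives a flattened-but-dispersed
  profile (about one order of magnitude between the 2.5% and 97.5%
  abundance quantiles), a realistic remnant of imperfect normalization.
  Neither models duplex-kinetics of the normalization reaction itself.
* **Effects.** A fraction `frac_enriched` of contigs (default 0 — the
  null world; power runs typically use 0.05–0.1) receive true fold
  effects cycled from `fold_grid` (default 2, 10, 100), implemented by
  multiplying the rate by `sqrt(fold)` in the favoured library and
  dividing in the other, so the rate *ratio* is exactly the stated fold.
  `frac_exclusive` contigs get a structural zero rate in one library.
* **Sampling.** Counts are multinomial per library, so column sums equal
  the configured library sizes exactly — the fixed-yield view of a
  sequencing run. (Independent Poisson sampling agrees with this
  conditionally on the totals.) Contigs drawing zero reads in both
  libraries are dropped, as an assembler would never emit them; their
  number is reported.

What a green test on synthetic data does establish: type-I-error control
and power behaviour of the *test* under its own sampling assumptions.
What it does not: robustness to assembly artefacts (chimeric or
fragmented contigs), mapping ambiguity, or biological dispersion — none
of which the generator emulates.

## qPCR quantification choices

`ddct_rq()` implements the comparative-CT method with amplification
efficiency fixed at 2.0 (one cycle = one doubling); an `efficiency`
argument exists but no efficiency correction is applied by default, as
none is conventional when none was measured. Rows are one biological
replicate × gene; technical replicates are expected to be averaged on the
CT scale upstream (duplicate `(sample, gene)` rows are an error, not
silently averaged). The calibrator may be a sample or a group; with a
group calibrator, ΔΔCT is taken against the group's *mean* ΔCT, making
the calibrator group's geometric mean RQ exactly 1.

`compare_groups()` defaults to a pooled-variance (Student) two-tailed
t-test on the RQ scale, matching the classical reporting convention of
averaging relative quantities across biological replicates; Welch
variance and log2-RQ or ΔCT scales are options (log2-RQ and ΔCT give
identical p-values, since they differ by a per-gene constant and a sign).
Degenerate variance is handled explicitly rather than by letting
`t.test()` fail: if both groups are internally constant and equal, p = 1;
if constant but different (exact separation), the t statistic is infinite,
no finite p exists, and the package reports p = 0 with
`degenerate = TRUE` so the row cannot be mistaken for a regular test.

## CEG coverage

`coverage_from_hits()` counts a core gene as covered iff it has ≥ 1 hit —
multiplicity beyond presence is deliberately ignored, so a gene hit ten
times counts once. The headline percentage is kept at full precision with
a nearest-integer display value (132/248 → 53.2% → "53%"). The default
reference is the CEG-248 split into four conservation categories of 66,
56, 61 and 65 genes; since coverage arithmetic needs only category sizes,
the packaged reference generates synthetic placeholder gene identifiers
(`KOG_category1_001`, …) when real ones are not supplied. Extrapolating
CEG coverage to "fraction of the transcriptome covered" assumes core
genes are sampled like average genes; the report prints that caveat
rather than asserting the extrapolation.

## Keyword mining

Matching is case-insensitive on the annotation description. The default
`word` mode tokenizes at every non-alphanumeric character (so
"testis-specific" matches *testis*) and tolerates naive plurals ("eggs"
matches *egg*), but requires whole-token identity — "sexual" does not
match *sex*, avoiding the classic false-hit class. `substring` mode is
available for recall-oriented scans, and the mode used is recorded in
pipeline provenance. Published candidate counts from any particular study
depend on the annotation database version and are not reproduced by this
rule alone.

## Numerical notes

* All binomial masses and tails are computed in log space
  (`lchoose` + `pbinom`); at extreme imbalance (say 5 × 10^5 vs 2 × 10^5
  reads) the true p-value is below double-precision underflow and is
  reported as 0 — never NaN or Inf.
* The two tails are evaluated from opposite ends of the distribution, so
  label-swap symmetry (swap libraries and counts) holds to ~10⁻¹² relative,
  not bitwise.
* Wilson intervals in `power_curve()` pin their endpoints exactly at
  empirical rates of 0 or 1, where the closed-form algebra is off by one
  ulp.
* Test oracles in the suite are independent brute-force implementations
  (direct factorial products and explicit tail sums; a textbook pooled-t
  formula), never the library calls they check.

## Known limitations

* Single-library designs only: no dispersion estimation, no replicate
  normalization.
* The simulator draws reads, not sequences: no read-level error model, no
  assembly simulation.
* CEG coverage consumes a gene → hit-count table; the homology search
  that produces it is out of scope.
* The keyword rule is a screen, not a classifier; precision depends
  entirely on the annotation source.
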