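---
title: "Scoring microhomology at CRISPR deletion junctions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microhomology at CRISPR deletion junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhjunction)
```

# Background

CRISPR/Cas9 editing frequently produces deletions far larger than the
intended edit — hundreds of bases to several kilobases beyond the sgRNA
target sites. Such larger deletions (LDs) are easy to miss with
short-range genotyping PCR, because they remove primer binding sites and
masquerade as wild-type or simple knock-out clones. Two signatures help
characterise the repair pathway behind them and quantify their burden in
an edited cell population:

1. **Junction microhomology.** Microhomology-mediated end joining
   (MMEJ) anneals resected DNA ends at short (1–10 bp) identical
   sequences, deleting the intervening stretch and one homology copy.
   An excess of short identities at deletion breakpoint junctions,
   relative to what base composition alone predicts, is the classic
   MMEJ footprint.
2. **Distance decay of deletion frequency.** Droplet digital PCR
   (ddPCR) measures the fraction of alleles that still retain a given
   position. The deleted fraction falls off with distance from the cut
   site, and the decay is well described by a linear model in
   log-distance plus a per-sample cutting-efficiency term.

`mhjunction` implements both analyses, their null models, and seeded
generators that emulate the data so the whole pipeline is testable
without external downloads.

# The microhomology statistic

## Definition

All coordinates are 0-based half-open. A deletion $[s, e)$ joins the
sequence retained 5′ of $s$ to the sequence retained 3′ of $e$. Consider
the offsets $j$ for which

$$ g[s + j] = g[e + j]. $$

The maximal contiguous run of matching offsets around $j = 0$ — `k_left`
offsets with $j < 0$ and `k_right` with $j \ge 0$ — forms a single
matched block straddling the junction. Its total length

$$ x = k_\text{left} + k_\text{right} $$

is the reported microhomology length, with the block sequence
$g[s - k_\text{left},\, s - k_\text{left} + x)$. Each side is searched
at most `window` (default 10) bp deep and the reported total is capped
at `window`. Identity is exact: any mismatch terminates a run, and `N`
never matches anything, including another `N` (a conservative choice —
an undetermined base cannot support an identity claim).

Why the *sum* and not, say, the longer of the two runs? Because the
block is the physically meaningful object. If repair annealed a $k$-bp
motif, the aligner that mapped the allele was free to place the deletion
anywhere within the resulting ambiguity run: every deletion
$[s - k_\text{left} + j,\; e - k_\text{left} + j)$ for
$j = 0, \dots, x$ yields exactly the same repaired sequence. Depending
on placement the same event appears as a pure right extension, a pure
left extension, or a split (`spanning`) block; only the sum recovers the
motif length regardless of placement. The test suite asserts this
repair-invariance identity literally.

The `direction` field records where the block sits relative to the
reported breakpoints: `right_extension` (entirely 3′, i.e.
`k_left = 0`), `left_extension` (entirely 5′), `spanning` (split), or
`none`. It is alignment metadata, not biology — the spanning case simply
means the submitted coordinates placed the junction inside the ambiguity
run.

## The chance null

For two independent positions in an i.i.d. equal-frequency genome, each
side's run length is geometric with success probability $3/4$, so the
total $x$ has probability mass

$$ P(x) = (x + 1)\left(\tfrac{1}{4}\right)^{x}\left(\tfrac{3}{4}\right)^{2}, $$

the $(x+1)$ factor counting the ways a length-$x$ block can be split
across the junction. `chance_expectation()` returns this closed form
($P(0) = 0.5625$, $P(1) = 0.28125$, …) and `chance_distribution()`
truncates it with an explicit tail mass. Because the scorer caps lengths
at the window, comparisons fold all null mass beyond the window into the
top bin.

The second null is *simulated*: `simulate_background()` draws deletions
of fixed length (the mean observed LD length, following the study
design) at uniform random genomic positions and scores them **with the
same estimator** as the observed set, so the two distributions share any
estimator quirks. On an i.i.d. genome this background converges to the
chance law (total variation < 0.005 at $n = 10^5$ in the validation
suite, bound 0.02).

## Enrichment testing

`enrichment_test()` distinguishes two situations:

* against the **analytic chance law**, a chi-squared goodness-of-fit
  test, with tail bins pooled until every expected cell reaches 5; if
  even a two-cell table cannot reach that bound, an exact binomial test
  on the pooled top cell is used instead;
* against a **finite simulated background**, a two-sample chi-squared
  test of homogeneity on the observed-vs-background table. Treating a
  74-deletion background histogram as exact probabilities would roughly
  double the test statistic's scale and inflate false positives; the
  homogeneity form accounts for the null's own sampling noise.

## Alternative microhomologies

For a junction with motif $M$, occurrences of $M$ strictly inside the
deleted sequence (overlaps allowed) are *alternative* microhomologies —
more cut-proximal options the repair bypassed. The copy consumed at the
junction is subtracted for pure right/left extensions (a spanning block
has no copy fully inside the deletion), and positions inside an excluded
interval — for paired-sgRNA designs, the segment between the two cut
sites, which is deleted by the intended edit rather than by resection —
are not counted.

## GC bias

Under no compositional bias, each microhomology base is G/C with
probability equal to the background GC fraction; `gc_bias_test()`
compares the pooled G/C base count to that expectation (two-cell
chi-squared), optionally within each length stratum with Bonferroni
correction, refusing strata whose expected cell falls below 5. For deep
sequencing data, `background_gc()` derives the background from the
amplicon interval that holds 93–95% of the read mass, growing the
interval outward from the coverage-weighted median, at each step taking
the side with more coverage — the mass-greedy rule keeps the interval
minimal when coverage is asymmetric.

One calibration subtlety: in an i.i.d. genome with unequal base
frequencies $p_b$, a base *conditioned on matching across the junction*
is distributed $\propto p_b^2$, so microhomology GC equals genome GC
only at GC = 0.5. The built-in calibration experiments therefore run on
a GC = 0.5 genome, where the background-GC assumption is exact. On
strongly skewed real regions the pooled test inherits the same mild
distortion as the assumption it tests.

# The deletion-frequency model

ddPCR reports the concentration of a target amplicon relative to a
matched non-targeting control. Alleles that deleted the amplicon no
longer amplify, so

$$ y = 1 - \frac{c_\text{sample}}{c_\text{control}} $$

is the deletion frequency at that position (ratios slightly above 1 are
clipped with a warning; a `ratio` mode returns the raw ratio for users
who prefer the literal quotient). The model is ordinary least squares of

$$ y = \beta_0 + \beta_1 \ln x + \beta_2 a + \varepsilon, $$

with $x$ the distance (bp) from the amplicon midpoint to the nearest
sgRNA midpoint and $a$ the sample's cutting efficiency — the largest
deletion frequency measured directly at an sgRNA site. Natural log is
used, matching the convention of the `lm` formula idiom. Amplicons
sitting on the sgRNA site (within 30 bp by default) define $a$ and are
excluded from the response by default, since their distance is
degenerate under the log transform; `include_at_site = TRUE` restores
them with distance floored at 1 bp.

Diagnostics follow standard practice: residual histogram, Q–Q pairs and
a Shapiro–Wilk p-value (degenerate all-zero residuals are flagged, not
tested). Predictions carry delta-method 95% confidence intervals from
the OLS covariance; reported values are clipped to $[0,1]$ with the
unclipped value retained. `allele_frequency_profile()` evaluates
$1 - \hat y$ symmetrically across ±3 kb (distance floored at 1 bp at the
centre), the conventional way to display the retained-allele landscape
around a cut.

# The synthetic-data generators

`sim_config()` fixes the simulated study conditions:

* **Genome**: i.i.d. bases, 200 kb, GC 0.5 — long enough to host a
  3 kb resection radius on both sides of several cut sites. What this
  deliberately does *not* emulate: repeats, chromatin, sequence
  context, sequencing error, PCR bias. Passing tests therefore
  demonstrate statistical correctness of the estimators and tests, not
  robustness to genomic repeat structure.
* **Repair outcomes** (`simulate_repair_alleles()`): with probability
  `p_mmej` an allele anneals at a sampled microhomology pair flanking
  the cut — length drawn from `mh_length_weights` (default mass on
  2–5 bp, the range dominating observed LD junctions), composition
  tilted by `gc_pull` per G/C base — deleting between the copies so
  that re-scoring the emitted deletion recovers at least the sampled
  homology. Otherwise the allele is an NHEJ-style 1–25 bp deletion
  spanning the cut. Insertions (1–10 bp) occur with probability
  `p_insertion`; read counts are geometric (heavy-tailed, like
  amplicon data).
* **ddPCR tables** (`simulate_ddpcr()`): per-sample efficiency uniform
  on 0.4–0.9, frequencies from the linear model plus Gaussian noise
  (`noise_sd`, default 0.02), clipped to $[0,1]$, and converted to
  sample/control concentrations so the frequency definition
  round-trips. Default coefficients $\beta_0 = 0.62$,
  $\beta_1 = -0.10$, $\beta_2 = 0.30$ were chosen once so that the
  deletion frequency approaches the cutting efficiency at the cut
  itself, roughly a quarter of alleles are deleted 250 bp out at
  average efficiency, the signal decays to near zero by 3 kb, and the
  default design (distances 250–1500 bp) stays inside the unit
  interval so clipping does not distort the linear truth.

# Validation design and problem sizes

The package's statistical checks run at sizes chosen to mirror the
experimental regime while remaining quick:

* scorer agreement with an independent brute-force enumeration on
  1,000 random genome/deletion pairs (exact, 100% required);
* background-vs-chance convergence at $10^5$ simulated deletions on a
  1 Mb genome (TV < 0.02);
* enrichment detection on 74 junctions spread over 16 cut sites — the
  observed LD census — with 100 seeded replicates per condition:
  MMEJ-biased sets must reject both nulls at $p < 10^{-6}$ in ≥95% of
  replicates, NHEJ-only sets must stay non-significant ($p > 0.01$) in
  ≥90%. Spreading junctions over sites matters: piling all 74 alleles
  onto one cut makes their junction flanks heavily dependent and
  invalidates any i.i.d. null;
* regression: exact coefficient recovery (≤ 10⁻⁸) on noiseless tables;
  95% CI coverage within 91–99% over 500 replicates at noise SD 0.05,
  $n = 48$, on a 50–500 bp design where the model stays interior;
* GC-bias calibration: empirical type-I ≤ 0.02 at nominal 0.01 over
  200 replicates; power ≥ 0.9 at `gc_pull = 4`.

# Degenerate inputs and numerical conventions

* Coordinates are converted from 1-based-inclusive inputs exactly once,
  at parse time (`# coord=1-based-inclusive` pragma), and all written
  tables are 0-based half-open — one conversion point, no off-by-one
  drift.
* Windows truncate (never pad) at contig edges.
* Chi-squared tables pool tail bins to keep expected cells ≥ 5; the
  goodness-of-fit path falls back to an exact binomial test when even
  two pooled cells cannot reach the bound; per-length GC strata use
  Bonferroni across tested strata.
* Dunn's post-hoc z-tests after Kruskal–Wallis use tie-corrected pooled
  ranks with `p.adjust` (Bonferroni by default).
* Constant-response regressions report $R^2 = 0$ rather than the
  numerically unstable ratio of two near-zero sums of squares.
* All stochastic helpers take explicit seeds, record them in their
  outputs, and restore the caller's RNG state on exit.

# Limitations

* The scorer finds exact identities only; MMEJ with mismatch-tolerant
  annealing, and single-strand annealing at long repeats, are out of
  scope.
* The allele tables consumed here are the *output* of an external
  allele caller; read trimming, merging, alignment and base-quality
  modelling are not re-implemented.
* The simulated genomes carry no repeat structure, so enrichment
  results on real loci with dense repeats should additionally consult a
  repeat annotation.
* The regression is descriptive, not mechanistic: it summarises the
  population-level distance decay and makes no claim about resection
  kinetics.
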