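# mhjunction

Analysis of larger-than-expected deletions induced by CRISPR/Cas9
editing: microhomology scoring at deletion breakpoint junctions, null
models for enrichment testing, GC-bias and insertion statistics, and a
regression model of deletion frequency around sgRNA cut sites.

## Who this is for

Genome-editing labs that genotype edited clones or pools and want to
know (a) whether the breakpoint junctions of their larger deletions
(LDs) carry the short-microhomology footprint of microhomology-mediated
end joining (MMEJ), and (b) what fraction of alleles in a targeted
population is deleted at a given distance from the cut site, as
measured by droplet digital PCR (ddPCR).

## The statistics at the core

**Junction microhomology.** For a deletion `[s, e)` on reference `g`,
the junction microhomology is the contiguous block of offsets `j`
around the junction with `g[s + j] == g[e + j]` — `k_left` matches on
the 5′ side plus `k_right` on the 3′ side, searched 10 bp deep per
side. Its total length `x = k_left + k_right` is the length of the
annealed motif regardless of where the aligner placed the deletion
inside the ambiguity run. Under a uniform-base null,

    P(x) = (x + 1) (1/4)^x (3/4)^2

which the package provides as the analytic chance distribution,
alongside a simulated background (random genomic positions, fixed
length, scored with the same estimator). Observed length histograms are
tested against the chance law by chi-squared goodness-of-fit and
against simulated backgrounds by a two-sample homogeneity test.

**Deletion-frequency regression.** From ddPCR relative concentrations,
deletion frequency is `y = 1 − c_sample / c_control`, and

    y = b0 + b1·ln(x) + b2·a + e

is fit by OLS, where `x` is the distance from the amplicon midpoint to
the nearest sgRNA midpoint and `a` is the sample's cutting efficiency
(the maximum `y` at an sgRNA site). Predictions carry delta-method 95%
confidence intervals, and `allele_frequency_profile()` renders the
retained-allele landscape `1 − ŷ` across ±3 kb of a cut site.

See `vignettes/junction-microhomology.Rmd` for the full model account.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly.

```r
library(mhjunction)

# 74 repair outcomes at one cut site, 70% MMEJ with 2-5 bp homologies
cfg <- sim_config(seed = 42, p_mmej = 0.7, n_alleles = 74)
g   <- generate_genome(cfg$genome_length, cfg$gc, seed = cfg$seed)
sim <- simulate_repair_alleles(g, 100000L, cfg)

scored <- score_microhomology(g, sim$deletions)
head(scored[, c("start", "end", "mh_length", "mh_seq", "direction")], 4)
#>    start    end mh_length mh_seq       direction
#> 1 100000 100005         1      C  left_extension
#> 2  99997 100007         1      A right_extension
#> 3  99986 100003         1      T  left_extension
#> 4  99997 100004         0                   none

enrichment_test(scored$mh_length, chance_distribution(10))[c("statistic", "p")]
#> $statistic
#> [1] 202.6571
#> $p
#> [1] 9.651771e-45
```

The MMEJ-biased set is massively enriched over chance: under the null
only ~16% of junctions would show ≥2 bp of microhomology, while the
simulated repair outcomes concentrate at 2–5 bp.

```r
# ddPCR: 8 samples, amplicons 250-1500 bp from the cut
dd  <- simulate_ddpcr(sim_config(seed = 7))
sg  <- data.frame(chrom = "chrS", proto_start = dd$sg_mid - 10L,
                  proto_end = dd$sg_mid + 10L, pam_end = dd$sg_mid + 13L,
                  strand = "+", cut_site = dd$sg_mid)
fit <- fit_ld_model(ddpcr_to_points(dd$ddpcr, sg))
fit
#> <ld_model_fit> frequency ~ log(distance) + efficiency, n = 40
#>   b0 = 0.69706  b1 = -0.10807  b2 = 0.26993
#>   R^2 = 0.9522  adjusted R^2 = 0.9496

predict_frequency(fit, 250)
#>   distance efficiency  estimate     lower     upper       raw
#> 1      250  0.6449991 0.2744734 0.2629046 0.2860422 0.2744734
```

At average cutting efficiency, about 27% of alleles are predicted
deleted 250 bp from the cut in this simulated population, with a tight
confidence interval — the kind of number that explains why short-range
genotyping PCR misses a substantial fraction of edited alleles.

A thin command-line wrapper over the same functions lives at
`inst/scripts/mhjunction.R` (subcommands `simulate`, `score`, `null`,
`enrich`, `sd`, `ldfit`, `run-all`).

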