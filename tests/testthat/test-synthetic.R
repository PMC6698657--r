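test_that("generated genomes hit their GC target and are seed-deterministic", {
  g <- generate_genome(100000, gc = 0.5, seed = 3)
  s <- unclass(g)[[1]]
  gc_obs <- (nchar(s) - nchar(gsub("[GC]", "", s))) / 100000
  se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(gc_obs - 0.5), 3 * se)
  expect_identical(unclass(generate_genome(1000, seed = 8)),
                   unclass(generate_genome(1000, seed = 8)))
  g0 <- generate_genome(1000, gc = 0, seed = 1)
  expect_false(grepl("[GC]", unclass(g0)[[1]]))
  expect_error(generate_genome(1000, gc = 1.2), "gc must lie")
})

test_that("MMEJ alleles re-score to at least their sampled microhomology", {
  cfg <- sim_config(seed = 101, p_mmej = 1, n_alleles = 150,
                    mh_length_weights = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))
  g <- generate_genome(cfg$genome_length, cfg$gc, seed = cfg$seed)
  sim <- simulate_repair_alleles(g, 100000L, cfg)
  scored <- score_microhomology(g, sim$deletions)
  mmej <- !is.na(sim$mh_sampled)
  expect_gt(mean(mmej), 0.95)  # MMEJ placement rarely fails at k = 3
  # accidental longer homologies are allowed, shorter ones are not
  expect_gte(mean(scored$mh_length[mmej] >= 3), 0.99)
  # the cut site lies inside every MMEJ deletion
  expect_true(all(sim$deletions$start[mmej] < 100000 &
                  sim$deletions$end[mmej] >= 100000))
})

test_that("repair simulation is deterministic given the config seed", {
  cfg <- sim_config(seed = 77, n_alleles = 40)
  g <- generate_genome(50000, seed = 7)
  a <- simulate_repair_alleles(g, 25000L, cfg)
  b <- simulate_repair_alleles(g, 25000L, cfg)
  expect_identical(a, b)
})

test_that("NHEJ-only alleles carry no imposed microhomology and insertions obey p", {
  cfg <- sim_config(seed = 55, p_mmej = 0, p_insertion = 0, n_alleles = 60)
  g <- generate_genome(50000, seed = 5)
  sim <- simulate_repair_alleles(g, 25000L, cfg)
  expect_true(all(is.na(sim$mh_sampled)))
  expect_false(any(sim$alleles$has_insertion))
  expect_equal(insertion_fraction(sim$alleles), 0)
  lens <- sim$deletions$end - sim$deletions$start
  expect_true(all(lens >= 1 & lens <= cfg$nhej_max_del))
})

test_that("gc_pull shifts the composition of sampled microhomologies", {
  g <- generate_genome(200000, gc = 0.5, seed = 21)
  base <- sim_config(seed = 22, p_mmej = 1, n_alleles = 120,
                     mh_length_weights = c(0, 1, 2, 2, 1, 0, 0, 0, 0, 0))
  pulled <- base; pulled$gc_pull <- 4
  s0 <- score_microhomology(g, simulate_repair_alleles(g, 1e5, base)$deletions)
  s1 <- score_microhomology(g, simulate_repair_alleles(g, 1e5, pulled)$deletions)
  gc0 <- sum(s0$gc_count) / sum(s0$mh_length)
  gc1 <- sum(s1$gc_count) / sum(s1$mh_length)
  expect_gt(gc1, gc0 + 0.1)
})

test_that("simulated ddPCR tables round-trip the frequency definition", {
  cfg <- sim_config(seed = 31, noise_sd = 0)
  dd <- simulate_ddpcr(cfg)
  # re-deriving frequency from concentrations inverts the simulation
  freq <- deletion_frequency(dd$ddpcr$rel_conc, dd$ddpcr$control_conc)
  sg <- data.frame(chrom = "chrS", proto_start = dd$sg_mid - 10L,
                   proto_end = dd$sg_mid + 10L, pam_end = dd$sg_mid + 13L,
                   strand = "+", cut_site = dd$sg_mid)
  pts <- ddpcr_to_points(dd$ddpcr, sg)
  # efficiency amplicons recover the drawn efficiencies
  eff <- cutting_efficiency(pts)
  expect_equal(unname(eff[dd$truth$sample]), dd$truth$efficiency,
               tolerance = 1e-12)
  # noiseless fit recovers the generator coefficients
  fit <- fit_ld_model(pts)
  expect_equal(fit$b0, cfg$ld_b0, tolerance = 1e-8)
  expect_equal(fit$b1, cfg$ld_b1, tolerance = 1e-8)
  expect_equal(fit$b2, cfg$ld_b2, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
})

test_that("noisy ddPCR simulation allows coefficient recovery within 2 SE", {
  set.seed(40)
  reps <- 60
  est <- matrix(NA_real_, 3, reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(seed = 1000 + i, noise_sd = 0.05,
                      efficiency_range = c(0.55, 0.9))
    dd <- simulate_ddpcr(cfg, distances = c(50, 100, 200, 300, 400, 500))
    sg <- data.frame(chrom = "chrS", proto_start = dd$sg_mid - 10L,
                     proto_end = dd$sg_mid + 10L, pam_end = dd$sg_mid + 13L,
                     strand = "+", cut_site = dd$sg_mid)
    fit <- fit_ld_model(ddpcr_to_points(dd$ddpcr, sg))
    est[, i] <- c(fit$b0, fit$b1, fit$b2)
  }
  means <- rowMeans(est)
  ses <- apply(est, 1, sd) / sqrt(reps)
  truth <- c(0.62, -0.10, 0.30)
  expect_true(all(abs(means - truth) < 2.5 * ses + 1e-12))
})
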