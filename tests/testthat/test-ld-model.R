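make_points <- function(b0 = 0.9, b1 = -0.1, b2 = 0.3, noise = 0,
                        distances = c(50, 100, 250, 500, 1000, 2000),
                        efficiencies = c(0.5, 0.9)) {
  grid <- expand.grid(distance = distances, efficiency = efficiencies)
  grid$frequency <- b0 + b1 * log(grid$distance) + b2 * grid$efficiency +
    rnorm(nrow(grid), 0, noise)
  grid$sample <- paste0("s", as.integer(factor(grid$efficiency)))
  grid
}

test_that("deletion frequency definition, clipping and guards", {
  expect_equal(deletion_frequency(0.78, 1.0), 0.22)
  expect_equal(deletion_frequency(1.0, 1.0), 0)
  expect_warning(f <- deletion_frequency(1.05, 1.0), "clipped")
  expect_equal(f, 0)
  expect_equal(deletion_frequency(0.78, 1.0, definition = "ratio"), 0.78)
  expect_error(deletion_frequency(0.5, 0), "control")
})

test_that("cutting efficiency is the max at-site frequency per sample", {
  pts <- data.frame(sample = c("s1", "s1", "s1", "s2"),
                    frequency = c(0.6, 0.55, 0.9, 0.4),
                    at_site = c(TRUE, TRUE, FALSE, TRUE))
  eff <- cutting_efficiency(pts)
  expect_equal(unname(eff[c("s1", "s2")]), c(0.6, 0.4))
  pts$at_site[4] <- FALSE
  expect_error(cutting_efficiency(pts), "s2")
})

test_that("noiseless data are interpolated exactly", {
  set.seed(1)
  pts <- make_points()
  fit <- fit_ld_model(pts)
  expect_equal(fit$b0, 0.9, tolerance = 1e-8)
  expect_equal(fit$b1, -0.1, tolerance = 1e-8)
  expect_equal(fit$b2, 0.3, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  # predictions at training points reproduce fitted values exactly
  for (i in c(1L, 5L, 9L)) {
    p <- predict_frequency(fit, pts$distance[i], pts$efficiency[i])
    expect_equal(p$raw, pts$frequency[i], tolerance = 1e-8)
  }
})

test_that("constant response yields zero slopes and R2 = 0", {
  pts <- make_points(b1 = 0, b2 = 0, b0 = 0.4)
  fit <- fit_ld_model(pts)
  expect_equal(fit$b1, 0, tolerance = 1e-12)
  expect_equal(fit$b2, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 0)
})

test_that("adjusted R2 matches the closed form with two predictors", {
  set.seed(4)
  pts <- make_points(noise = 0.05)
  fit <- fit_ld_model(pts)
  n <- fit$n
  expect_equal(fit$adjusted_r2, 1 - (1 - fit$r2) * (n - 1) / (n - 2 - 1))
  expect_lte(fit$adjusted_r2, fit$r2)
})

test_that("fit guards degenerate designs and is row-order invariant", {
  pts <- make_points()
  expect_error(fit_ld_model(pts[1:3, ]), "at least 4")
  same_d <- pts; same_d$distance <- 100
  expect_error(fit_ld_model(same_d), "rank-deficient|identical")
  set.seed(2)
  shuf <- pts[sample.int(nrow(pts)), ]
  f1 <- fit_ld_model(pts); f2 <- fit_ld_model(shuf)
  expect_equal(c(f1$b0, f1$b1, f1$b2), c(f2$b0, f2$b1, f2$b2))
})

test_that("coefficient estimates are unbiased under generator noise", {
  set.seed(9)
  est <- replicate(100, {
    pts <- make_points(noise = 0.05,
                       distances = c(50, 100, 250, 500, 1000, 2000),
                       efficiencies = seq(0.4, 0.9, length.out = 8))
    fit <- fit_ld_model(pts)
    c(fit$b0, fit$b1, fit$b2)
  })
  means <- rowMeans(est)
  ses <- apply(est, 1, sd) / sqrt(ncol(est))
  truth <- c(0.9, -0.1, 0.3)
  expect_true(all(abs(means - truth) < 2 * ses + 1e-12))
})

test_that("diagnostics expose residual structure", {
  set.seed(5)
  pts <- make_points(noise = 0)
  fit <- fit_ld_model(pts)
  d <- diagnose_fit(fit)
  expect_true(d$degenerate)  # all-zero residuals flagged
  expect_true(is.na(d$normality_p))

  # normal residuals pass, exponential residuals fail, most of the time
  norm_p <- replicate(40, {
    pts <- make_points(noise = 0.05,
                       distances = round(exp(seq(log(50), log(2000),
                                                 length.out = 25))),
                       efficiencies = seq(0.4, 0.9, length.out = 8))
    diagnose_fit(fit_ld_model(pts))$normality_p
  })
  expect_gt(mean(norm_p > 0.01), 0.9)
  skew_p <- replicate(40, {
    pts <- make_points(noise = 0,
                       distances = round(exp(seq(log(50), log(2000),
                                                 length.out = 25))),
                       efficiencies = seq(0.4, 0.9, length.out = 8))
    pts$frequency <- pts$frequency + rexp(nrow(pts), 10)
    diagnose_fit(fit_ld_model(pts))$normality_p
  })
  expect_gt(mean(skew_p < 0.01), 0.6)
})

test_that("confidence intervals tighten with sample size", {
  set.seed(6)
  width <- sapply(c(12, 120), function(n) {
    d <- exp(runif(n, log(50), log(2000)))
    pts <- data.frame(distance = d, efficiency = runif(n, 0.4, 0.9))
    pts$frequency <- 0.9 - 0.1 * log(pts$distance) + 0.3 * pts$efficiency +
      rnorm(n, 0, 0.05)
    fit <- fit_ld_model(pts)
    p <- predict_frequency(fit, 250)
    p$upper - p$lower
  })
  expect_lt(width[2], width[1])
})

test_that("allele frequency profile is symmetric and decays with |offset|", {
  pts <- make_points()
  fit <- fit_ld_model(pts)
  prof <- allele_frequency_profile(fit, half_window = 3000, step = 50)
  expect_equal(range(prof$offset), c(-3000, 3000))
  mirrored <- prof$allele_frequency[match(-prof$offset, prof$offset)]
  expect_equal(prof$allele_frequency, mirrored)
  expect_true(all(prof$allele_frequency >= 0 & prof$allele_frequency <= 1))
  # with b1 < 0 the deletion frequency falls with distance, so the
  # retained-allele frequency rises monotonically away from the cut
  right <- prof[prof$offset >= 0, ]
  expect_true(all(diff(right$allele_frequency) >= -1e-12))
  # profile value is 1 - the point prediction
  p250 <- predict_frequency(fit, 250)
  expect_equal(prof$allele_frequency[prof$offset == 250],
               1 - p250$estimate)
  # "average" efficiency equals prediction at the mean efficiency
  expect_equal(predict_frequency(fit, 250, "average")$estimate,
               predict_frequency(fit, 250, fit$mean_efficiency)$estimate)
})
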