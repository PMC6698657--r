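# Linear model of deletion frequency: y ~ log(x) + a, where y is the
# fraction of alleles deleted at a position, x the distance in bp from
# the ddPCR amplicon midpoint to the nearest sgRNA midpoint, and a the
# per-sample cutting efficiency. Natural logarithm throughout.

#' Deletion frequency from ddPCR relative concentrations
#'
#' Deletion frequency at a position is one minus the ratio of the
#' relative target concentration in the edited sample to the matched
#' non-targeting control: alleles that deleted the amplicon no longer
#' amplify, so the concentration drop is the deleted fraction. With
#' `definition = "ratio"` the raw ratio itself is returned instead.
#' Values are clipped to `[0, 1]` with a warning when the ratio exceeds 1
#' (measurement noise).
#'
#' @param rel_conc_sample Relative concentration(s) in the edited sample.
#' @param rel_conc_control Matched non-targeting control concentration(s),
#'   `> 0`.
#' @param definition `"one_minus_ratio"` (default) or `"ratio"`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
deletion_frequency <- function(rel_conc_sample, rel_conc_control,
                               definition = c("one_minus_ratio", "ratio")) {
  definition <- match.arg(definition)
  if (any(!is.finite(rel_conc_control)) || any(rel_conc_control <= 0)) {
    stop("control concentration must be > 0", call. = FALSE)
  }
  if (any(rel_conc_sample < 0)) {
    stop("sample concentration must be >= 0", call. = FALSE)
  }
  ratio <- rel_conc_sample / rel_conc_control
  if (any(ratio > 1)) {
    warning(sum(ratio > 1), " observation(s) with sample/control ratio > 1 ",
            "clipped to the [0, 1] range")
    ratio <- pmin(ratio, 1)
  }
  if (definition == "ratio") ratio else 1 - ratio
}

#' Build regression observations from a ddPCR table
#'
#' Converts a ddPCR measurement table into frequency points: deletion
#' frequency per amplicon, distance from the amplicon midpoint to the
#' nearest sgRNA midpoint (floored at 1 bp before the log transform),
#' and the per-sample cutting efficiency. Amplicons whose midpoint lies
#' within `amplicon_halfwidth` bp of an sgRNA midpoint are efficiency
#' amplicons: the efficiency of a sample is the highest deletion
#' frequency among them.
#'
#' @param ddpcr ddPCR table (`sample`, `chrom`, `amplicon_mid`,
#'   `rel_conc`, `control_conc`).
#' @param sgrnas sgRNA table.
#' @param amplicon_halfwidth Half-width in bp used to decide that an
#'   amplicon sits on an sgRNA target site (default 30).
#' @param definition Frequency definition, see [deletion_frequency()].
#' @return Data.frame of frequency points (`sample`, `distance`,
#'   `frequency`, `efficiency`, `at_site`).
#' @export
ddpcr_to_points <- function(ddpcr, sgrnas, amplicon_halfwidth = 30L,
                            definition = c("one_minus_ratio", "ratio")) {
  definition <- match.arg(definition)
  freq <- deletion_frequency(ddpcr$rel_conc, ddpcr$control_conc, definition)
  sg_mid <- (sgrnas$proto_start + sgrnas$proto_end) / 2
  dist <- numeric(nrow(ddpcr))
  for (i in seq_len(nrow(ddpcr))) {
    j <- which(sgrnas$chrom == ddpcr$chrom[i])
    if (!length(j)) {
      stop("no sgRNA on chromosome ", ddpcr$chrom[i], " (row ", i, ")",
           call. = FALSE)
    }
    dist[i] <- min(abs(ddpcr$amplicon_mid[i] - sg_mid[j]))
  }
  at_site <- dist <= amplicon_halfwidth
  pts <- data.frame(sample = ddpcr$sample, distance = pmax(dist, 1),
                    frequency = freq, at_site = at_site,
                    stringsAsFactors = FALSE)
  eff <- tapply(ifelse(at_site, freq, -Inf), ddpcr$sample, max)
  no_eff <- names(eff)[!is.finite(eff)]
  if (length(no_eff)) {
    stop("no amplicon overlapping an sgRNA target site for sample(s): ",
         paste(no_eff, collapse = ", "), call. = FALSE)
  }
  pts$efficiency <- as.numeric(eff[pts$sample])
  pts
}

#' Per-sample sgRNA cutting efficiency
#'
#' The cutting efficiency of a sample is the highest deletion frequency
#' measured directly at an sgRNA target site.
#'
#' @param points Frequency points with `sample`, `frequency` and
#'   `at_site` columns (see [ddpcr_to_points()]).
#' @return Named numeric vector, one efficiency per sample.
#' @export
cutting_efficiency <- function(points) {
  stopifnot(all(c("sample", "frequency", "at_site") %in% names(points)))
  eff <- tapply(ifelse(points$at_site, points$frequency, -Inf),
                points$sample, max)
  bad <- names(eff)[!is.finite(eff)]
  if (length(bad)) {
    stop("no amplicon at an sgRNA target site for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- as.numeric(eff)
  names(out) <- names(eff)
  out
}

#' Fit the log-distance deletion-frequency model
#'
#' Ordinary least squares of deletion frequency on the natural log of
#' distance and cutting efficiency: `frequency ~ log(distance) +
#' efficiency`. Amplicons sitting on sgRNA target sites define the
#' efficiency covariate and are excluded from the response by default.
#'
#' @param points Frequency points (`distance`, `frequency`,
#'   `efficiency`, optional `at_site`).
#' @param include_at_site Keep at-site points as response observations
#'   (default `FALSE`).
#' @return An object of class `ld_model_fit`: coefficients `b0`, `b1`,
#'   `b2`, `r2`, `adjusted_r2`, `residuals`, `n`, `covariance` (3x3),
#'   `mean_efficiency` and the underlying `lm` fit.
#' @export
fit_ld_model <- function(points, include_at_site = FALSE) {
  stopifnot(all(c("distance", "frequency", "efficiency") %in% names(points)))
  if (!include_at_site && "at_site" %in% names(points)) {
    points <- points[!points$at_site, , drop = FALSE]
  }
  if (any(points$distance <= 0)) {
    stop("distances must be > 0 for the log transform", call. = FALSE)
  }
  if (nrow(points) < 4L) {
    stop("need at least 4 observations to fit the model", call. = FALSE)
  }
  if (length(unique(points$distance)) < 2L) {
    stop("all distances identical: log(distance) term is rank-deficient",
         call. = FALSE)
  }
  dat <- data.frame(y = points$frequency, logx = log(points$distance),
                    a = points$efficiency)
  fit <- stats::lm(y ~ logx + a, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  }
  # summary.lm warns on exactly-interpolated (noiseless) data; the
  # degenerate R^2 is handled explicitly below
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(fit)
  r2 <- sm$r.squared
  ar2 <- sm$adj.r.squared
  sst <- sum((dat$y - mean(dat$y))^2)
  if (!is.finite(r2) || sst < .Machine$double.eps * nrow(dat)) {
    # constant response: no variance to explain
    r2 <- 0
    ar2 <- 1 - (1 - r2) * (nrow(dat) - 1) / (nrow(dat) - 3)
  }
  structure(list(
    b0 = unname(co[["(Intercept)"]]),
    b1 = unname(co[["logx"]]),
    b2 = unname(co[["a"]]),
    r2 = r2,
    adjusted_r2 = ar2,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    n = nrow(dat),
    covariance = sm$cov.unscaled * sm$sigma^2,
    mean_efficiency = mean(points$efficiency),
    lm = fit
  ), class = "ld_model_fit")
}

#' @export
print.ld_model_fit <- function(x, ...) {
  cat("<ld_model_fit> frequency ~ log(distance) + efficiency, n =", x$n,
      "\n  b0 =", signif(x$b0, 5), " b1 =", signif(x$b1, 5),
      " b2 =", signif(x$b2, 5),
      "\n  R^2 =", signif(x$r2, 4),
      " adjusted R^2 =", signif(x$adjusted_r2, 4), "\n")
  invisible(x)
}

#' Residual diagnostics for a fitted log-distance model
#'
#' Produces the material for goodness-of-fit inspection: residual
#' histogram counts, theoretical-vs-sample quantile pairs for a Q-Q
#' plot, and a Shapiro-Wilk normality p-value. Degenerate (all-zero)
#' residuals are flagged instead of tested.
#'
#' @param fit An `ld_model_fit`.
#' @param breaks Histogram breaks passed to [graphics::hist()] logic
#'   (computed with `hist(plot = FALSE)`).
#' @return List with `histogram` (data.frame mids/counts), `qq`
#'   (data.frame theoretical/sample), `normality_p` and `degenerate`.
#' @export
diagnose_fit <- function(fit, breaks = "Sturges") {
  stopifnot(inherits(fit, "ld_model_fit"))
  r <- fit$residuals
  degenerate <- stats::sd(r) < .Machine$double.eps^0.5
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  qq <- stats::qqnorm(r, plot.it = FALSE)
  ord <- order(qq$x)
  normality_p <- if (degenerate) NA_real_ else stats::shapiro.test(r)$p.value
  list(histogram = data.frame(mid = h$mids, count = h$counts),
       qq = data.frame(theoretical = qq$x[ord], sample = qq$y[ord]),
       normality_p = normality_p, degenerate = degenerate)
}

#' Predict deletion frequency at a distance
#'
#' Point estimate with a delta-method 95% confidence interval from the
#' OLS covariance. The reported estimate and interval are clipped to
#' `[0, 1]`; the unclipped value is retained in `raw`.
#'
#' @param fit An `ld_model_fit`.
#' @param distance Distance(s) in bp, `> 0`.
#' @param efficiency A cutting-efficiency fraction, or `"average"` for
#'   the mean per-observation efficiency of the training data.
#' @param level Confidence level (default 0.95).
#' @return Data.frame with `distance`, `efficiency`, `estimate`,
#'   `lower`, `upper` (clipped) and `raw`.
#' @export
predict_frequency <- function(fit, distance, efficiency = "average",
                              level = 0.95) {
  stopifnot(inherits(fit, "ld_model_fit"))
  if (any(distance <= 0)) stop("distance must be > 0", call. = FALSE)
  a <- if (identical(efficiency, "average")) fit$mean_efficiency
       else as.numeric(efficiency)
  stopifnot(is.finite(a), length(a) == 1L)
  X <- cbind(1, log(distance), a)
  est <- drop(X %*% c(fit$b0, fit$b1, fit$b2))
  se <- sqrt(rowSums((X %*% fit$covariance) * X))
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - 3L)
  data.frame(distance = distance, efficiency = a,
             estimate = pmin(1, pmax(0, est)),
             lower = pmin(1, pmax(0, est - tq * se)),
             upper = pmin(1, pmax(0, est + tq * se)),
             raw = est)
}

#' Relative allele-frequency profile around a cut site
#'
#' Evaluates `1 - predicted deletion frequency` over a symmetric window
#' around a simulated sgRNA cut site (default +/- 3 kb). The distance
#' used at each offset is `max(|offset|, 1)` bp.
#'
#' @param fit An `ld_model_fit`.
#' @param half_window Half-window in bp (default 3000).
#' @param step Step in bp between evaluated offsets (default 10).
#' @param efficiency Efficiency passed to [predict_frequency()].
#' @return Data.frame with `offset`, `distance`, `allele_frequency`
#'   (in `[0, 1]`).
#' @export
allele_frequency_profile <- function(fit, half_window = 3000L, step = 10L,
                                     efficiency = "average") {
  stopifnot(step >= 1)
  offsets <- seq(-half_window, half_window, by = step)
  dist <- pmax(abs(offsets), 1)
  pred <- predict_frequency(fit, dist, efficiency)
  data.frame(offset = offsets, distance = dist,
             allele_frequency = 1 - pred$estimate)
}
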