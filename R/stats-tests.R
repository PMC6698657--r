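# Group comparison and GC-bias tests for microhomology length/composition.

#' Test microhomology base composition for GC bias
#'
#' Under the no-bias null, each base of a microhomology is G or C with
#' probability equal to the background GC fraction of the region the
#' deletions come from. The pooled test compares the total number of G/C
#' bases among all microhomology bases against that expectation with a
#' two-cell chi-squared goodness-of-fit test; with
#' `stratify_by_length = TRUE` the same test is additionally run within
#' each microhomology length stratum, with Bonferroni correction across
#' strata.
#'
#' Strata (or a pooled table) whose smaller expected cell falls below
#' `min_expected` are not tested and report `NA`.
#'
#' @param results Scored table from [score_microhomology()] (or any
#'   data.frame with `mh_length` and `gc_count`).
#' @param background_gc Background GC fraction, strictly between 0 and 1.
#' @param stratify_by_length Also test each length stratum separately.
#' @param weights Optional observation weights (e.g. read counts).
#' @param min_expected Minimum expected cell count to run a test
#'   (default 5).
#' @return A list with `pooled` (data.frame: n_bases, observed_gc,
#'   expected_gc, statistic, p) and, if requested, `by_length` with one
#'   row per stratum plus Bonferroni-adjusted p-values.
#' @export
gc_bias_test <- function(results, background_gc, stratify_by_length = FALSE,
                         weights = NULL, min_expected = 5) {
  if (!(background_gc > 0 && background_gc < 1)) {
    stop("background_gc must lie strictly between 0 and 1", call. = FALSE)
  }
  len <- results$mh_length
  gc <- results$gc_count
  if (is.null(weights)) weights <- rep(1, length(len))
  keep <- len >= 1
  len <- len[keep]; gc <- gc[keep]; weights <- weights[keep]
  if (!length(len)) stop("no microhomology bases to test", call. = FALSE)

  cell_test <- function(n_bases, observed_gc) {
    expected_gc <- n_bases * background_gc
    expected_at <- n_bases * (1 - background_gc)
    if (min(expected_gc, expected_at) < min_expected) {
      return(c(statistic = NA_real_, p = NA_real_,
               expected_gc = expected_gc))
    }
    stat <- (observed_gc - expected_gc)^2 / expected_gc +
      ((n_bases - observed_gc) - expected_at)^2 / expected_at
    c(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      expected_gc = expected_gc)
  }

  n_bases <- sum(weights * len)
  observed_gc <- sum(weights * gc)
  pooled <- cell_test(n_bases, observed_gc)
  out <- list(pooled = data.frame(
    n_bases = n_bases, observed_gc = observed_gc,
    expected_gc = pooled[["expected_gc"]],
    statistic = pooled[["statistic"]], p = pooled[["p"]]))

  if (stratify_by_length) {
    ks <- sort(unique(len))
    rows <- lapply(ks, function(k) {
      i <- len == k
      nb <- sum(weights[i]) * k
      og <- sum(weights[i] * gc[i])
      ct <- cell_test(nb, og)
      data.frame(length = k, n_bases = nb, observed_gc = og,
                 expected_gc = ct[["expected_gc"]],
                 statistic = ct[["statistic"]], p = ct[["p"]])
    })
    by_length <- do.call(rbind, rows)
    tested <- sum(!is.na(by_length$p))
    by_length$p_adjusted <- pmin(1, by_length$p * max(tested, 1L))
    out$by_length <- by_length
  }
  out
}

#' Compare microhomology length distributions between groups
#'
#' * `chi2`: chi-squared test of homogeneity on the groups' length
#'   histograms (bins pooled from the tail so every expected cell is at
#'   least `min_expected`);
#' * `mannwhitney`: two-tailed Mann-Whitney (Wilcoxon rank-sum) test,
#'   two groups only;
#' * `kruskal_dunn`: Kruskal-Wallis across all groups followed by Dunn's
#'   pairwise post-hoc z tests (tie-corrected) with p-value adjustment.
#'
#' @param groups Named list of integer length vectors (>= 2 non-empty
#'   groups).
#' @param method `"chi2"`, `"kruskal_dunn"` or `"mannwhitney"`.
#' @param p_adjust_method Adjustment for Dunn pairwise p-values
#'   (default `"bonferroni"`).
#' @param min_expected Minimum expected cell for the chi-squared variant.
#' @return A list with `method`, `statistic`, `p`, and for
#'   `kruskal_dunn` a `pairwise` data.frame of Dunn comparisons.
#' @export
compare_groups <- function(groups,
                           method = c("chi2", "kruskal_dunn", "mannwhitney"),
                           p_adjust_method = "bonferroni", min_expected = 5) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("groups must be a list of >= 2 length vectors", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    stop("empty group(s): ",
         paste(which(sizes == 0L), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }

  if (method == "mannwhitney") {
    if (length(groups) != 2L) {
      stop("mannwhitney compares exactly two groups", call. = FALSE)
    }
    wt <- suppressWarnings(
      stats::wilcox.test(groups[[1L]], groups[[2L]],
                         alternative = "two.sided", exact = FALSE,
                         correct = TRUE))
    return(list(method = "mannwhitney",
                statistic = unname(wt$statistic), p = wt$p.value))
  }

  if (method == "chi2") {
    kmax <- max(unlist(groups))
    tab <- vapply(groups, function(x) tabulate(x + 1L, nbins = kmax + 1L),
                  integer(kmax + 1L))
    tab <- matrix(tab, nrow = kmax + 1L,
                  dimnames = list(0:kmax, names(groups)))
    tab <- pool_histogram_tail(tab, min_expected)
    if (nrow(tab) < 2L) {
      stop("all observations in one pooled bin; chi-squared not defined",
           call. = FALSE)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(method = "chi2", statistic = unname(ct$statistic),
                p = ct$p.value, table = tab))
  }

  # kruskal_dunn
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  kw <- stats::kruskal.test(values, fac)
  list(method = "kruskal_dunn", statistic = unname(kw$statistic),
       p = kw$p.value,
       pairwise = dunn_posthoc(values, fac, p_adjust_method))
}

# pool rows of a histogram (lowest length bins kept, tail collapsed)
# until every expected cell under homogeneity is >= min_expected
pool_histogram_tail <- function(tab, min_expected) {
  repeat {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (nrow(tab) <= 2L || min(expected) >= min_expected) break
    m <- nrow(tab)
    label <- paste0(">=", sub("^>=", "", rownames(tab)[m - 1L]))
    top <- tab[m - 1L, ] + tab[m, ]
    tab <- rbind(tab[seq_len(m - 2L), , drop = FALSE], top)
    rownames(tab)[m - 1L] <- label
  }
  tab
}

# Dunn's pairwise post-hoc z tests on pooled ranks with tie correction
dunn_posthoc <- function(values, fac, p_adjust_method) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(fac)
  mean_rank <- tapply(r, fac, mean)
  n_i <- tabulate(fac)
  pairs <- utils::combn(seq_along(lv), 2L)
  z <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j]))
    z[p] <- (mean_rank[i] - mean_rank[j]) / se
  }
  pval <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = lv[pairs[1L, ]], group2 = lv[pairs[2L, ]],
             z = z, p = pval,
             p_adjusted = stats::p.adjust(pval, method = p_adjust_method))
}
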