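# Null models for junction microhomology: the analytic chance
# expectation for two random genomic locations, and a simulated
# random-location background scored with the same estimator as the
# observed deletions.

#' Chance probability of an x-bp microhomology at two random locations
#'
#' For two independent uniform DNA locations, the probability that the
#' longest shared abutting run has length exactly `x` is
#' `P(x) = (x + 1) * (1/4)^x * (3/4)^2`: the run can be split between the
#' left and right extensions in `x + 1` ways, each matched base carries
#' probability 1/4, and both flanking positions must mismatch.
#'
#' @param x Integer homology length(s), `>= 0`.
#' @return Probability vector of the same length as `x`.
#' @examples
#' chance_expectation(0:2)  # 0.5625 0.28125 0.10546875
#' @export
chance_expectation <- function(x) {
  if (any(x < 0) || any(x != floor(x))) {
    stop("homology length x must be a non-negative integer", call. = FALSE)
  }
  (x + 1) * (1 / 4)^x * (3 / 4)^2
}

#' Truncated chance distribution of microhomology lengths
#'
#' @param x_max Truncation point (largest explicit length bin).
#' @return A list of class `mh_chance` with `probabilities` (lengths
#'   `0..x_max`), `x_max` and `tail_mass` (probability of lengths
#'   `> x_max`); the entries and tail sum to 1.
#' @export
chance_distribution <- function(x_max) {
  stopifnot(x_max >= 0, x_max == floor(x_max))
  p <- chance_expectation(0:x_max)
  structure(list(probabilities = p, x_max = as.integer(x_max),
                 tail_mass = 1 - sum(p)),
            class = "mh_chance")
}

#' @export
print.mh_chance <- function(x, ...) {
  cat("<chance microhomology distribution> lengths 0..", x$x_max,
      ", tail mass ", signif(x$tail_mass, 4), "\n", sep = "")
  print(stats::setNames(round(x$probabilities, 6), 0:x$x_max))
  invisible(x)
}

#' Simulate a random-genomic-location deletion background
#'
#' Draws `n` deletions of fixed length at uniform random genomic
#' positions (chromosome chosen proportionally to the number of valid
#' start positions), to be scored with [score_microhomology()] exactly
#' like the observed set. In the study design the deletion length is set
#' to the mean length of the observed larger deletions.
#'
#' @param g An `mh_genome`.
#' @param n Number of simulated deletions.
#' @param length Deleted length in bp; must fit on at least one
#'   chromosome.
#' @param seed Integer seed; the draw is reproducible.
#' @return Deletions data.frame (`chrom`, `start`, `end`, `sample`,
#'   `modality`, `source`) with attributes `seed` and `length_used`.
#' @export
simulate_background <- function(g, n, length, seed) {
  stopifnot(inherits(g, "mh_genome"), n >= 1, length >= 1)
  lens <- seq_lengths(g)
  valid <- lens - length  # number of valid (start, start+length) placements
  usable <- valid > 0
  if (!any(usable)) {
    stop("deletion length ", length,
         " does not fit on any chromosome", call. = FALSE)
  }
  valid <- valid[usable]
  chroms <- names(valid)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ci <- sample.int(length(chroms), n, replace = TRUE,
                   prob = as.numeric(valid))
  start <- floor(stats::runif(n) * valid[ci])
  out <- data.frame(chrom = chroms[ci], start = as.integer(start),
                    end = as.integer(start) + as.integer(length),
                    sample = paste0("sim", seq_len(n)),
                    modality = "nuclease_1x", source = "pool",
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "length_used") <- as.integer(length)
  out
}

# save/restore .Random.seed so seeded helpers do not disturb the caller
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Chi-squared enrichment test of observed microhomology lengths
#'
#' Tests an observed length histogram against a null. When the null is
#' the analytic chance distribution the test is a chi-squared
#' goodness-of-fit; when it is a second finite sample (e.g. a simulated
#' background set) a two-sample chi-squared test of homogeneity is used
#' instead, so the null's own sampling noise is accounted for. Tail bins
#' are pooled so that every expected cell is at least `min_expected`;
#' when even two pooled cells cannot reach that bound in the
#' goodness-of-fit case, an exact binomial test on the two-cell table is
#' used (reported as `method = "exact_binomial"`).
#'
#' @param observed Integer vector of microhomology lengths, a scored
#'   table, or a histogram from [length_distribution()].
#' @param null An `mh_chance` object, or a second set of lengths /
#'   histogram used as the null (normalised to probabilities).
#' @param window Largest length bin considered (default 10).
#' @param min_expected Minimum expected cell count (default 5).
#' @return List with `statistic`, `p`, `method`, `observed_counts`,
#'   `expected_counts` and the pooled bin labels.
#' @export
enrichment_test <- function(observed, null, window = 10L, min_expected = 5) {
  obs <- as_length_counts(observed, window)
  if (sum(obs) < 1) stop("no observations", call. = FALSE)
  if (inherits(null, "mh_chance")) {
    if (null$x_max < window) {
      stop("null distribution truncated below window (bins mismatch)",
           call. = FALSE)
    }
    # fold all null mass beyond the window into the top bin
    p_all <- null$probabilities
    p0 <- p_all[1:(window + 1L)]
    extra <- if (null$x_max > window) {
      sum(p_all[(window + 2L):(null$x_max + 1L)])
    } else 0
    p0[window + 1L] <- p0[window + 1L] + extra + null$tail_mass
  } else {
    cnull <- as_length_counts(null, window)
    if (sum(cnull) < 1) stop("empty null histogram", call. = FALSE)
    # two-sample case: homogeneity test on the observed-vs-null table
    tab <- cbind(observed = obs, null = cnull)
    rownames(tab) <- as.character(0:window)
    tab <- pool_histogram_tail(tab, min_expected)
    keep <- rowSums(tab) > 0
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) < 2L) {
      stop("all observations in one pooled bin; chi-squared not defined",
           call. = FALSE)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(statistic = unname(ct$statistic), p = ct$p.value,
                method = "chi_squared_homogeneity",
                df = unname(ct$parameter),
                observed_counts = tab[, "observed"],
                expected_counts = ct$expected[, "observed"],
                labels = rownames(tab)))
  }
  labels <- as.character(0:window)
  # pool from the tail until expected cells reach min_expected
  n <- sum(obs)
  while (length(obs) > 2L && min(n * p0) < min_expected) {
    m <- length(obs)
    obs <- c(obs[seq_len(m - 2L)], obs[m - 1L] + obs[m])
    p0 <- c(p0[seq_len(m - 2L)], p0[m - 1L] + p0[m])
    labels <- c(labels[seq_len(m - 2L)], paste0(">=", labels[m - 1L]))
  }
  if (min(n * p0) < min_expected) {
    # two-cell small-sample fallback: exact binomial on the top cell
    pt <- stats::binom.test(obs[2L], n, p = p0[2L])
    return(list(statistic = NA_real_, p = pt$p.value,
                method = "exact_binomial", observed_counts = obs,
                expected_counts = n * p0, labels = labels))
  }
  zero <- p0 <= 0
  if (any(zero & obs > 0)) {
    stop("observed counts in bins with zero null mass", call. = FALSE)
  }
  stat <- sum((obs[!zero] - n * p0[!zero])^2 / (n * p0[!zero]))
  df <- sum(!zero) - 1L
  list(statistic = stat,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       method = "chi_squared", df = df, observed_counts = obs,
       expected_counts = n * p0, labels = labels)
}

# coerce lengths / scored table / length_distribution output to counts 0..window
as_length_counts <- function(x, window) {
  if (is.data.frame(x)) {
    if (all(c("length", "count") %in% names(x))) {
      if (any(x$length > window & x$count > 0)) {
        stop("histogram has mass above the requested window (bins mismatch)",
             call. = FALSE)
      }
      idx <- match(0:window, x$length)
      return(ifelse(is.na(idx), 0, x$count[idx]))
    }
    x <- x$mh_length
  }
  if (any(x < 0)) stop("negative lengths", call. = FALSE)
  if (any(x > window)) {
    stop("lengths above the requested window (bins mismatch)", call. = FALSE)
  }
  tabulate(x + 1L, nbins = window + 1L)
}
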