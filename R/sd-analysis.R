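# Short-amplicon (deep-sequencing) allele analysis: simple-deletion
# filtering, read-weighted microhomology scoring against the amplicon
# reference, insertion fractions, and the coverage-based background GC.

#' Filter alleles down to simple deletions
#'
#' A simple deletion spans one contiguous region and carries no
#' insertion and no mutation within 10 bp of the deletion. Only such
#' alleles are scored for junction microhomology. The filter is
#' idempotent.
#'
#' @param alleles Alleles table (see [read_tables()]), with logical
#'   `has_insertion` and `has_proximal_mutation` columns and `del_start`
#'   / `del_end` (`NA` when the allele has no deletion).
#' @return The subset of rows that are simple deletions.
#' @export
filter_simple_deletions <- function(alleles) {
  keep <- !is.na(alleles$del_start) & !is.na(alleles$del_end) &
    !alleles$has_insertion & !alleles$has_proximal_mutation
  alleles[keep, , drop = FALSE]
}

#' Score short-deletion microhomologies against an amplicon reference
#'
#' Applies the same junction scoring rule as for larger deletions, but
#' against a single amplicon sequence; results carry the allele read
#' counts as weights so distribution statistics can be read-weighted.
#'
#' @param alleles Simple-deletion alleles (from
#'   [filter_simple_deletions()]); rows with no deletion are an error.
#' @param amplicon_ref Amplicon reference DNA string.
#' @param window Scoring window (default 10 bp).
#' @return Scored data.frame with `mh_length`, `mh_seq`, `direction`,
#'   `gc_count` and `reads` columns.
#' @export
sd_microhomology <- function(alleles, amplicon_ref, window = 10L) {
  if (any(is.na(alleles$del_start) | is.na(alleles$del_end))) {
    stop("alleles without a deletion cannot be scored; run ",
         "filter_simple_deletions() first", call. = FALSE)
  }
  g <- genome(c(amplicon = amplicon_ref))
  dels <- data.frame(chrom = "amplicon", start = alleles$del_start,
                     end = alleles$del_end, stringsAsFactors = FALSE)
  scored <- score_microhomology(g, dels, window = window)
  out <- alleles
  out$mh_length <- scored$mh_length
  out$mh_seq <- scored$mh_seq
  out$direction <- scored$direction
  out$gc_count <- scored$gc_count
  out
}

#' Fraction of modified reads that contain an insertion
#'
#' Insertion-containing reads over all modified reads (reads carrying
#' any deletion, insertion or proximal mutation).
#'
#' @param alleles Alleles table with `modified`, `has_insertion` and
#'   `reads` columns.
#' @return A single fraction in `[0, 1]`.
#' @export
insertion_fraction <- function(alleles) {
  mod <- alleles$modified
  total <- sum(alleles$reads[mod])
  if (total == 0) stop("no modified reads", call. = FALSE)
  sum(alleles$reads[mod & alleles$has_insertion]) / total
}

#' Background GC content over the read-covered core of an amplicon
#'
#' Finds the smallest central contiguous interval holding at least
#' `coverage_fraction` of the total read mass — expanding symmetrically
#' outwards from the coverage-weighted median position — and returns the
#' GC fraction of the amplicon reference over that interval. In the
#' study design the fraction is 0.93-0.95 of the reads.
#'
#' @param coverage Numeric per-position read coverage, one value per
#'   amplicon base.
#' @param amplicon_ref Amplicon reference DNA string (same length).
#' @param coverage_fraction Fraction of read mass to cover, in `(0, 1]`
#'   (default 0.94).
#' @return List with `gc` (the background GC fraction), `start`, `end`
#'   (0-based half-open interval used) and `mass_fraction` achieved.
#' @export
background_gc <- function(coverage, amplicon_ref, coverage_fraction = 0.94) {
  if (!(coverage_fraction > 0 && coverage_fraction <= 1)) {
    stop("coverage_fraction must lie in (0, 1]", call. = FALSE)
  }
  L <- nchar(amplicon_ref)
  stopifnot(length(coverage) == L, all(coverage >= 0))
  total <- sum(coverage)
  if (total <= 0) stop("total coverage must be > 0", call. = FALSE)
  # coverage-weighted median position
  cum <- cumsum(coverage)
  med <- which(cum >= total / 2)[1L]
  lo <- med; hi <- med
  mass <- coverage[med]
  while (mass < coverage_fraction * total && (lo > 1L || hi < L)) {
    can_l <- lo > 1L; can_r <- hi < L
    take_left <- can_l &&
      (!can_r || coverage[lo - 1L] >= coverage[hi + 1L])
    if (take_left) {
      lo <- lo - 1L; mass <- mass + coverage[lo]
    } else {
      hi <- hi + 1L; mass <- mass + coverage[hi]
    }
  }
  core <- substr(amplicon_ref, lo, hi)
  list(gc = gc_count(core) / nchar(core), start = lo - 1L, end = hi,
       mass_fraction = mass / total)
}

#' Summary statistics bundle for a short-amplicon allele table
#'
#' Convenience wrapper: filters simple deletions, scores their
#' microhomologies (read-weighted), computes the insertion fraction and
#' the read-weighted length distribution.
#'
#' @param alleles Alleles table.
#' @param amplicon_ref Amplicon reference string.
#' @param window Scoring window.
#' @return List with `scored`, `length_distribution`,
#'   `insertion_fraction`, `n_alleles`, `n_simple`.
#' @export
sd_summary <- function(alleles, amplicon_ref, window = 10L) {
  simple <- filter_simple_deletions(alleles)
  scored <- if (nrow(simple)) {
    sd_microhomology(simple, amplicon_ref, window)
  } else simple
  ld <- length_distribution(
    if (nrow(simple)) scored$mh_length else integer(), window,
    weights = if (nrow(simple)) scored$reads else NULL)
  list(scored = scored, length_distribution = ld,
       insertion_fraction = insertion_fraction(alleles),
       n_alleles = nrow(alleles), n_simple = nrow(simple))
}
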