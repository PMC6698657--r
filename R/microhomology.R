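# Junction microhomology scoring.
#
# A deletion [start, end) creates a junction joining the retained sequence
# 5' of start to the retained sequence 3' of end. The junction
# microhomology is the contiguous run of positions j around the junction
# where genome[start + j] == genome[end + j]:
#
#   right part (k_right bases, j >= 0):
#     genome[start, start+k_right) == genome[end, end+k_right)
#     -- the first deleted bases equal the first retained bases after the
#        deletion, so the junction could equally sit further right;
#   left part (k_left bases, j < 0):
#     genome[start-k_left, start) == genome[end-k_left, end)
#     -- the retained bases before the deletion equal the last deleted
#        bases.
#
# The reported length is k_left + k_right: a single matched block
# straddling the junction, whose (length + 1) possible placements are
# exactly the deletions [start - k_left + j, end - k_left + j),
# j = 0..length, that all yield the same repaired sequence. Under a
# uniform-base null this total follows
# P(x) = (x + 1) (1/4)^x (3/4)^2, the chance law used by the null-model
# module. A mismatch (or any N) terminates each run; each side is
# searched up to `window` bp and truncated at contig edges, and the
# reported total is capped at `window`.

#' Extract the four 10-bp windows flanking a deletion junction
#'
#' For each deletion, returns the sequence immediately inside and outside
#' both breakpoints: `up_inside` (first bases of the deleted region),
#' `up_outside` (retained bases 5' of the upstream breakpoint),
#' `down_inside` (last bases of the deleted region) and `down_outside`
#' (retained bases 3' of the downstream breakpoint). Windows are truncated
#' (never padded) at contig edges, and the inside windows are additionally
#' capped by the deletion length. `up_outside` followed by `down_outside`
#' is the local sequence of the repaired junction.
#'
#' @param g An `mh_genome`.
#' @param deletions Deletions table (`chrom`, `start`, `end`, 0-based
#'   half-open), or any data.frame with those columns.
#' @param window Maximum window length in bp (default 10).
#' @return A data.frame with one row per deletion and the four window
#'   columns.
#' @export
junction_context <- function(g, deletions, window = 10L) {
  stopifnot(inherits(g, "mh_genome"), window >= 0)
  chrom <- deletions$chrom; start <- deletions$start; end <- deletions$end
  if (any(end - start < 1L)) {
    stop("deletion length must be >= 1 (row ",
         which(end - start < 1L)[1L], ")", call. = FALSE)
  }
  clen <- check_intervals(g, chrom, start, end, "deletion")
  seqs <- unclass(g)[chrom]
  len <- end - start
  w_in <- pmin(window, len)
  data.frame(
    chrom = chrom, start = start, end = end,
    up_inside = unname(substr(seqs, start + 1L, start + w_in)),
    up_outside = unname(substr(seqs, pmax(1L, start - window + 1L), start)),
    down_inside = unname(substr(seqs, end - w_in + 1L, end)),
    down_outside = unname(substr(seqs, end + 1L, pmin(clen, end + window))),
    stringsAsFactors = FALSE
  )
}

#' Score the microhomology at each deletion breakpoint junction
#'
#' Finds the contiguous block of identical bases straddling the junction
#' (left and right matched runs combined; see the package vignette for
#' the exact rule and its null distribution). Identity is exact: a
#' mismatch or an `N` terminates each run; each side is searched up to
#' `window` bp and the reported total is capped at `window`.
#'
#' @param g An `mh_genome`.
#' @param deletions Deletions table with `chrom`, `start`, `end` (0-based
#'   half-open); extra columns are carried through.
#' @param window Per-side search depth and cap on the reported length
#'   (default 10 bp).
#' @return The input table with columns `mh_length` (`k_left + k_right`,
#'   capped), `k_left`, `k_right`, `mh_seq` (the matched block,
#'   `genome[start - k_left, start - k_left + mh_length)`), `direction`
#'   (`right_extension` when the block lies entirely 3' of the junction,
#'   `left_extension` entirely 5', `spanning` when both parts are
#'   positive, `none` when empty) and `gc_count` appended.
#' @examples
#' g <- genome(c(c = "TTGCAAAAGCAGG"))
#' score_microhomology(g, data.frame(chrom = "c", start = 2, end = 8))
#' @export
score_microhomology <- function(g, deletions, window = 10L) {
  stopifnot(inherits(g, "mh_genome"), window >= 0)
  n <- nrow(deletions)
  chrom <- deletions$chrom
  start <- as.integer(deletions$start)
  end <- as.integer(deletions$end)
  if (n > 0 && any(end - start < 1L)) {
    stop("deletion length must be >= 1 (row ",
         which(end - start < 1L)[1L], ")", call. = FALSE)
  }
  clen <- if (n > 0) check_intervals(g, chrom, start, end, "deletion")
          else integer()
  seqs <- unclass(g)[chrom]

  kr <- integer(n); kl <- integer(n)
  alive_r <- rep(TRUE, n); alive_l <- rep(TRUE, n)
  if (window >= 1L && n > 0) {
    for (j in seq_len(window)) {
      # right: j-th deleted base vs j-th retained base after the deletion
      ok <- alive_r & end + j <= clen
      a <- substr(seqs, start + j, start + j)
      b <- substr(seqs, end + j, end + j)
      alive_r <- ok & a == b & a != "N"
      kr[alive_r] <- j
      # left: j-th retained base before vs j-th deleted base from the end
      ok <- alive_l & start - j >= 0L
      a <- substr(seqs, start - j + 1L, start - j + 1L)
      b <- substr(seqs, end - j + 1L, end - j + 1L)
      alive_l <- ok & a == b & a != "N"
      kl[alive_l] <- j
      if (!any(alive_r | alive_l)) break
    }
  }

  length_out <- pmin(kl + kr, as.integer(window))
  mh_seq <- unname(substr(seqs, start - kl + 1L, start - kl + length_out))
  mh_seq[length_out == 0L] <- ""
  direction <- rep("none", n)
  direction[kr > 0L & kl == 0L] <- "right_extension"
  direction[kl > 0L & kr == 0L] <- "left_extension"
  direction[kl > 0L & kr > 0L] <- "spanning"

  out <- deletions
  out$mh_length <- length_out
  out$k_left <- kl
  out$k_right <- kr
  out$mh_seq <- mh_seq
  out$direction <- direction
  out$gc_count <- gc_count(mh_seq)
  out
}

# number of G/C characters per string
gc_count <- function(x) {
  nchar(x) - nchar(gsub("[GCgc]", "", x))
}

#' Classify deletions relative to sgRNA target sites
#'
#' Applies the distance rules used throughout the pipeline:
#' * `ED` (expected-size deletion): both deletion ends reach at most
#'   `ed_max_beyond` bp (default 25) beyond the target site (protospacer
#'   plus PAM) of the nearest sgRNA;
#' * `LD` (larger deletion): either end lies more than `ld_min_distance`
#'   bp (default 200) from the sgRNA target sites and, when a primer
#'   table is given, the deletion removes at least one short-range (SR)
#'   primer binding site. With `mode = "literature"` the single rule
#'   "more than `lit_min_distance` bp (default 80) from a predicted cut
#'   site" is used instead;
#' * otherwise `other`.
#'
#' @param deletions Deletions table.
#' @param sgrnas sgRNA table (`chrom`, `proto_start`, `proto_end`,
#'   `pam_end`, `strand`, `cut_site`).
#' @param primers Optional primer table; only `tier == "SR"` rows are
#'   used for the ablation rule.
#' @param mode `"standard"` or `"literature"`.
#' @param ed_max_beyond,ld_min_distance,lit_min_distance Rule thresholds
#'   in bp.
#' @return The input table with `class`, `max_distance_to_sgrna` and
#'   `ablates_sr_primer` (logical, `NA` when no primer table was given)
#'   appended.
#' @export
classify_deletion <- function(deletions, sgrnas, primers = NULL,
                              mode = c("standard", "literature"),
                              ed_max_beyond = 25L, ld_min_distance = 200L,
                              lit_min_distance = 80L) {
  mode <- match.arg(mode)
  if (is.null(sgrnas) || nrow(sgrnas) == 0L) {
    stop("at least one sgRNA site is required for classification",
         call. = FALSE)
  }
  n <- nrow(deletions)
  # target site = protospacer extended to cover the PAM
  t_start <- pmin(sgrnas$proto_start, sgrnas$pam_end)
  t_end <- pmax(sgrnas$proto_end, sgrnas$pam_end + 1L)

  # distance from a point to the nearest target interval (0 if inside),
  # restricted to sgRNAs on the same chromosome
  dist_to_site <- function(chrom, pos, ref_start, ref_end, ref_chrom) {
    vapply(seq_along(pos), function(i) {
      j <- which(ref_chrom == chrom[i])
      if (!length(j)) return(Inf)
      d <- pmax(ref_start[j] - pos[i], pos[i] - ref_end[j], 0L)
      min(d)
    }, numeric(1))
  }

  d_up <- dist_to_site(deletions$chrom, deletions$start,
                       t_start, t_end, sgrnas$chrom)
  d_down <- dist_to_site(deletions$chrom, deletions$end,
                         t_start, t_end, sgrnas$chrom)
  max_dist <- pmax(d_up, d_down)

  ablates <- rep(NA, n)
  if (!is.null(primers)) {
    sr <- primers[primers$tier == "SR", , drop = FALSE]
    ablates <- vapply(seq_len(n), function(i) {
      j <- which(sr$chrom == deletions$chrom[i])
      any(sr$start[j] < deletions$end[i] & sr$end[j] > deletions$start[i])
    }, logical(1))
  }

  if (mode == "literature") {
    d_cut_up <- dist_to_site(deletions$chrom, deletions$start,
                             sgrnas$cut_site, sgrnas$cut_site, sgrnas$chrom)
    d_cut_down <- dist_to_site(deletions$chrom, deletions$end,
                               sgrnas$cut_site, sgrnas$cut_site, sgrnas$chrom)
    is_ld <- pmax(d_cut_up, d_cut_down) > lit_min_distance
    cls <- ifelse(is_ld, "LD", "other")
  } else {
    is_ed <- d_up <= ed_max_beyond & d_down <= ed_max_beyond
    far <- max_dist > ld_min_distance
    is_ld <- far & (if (is.null(primers)) TRUE else ablates)
    cls <- ifelse(is_ed, "ED", ifelse(is_ld, "LD", "other"))
  }

  out <- deletions
  out$class <- cls
  out$max_distance_to_sgrna <- max_dist
  out$ablates_sr_primer <- ablates
  out
}

#' Count alternative microhomologies inside a deleted sequence
#'
#' Counts exact occurrences (overlaps allowed) of the junction
#' microhomology motif strictly inside the deleted sequence. The single
#' inside copy of the motif that abuts the winning breakpoint — the copy
#' consumed by the repair — is subtracted, and occurrences overlapping
#' `excluded` (for paired-sgRNA designs, the interval between the two
#' cut sites) are not counted.
#'
#' @param g An `mh_genome`.
#' @param deletion One deletion: a list or one-row data.frame with
#'   `chrom`, `start`, `end`.
#' @param mh The corresponding scored result (one-row data.frame from
#'   [score_microhomology()], or a list with `mh_length`, `mh_seq`,
#'   `direction`).
#' @param excluded Optional excluded interval as `c(start, end)` (0-based
#'   half-open genomic coordinates on the deletion's chromosome).
#' @return Integer count of bypassed alternative microhomologies.
#' @export
count_alternative_microhomologies <- function(g, deletion, mh,
                                              excluded = NULL) {
  k <- as.integer(mh$mh_length)
  if (k == 0L) {
    warning("no junction microhomology to search for; returning 0")
    return(0L)
  }
  start <- as.integer(deletion$start); end <- as.integer(deletion$end)
  del_seq <- extract_interval(g, deletion$chrom, start, end)
  hits <- gregexpr(paste0("(?=", mh$mh_seq, ")"), del_seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(0L)
  offsets <- as.integer(hits) - 1L  # 0-based offsets within the deletion
  # drop the junction-consumed copy: a pure right extension uses the copy
  # at the start of the deleted region, a pure left extension the copy at
  # its end; a spanning block has no copy fully inside the deletion
  junction_offset <- switch(mh$direction,
    right_extension = 0L, left_extension = end - start - k, NULL)
  if (!is.null(junction_offset)) {
    offsets <- offsets[offsets != junction_offset]
  }
  if (!is.null(excluded)) {
    ex_lo <- as.integer(excluded[1L]) - start
    ex_hi <- as.integer(excluded[2L]) - start
    keep <- offsets + k <= ex_lo | offsets >= ex_hi
    offsets <- offsets[keep]
  }
  length(offsets)
}

#' Microhomology length distribution
#'
#' Tabulates exact microhomology lengths `0..window` with counts and
#' proportions, optionally weighting each observation (e.g. by read
#' count for short-amplicon alleles).
#'
#' @param lengths Integer vector of microhomology lengths, or a scored
#'   table from [score_microhomology()].
#' @param window Maximum length bin (default 10).
#' @param weights Optional non-negative observation weights.
#' @return A data.frame with `length`, `count` and `proportion`
#'   (proportions sum to 1 when any observation is present).
#' @export
length_distribution <- function(lengths, window = 10L, weights = NULL) {
  if (is.data.frame(lengths)) lengths <- lengths$mh_length
  if (is.null(weights)) weights <- rep(1, length(lengths))
  stopifnot(length(weights) == length(lengths), all(weights >= 0))
  if (length(lengths) && any(lengths < 0 | lengths > window)) {
    stop("lengths outside 0..window", call. = FALSE)
  }
  counts <- vapply(0:window, function(k) sum(weights[lengths == k]),
                   numeric(1))
  total <- sum(counts)
  data.frame(length = 0:window, count = counts,
             proportion = if (total > 0) counts / total else counts)
}
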