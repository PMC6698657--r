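#' Construct a genome object from named DNA strings
#'
#' A genome is a named character vector of uppercase DNA sequences
#' (alphabet `ACGTN`), one element per chromosome or contig. All
#' coordinates used against a genome in this package are 0-based
#' half-open intervals `[start, end)`.
#'
#' @param sequences Named character vector (or named list of single
#'   strings) mapping chromosome name to DNA sequence. `U` is mapped to
#'   `T` and case is normalised.
#' @return An object of class `mh_genome`.
#' @examples
#' g <- genome(c(chr1 = "acgtACGT"))
#' seq_lengths(g)
#' @export
genome <- function(sequences) {
  sequences <- unlist(sequences, use.names = TRUE)
  if (length(sequences) == 0L) {
    stop("genome must contain at least one sequence", call. = FALSE)
  }
  nms <- names(sequences)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("all genome sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("u", "t", sequences)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for chromosome(s): ",
         paste(nms[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("invalid DNA characters (not ACGTN/U) in chromosome(s): ",
         paste(nms[bad], collapse = ", "), call. = FALSE)
  }
  structure(seqs, class = "mh_genome")
}

#' Read a genome from a FASTA file
#'
#' Each FASTA record becomes one chromosome. Sequences are uppercased and
#' `U` is mapped to `T`; any character outside `ACGTN` is an error.
#'
#' @param path Path to a FASTA file.
#' @return An `mh_genome` object.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  # record ids: first whitespace-delimited token of the header
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  genome(seqs)
}

#' Write a genome to a FASTA file
#'
#' @param g An `mh_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "mh_genome"))
  set <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param g An `mh_genome`.
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(g) {
  stopifnot(inherits(g, "mh_genome"))
  stats::setNames(nchar(unclass(g)), names(g))
}

#' @export
print.mh_genome <- function(x, ...) {
  cat("<mh_genome> ", length(x), " sequence(s), ",
      format(sum(nchar(unclass(x))), big.mark = ","), " bp total\n", sep = "")
  lens <- seq_lengths(x)
  show <- utils::head(lens, 6L)
  for (nm in names(show)) cat("  ", nm, ": ", show[[nm]], " bp\n", sep = "")
  if (length(lens) > 6L) cat("  ...\n")
  invisible(x)
}

# internal: validate chrom/start/end against a genome, vectorised.
# start/end are 0-based half-open. Returns chromosome lengths per row.
check_intervals <- function(g, chrom, start, end, what = "interval") {
  unknown <- !(chrom %in% names(g))
  if (any(unknown)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[unknown]), collapse = ", "), call. = FALSE)
  }
  clen <- unname(nchar(unclass(g))[match(chrom, names(g))])
  bad <- !(start >= 0L & start < end & end <= clen)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(what, " out of bounds at row ", i, ": ", chrom[i], ":[", start[i],
         ", ", end[i], ") on a ", clen[i], " bp sequence", call. = FALSE)
  }
  clen
}

#' Extract plus-strand sequence for genomic intervals
#'
#' Coordinates are 0-based half-open; the returned string always has
#' exactly `end - start` characters. Vectorised over `chrom`, `start`
#' and `end`.
#'
#' @param g An `mh_genome`.
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open interval bounds.
#' @return Character vector of extracted sequences.
#' @examples
#' g <- genome(c(c = "AACCGGTT"))
#' extract_interval(g, "c", 2, 6)  # "CCGG"
#' @export
extract_interval <- function(g, chrom, start, end) {
  stopifnot(inherits(g, "mh_genome"))
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n)
  check_intervals(g, chrom, start, end)
  unname(substr(unclass(g)[chrom], start + 1L, end))
}
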