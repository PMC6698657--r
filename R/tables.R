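# Table schemas shared by the whole pipeline. All genomic coordinates are
# stored 0-based half-open; input files may declare
#   # coord=1-based-inclusive
# on their first line and are converted once, at parse time.

MODALITIES <- c("nuclease_1x", "nuclease_2x", "nickase_4x", "mRNA_embryo",
                "literature")
SOURCES <- c("clone", "pool", "animal")
PRIMER_TIERS <- c("SR", "MR", "LR")

table_schemas <- function() {
  list(
    deletions = list(
      required = c("chrom", "start", "end", "sample", "modality", "source"),
      integer = c("start", "end")),
    sgrnas = list(
      required = c("chrom", "proto_start", "proto_end", "pam_end", "strand",
                   "cut_site"),
      integer = c("proto_start", "proto_end", "pam_end", "cut_site")),
    primers = list(
      required = c("chrom", "start", "end", "tier"),
      integer = c("start", "end")),
    ddpcr = list(
      required = c("sample", "chrom", "amplicon_mid", "rel_conc",
                   "control_conc"),
      integer = "amplicon_mid"),
    alleles = list(
      required = c("sample", "allele_seq", "del_start", "del_end",
                   "has_insertion", "reads"),
      integer = c("del_start", "del_end", "reads"))
  )
}

#' Read a typed pipeline table from TSV
#'
#' Supported schemas: `deletions`, `sgrnas`, `primers`, `ddpcr`, `alleles`
#' (see Details for columns). Files may carry a first-line pragma
#' `# coord=1-based-inclusive`, in which case start-type coordinates are
#' shifted to the package's internal 0-based half-open convention during
#' parsing.
#'
#' @details Column sets:
#' * `deletions`: chrom, start, end, sample, modality, source
#' * `sgrnas`: chrom, proto_start, proto_end, pam_end, strand, cut_site
#' * `primers`: chrom, start, end, tier
#' * `ddpcr`: sample, chrom, amplicon_mid, rel_conc, control_conc
#' * `alleles`: sample, allele_seq, del_start, del_end, has_insertion, reads
#'   (optional: has_proximal_mutation, modified)
#'
#' For `alleles`, `del_start`/`del_end` may be `NA` (no deletion in that
#' allele); `modified` defaults to "has a deletion, insertion or proximal
#' mutation" when absent.
#'
#' @param path TSV file path.
#' @param schema One of the schema names above.
#' @return A `data.frame` with validated, typed columns.
#' @export
read_tables <- function(path, schema = c("deletions", "sgrnas", "primers",
                                         "ddpcr", "alleles")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  one_based <- length(first) == 1L &&
    grepl("^#\\s*coord\\s*=\\s*1-based-inclusive", first)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  validate_table(df, schema, one_based = one_based, file = path)
}

# shared validator so in-memory tables get the same checks as files
validate_table <- function(df, schema, one_based = FALSE, file = NULL) {
  sch <- table_schemas()[[schema]]
  where <- if (is.null(file)) "" else paste0(" in ", file)
  missing <- setdiff(sch$required, names(df))
  if (length(missing)) {
    stop("schema '", schema, "'", where, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in sch$integer) {
    v <- df[[col]]
    if (schema == "alleles" && col %in% c("del_start", "del_end")) {
      suppressWarnings(iv <- as.integer(v))
      bad <- !is.na(v) & v != "" & is.na(iv)
    } else {
      suppressWarnings(iv <- as.integer(v))
      bad <- is.na(iv)
    }
    if (any(bad)) {
      stop("non-integer value in column '", col, "'", where, " at row ",
           which(bad)[1L], call. = FALSE)
    }
    df[[col]] <- iv
  }
  if (one_based) {
    shift <- switch(schema,
      deletions = "start", sgrnas = c("proto_start", "cut_site"),
      primers = "start", ddpcr = character(), alleles = "del_start")
    for (col in shift) df[[col]] <- df[[col]] - 1L
    # pam_end / amplicon_mid are point coordinates: 1-based -> 0-based
    if (schema == "sgrnas") df$pam_end <- df$pam_end - 1L
    if (schema == "ddpcr") df$amplicon_mid <- df$amplicon_mid - 1L
  }
  err_row <- function(bad, msg) {
    if (any(bad)) {
      stop(msg, where, " at row ", which(bad)[1L], call. = FALSE)
    }
  }
  if (schema == "deletions") {
    err_row(df$start >= df$end, "deletion with start >= end")
    err_row(df$start < 0, "negative coordinate")
    err_row(!(df$modality %in% MODALITIES),
            paste0("modality not one of {",
                   paste(MODALITIES, collapse = ", "), "}"))
    err_row(!(df$source %in% SOURCES),
            paste0("source not one of {", paste(SOURCES, collapse = ", "),
                   "}"))
  } else if (schema == "sgrnas") {
    err_row(df$proto_start >= df$proto_end, "protospacer with start >= end")
    err_row(!(df$strand %in% c("+", "-")), "strand not one of {+, -}")
    err_row(df$cut_site < df$proto_start - 1L | df$cut_site > df$proto_end + 1L,
            "cut_site not within or adjacent to protospacer")
    pam_gap <- pmin(abs(df$pam_end - df$proto_start),
                    abs(df$pam_end - df$proto_end))
    err_row(pam_gap < 3L | pam_gap > 6L,
            "pam_end not within 3-6 bp of a protospacer edge")
  } else if (schema == "primers") {
    err_row(df$start >= df$end, "primer with start >= end")
    err_row(!(df$tier %in% PRIMER_TIERS),
            paste0("tier not one of {", paste(PRIMER_TIERS, collapse = ", "),
                   "}"))
  } else if (schema == "ddpcr") {
    df$rel_conc <- as.numeric(df$rel_conc)
    df$control_conc <- as.numeric(df$control_conc)
    err_row(!is.finite(df$rel_conc) | df$rel_conc < 0,
            "rel_conc not a non-negative number")
    err_row(!is.finite(df$control_conc) | df$control_conc <= 0,
            "control_conc must be > 0 (it divides the sample concentration)")
  } else if (schema == "alleles") {
    df$has_insertion <- as_flag(df$has_insertion, "has_insertion", where)
    if (!"has_proximal_mutation" %in% names(df)) {
      df$has_proximal_mutation <- FALSE
    } else {
      df$has_proximal_mutation <- as_flag(df$has_proximal_mutation,
                                          "has_proximal_mutation", where)
    }
    has_del <- !is.na(df$del_start)
    err_row(has_del != !is.na(df$del_end),
            "del_start and del_end must both be present or both absent")
    err_row(has_del & df$del_start >= df$del_end,
            "deletion with del_start >= del_end")
    err_row(df$reads < 1L, "reads must be >= 1")
    if (!"modified" %in% names(df)) {
      df$modified <- has_del | df$has_insertion | df$has_proximal_mutation
    } else {
      df$modified <- as_flag(df$modified, "modified", where)
      err_row(has_del & !df$modified, "allele with a deletion marked unmodified")
    }
  }
  df
}

as_flag <- function(v, col, where) {
  if (is.logical(v)) return(v)
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "True", "true", "1", 1)] <- TRUE
  out[v %in% c("FALSE", "False", "false", "0", 0)] <- FALSE
  if (anyNA(out)) {
    stop("column '", col, "'", where, " is not interpretable as TRUE/FALSE ",
         "at row ", which(is.na(out))[1L], call. = FALSE)
  }
  out
}

#' Write a pipeline table to TSV
#'
#' Written tables round-trip: re-reading with [read_tables()] under the
#' same schema yields identical records (0-based half-open coordinates,
#' no pragma emitted).
#'
#' @param df Table as returned by [read_tables()] or built in code.
#' @param path Output path.
#' @param schema Schema name; the table is validated before writing.
#' @return `path`, invisibly.
#' @export
write_tables <- function(df, path, schema = c("deletions", "sgrnas",
                                              "primers", "ddpcr", "alleles")) {
  schema <- match.arg(schema)
  df <- validate_table(df, schema)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export deletions as 6-column BED
#'
#' BED uses the same 0-based half-open convention as the package. `name`
#' is the sample id; `score` is the junction microhomology length when a
#' scored table is supplied (0 otherwise); strand is `.`.
#'
#' @param deletions Deletions table, optionally carrying an `mh_length`
#'   column from [score_microhomology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(deletions, path) {
  score <- if ("mh_length" %in% names(deletions)) deletions$mh_length else 0L
  bed <- data.frame(chrom = deletions$chrom, start = deletions$start,
                    end = deletions$end, name = deletions$sample,
                    score = score, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
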