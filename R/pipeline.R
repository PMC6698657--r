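# End-to-end orchestration: generate or load inputs, score junctions,
# run both nulls, enrichment and GC-bias tests, short-deletion
# statistics and the ddPCR regression, writing TSV/JSON artifacts.

#' Run the full junction-microhomology analysis
#'
#' Composes the pipeline stages over a set of input tables (or, when
#' `config$simulate` is `TRUE`, over synthetic data generated under
#' `config$sim`): junction scoring and length histogram, chance and
#' simulated-background nulls with enrichment tests, GC-bias test,
#' short-amplicon summary, and the log-distance frequency model with
#' diagnostics and the +/- 3 kb allele-frequency profile. Every table
#' has a TSV twin on disk and the scalar results are serialised to
#' JSON; reruns with the same seed are byte-identical.
#'
#' @param config A list: either `simulate = TRUE` with a `sim`
#'   ([sim_config()]) entry, or paths `genome`, `deletions`, `sgrnas`
#'   (optional `primers`, `ddpcr`, `alleles`, `amplicon`). Optional
#'   entries: `window` (default 10), `seed` (default 1), `n_background`
#'   (default: number of observed deletions), `background_gc` (default:
#'   genome-wide GC of the reference).
#' @param outdir Output directory, created if missing.
#' @return Invisibly, the report list (also written to
#'   `summary.json`).
#' @export
run_full_analysis <- function(config, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  window <- config$window %||% 10L
  seed <- as.integer(config$seed %||% 1L)
  log_lines <- c(paste0("mhjunction ",
                        as.character(utils::packageVersion("mhjunction"))),
                 paste0("seed ", seed))

  if (isTRUE(config$simulate)) {
    cfg <- config$sim %||% sim_config(seed = seed)
    g <- generate_genome(cfg$genome_length, cfg$gc, seed = cfg$seed)
    cut <- as.integer(cfg$genome_length / 2)
    sim <- simulate_repair_alleles(g, cut, cfg)
    deletions <- sim$deletions
    alleles <- sim$alleles
    dd <- simulate_ddpcr(cfg)
    ddpcr <- dd$ddpcr
    sgrnas <- data.frame(chrom = names(g)[1L],
                         proto_start = cut - 17L, proto_end = cut + 3L,
                         pam_end = cut + 6L, strand = "+", cut_site = cut,
                         stringsAsFactors = FALSE)
    # ddPCR amplicons in the simulated table sit around their own midpoint
    sg_ddpcr <- data.frame(chrom = "chrS", proto_start = dd$sg_mid - 10L,
                           proto_end = dd$sg_mid + 10L,
                           pam_end = dd$sg_mid + 13L, strand = "+",
                           cut_site = dd$sg_mid, stringsAsFactors = FALSE)
    amplicon_ref <- extract_interval(g, names(g)[1L],
                                     max(0L, cut - 112L), cut + 113L)
    write_genome(g, file.path(outdir, "genome.fa"))
    log_lines <- c(log_lines, paste0("simulated inputs, generator seed ",
                                     cfg$seed))
  } else {
    g <- read_genome(config$genome)
    deletions <- read_tables(config$deletions, "deletions")
    sgrnas <- read_tables(config$sgrnas, "sgrnas")
    sg_ddpcr <- sgrnas
    alleles <- if (!is.null(config$alleles)) {
      read_tables(config$alleles, "alleles")
    }
    ddpcr <- if (!is.null(config$ddpcr)) read_tables(config$ddpcr, "ddpcr")
    amplicon_ref <- if (!is.null(config$amplicon)) {
      unclass(read_genome(config$amplicon))[[1L]]
    }
    cfg <- NULL
  }
  primers <- if (!is.null(config$primers)) {
    read_tables(config$primers, "primers")
  }

  report <- list(seed = seed, window = window)

  # --- junction scoring -------------------------------------------------
  scored <- score_microhomology(g, deletions, window = window)
  if (!is.null(sgrnas) && nrow(sgrnas)) {
    scored <- classify_deletion(scored, sgrnas, primers)
  }
  write_scored(scored, file.path(outdir, "scored_deletions.tsv"))
  hist_obs <- length_distribution(scored$mh_length, window)
  utils::write.table(hist_obs, file.path(outdir, "mh_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- nulls and enrichment --------------------------------------------
  chance <- chance_distribution(window)
  mean_len <- max(1L, as.integer(round(mean(scored$end - scored$start))))
  n_bg <- config$n_background %||% nrow(scored)
  bg <- simulate_background(g, n_bg, mean_len, seed = seed)
  bg_scored <- score_microhomology(g, bg, window = window)
  utils::write.table(
    length_distribution(bg_scored$mh_length, window),
    file.path(outdir, "background_histogram.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  report$enrichment_vs_chance <-
    strip_tables(enrichment_test(scored$mh_length, chance, window))
  report$enrichment_vs_background <-
    strip_tables(enrichment_test(scored$mh_length, bg_scored$mh_length,
                                 window))
  report$background_length_used <- mean_len

  # --- GC bias ----------------------------------------------------------
  bgc <- config$background_gc %||%
    (gc_count(paste(unclass(g), collapse = "")) /
       sum(nchar(unclass(g))))
  gc_res <- gc_bias_test(scored, bgc, stratify_by_length = TRUE)
  utils::write.table(gc_res$by_length, file.path(outdir, "gc_bias.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$background_gc <- bgc
  report$gc_bias_pooled <- as.list(gc_res$pooled)

  # --- short-amplicon analysis -----------------------------------------
  if (!is.null(alleles) && !is.null(amplicon_ref) && nrow(alleles)) {
    sd_alleles <- alleles
    if (isTRUE(config$simulate)) {
      # re-express genomic deletion coordinates in amplicon space, keeping
      # only alleles whose deletion lies inside the amplicon
      amp_start <- max(0L, as.integer(cfg$genome_length / 2) - 112L)
      sd_alleles$del_start <- sd_alleles$del_start - amp_start
      sd_alleles$del_end <- sd_alleles$del_end - amp_start
      inside <- !is.na(sd_alleles$del_start) & sd_alleles$del_start >= 0 &
        sd_alleles$del_end <= nchar(amplicon_ref)
      sd_alleles <- sd_alleles[inside, , drop = FALSE]
    }
    if (nrow(sd_alleles)) {
      sdres <- sd_summary(sd_alleles, amplicon_ref, window)
      utils::write.table(sdres$length_distribution,
                         file.path(outdir, "sd_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$sd <- list(insertion_fraction = sdres$insertion_fraction,
                        n_alleles = sdres$n_alleles,
                        n_simple = sdres$n_simple)
    }
  }

  # --- ddPCR regression -------------------------------------------------
  if (!is.null(ddpcr) && nrow(ddpcr)) {
    pts <- ddpcr_to_points(ddpcr, sg_ddpcr)
    fit <- fit_ld_model(pts)
    diag <- diagnose_fit(fit)
    prof <- allele_frequency_profile(fit, step = 50L)
    utils::write.table(prof, file.path(outdir, "allele_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p250 <- predict_frequency(fit, 250)
    report$ld_model <- list(
      b0 = fit$b0, b1 = fit$b1, b2 = fit$b2, n = fit$n,
      r2 = fit$r2, adjusted_r2 = fit$adjusted_r2,
      residual_normality_p = diag$normality_p,
      predicted_frequency_250bp = p250$estimate,
      predicted_frequency_250bp_ci = c(p250$lower, p250$upper))
  }

  jsonlite::write_json(report, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(report)
}

write_scored <- function(scored, path) {
  utils::write.table(scored, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

strip_tables <- function(x) {
  x[c("statistic", "p", "method")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
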