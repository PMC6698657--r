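# Synthetic-data generators. These define the study conditions used in
# the package's own validation: i.i.d. genomes of tunable GC, repair
# outcome allele sets with controllable MMEJ / NHEJ / insertion
# structure, and ddPCR-style frequency tables drawn from the
# log-distance model.

#' Default simulation configuration
#'
#' Collects every tunable generator parameter in one list. Defaults
#' mirror the experimental regime the pipeline targets: a handful of
#' cut sites on a ~200 kb locus, MMEJ favouring 2-5 bp microhomologies,
#' a resection radius matching the 3 kb profile window, an efficiency
#' range typical of selected pools, and a deletion-frequency model that
#' deletes roughly a quarter of alleles 250 bp from the cut at average
#' efficiency, decays to near zero by 3 kb, and approaches the cutting
#' efficiency at the cut itself.
#'
#' @param genome_length Genome length in bp.
#' @param gc Genome GC fraction.
#' @param seed Integer seed.
#' @param p_mmej Probability that a repair event resolves by MMEJ
#'   (deleting between a sampled microhomology pair); the remainder are
#'   NHEJ-style small indels.
#' @param mh_length_weights Unnormalised sampling weights over
#'   microhomology lengths 1..10 for MMEJ events.
#' @param gc_pull Multiplicative preference (`>= 0`) per G/C base when
#'   accepting a candidate microhomology; 1 = no GC bias.
#' @param p_insertion Probability that an allele carries a 1-10 bp
#'   insertion.
#' @param max_resection Maximum distance (bp) from the cut site at
#'   which a microhomology copy may sit.
#' @param nhej_max_del Maximum NHEJ deletion size (bp).
#' @param ld_b0,ld_b1,ld_b2 Coefficients of the deletion-frequency model
#'   `freq = b0 + b1 log(distance) + b2 efficiency`.
#' @param noise_sd Gaussian noise SD on simulated frequencies.
#' @param efficiency_range Range the per-sample cutting efficiency is
#'   drawn from (uniform).
#' @param read_geom_prob Geometric-distribution parameter of per-allele
#'   read counts.
#' @param n_alleles Alleles per simulated cut site.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, gc = 0.5, seed = 1L,
                       p_mmej = 0.7,
                       mh_length_weights = c(0, 1, 2, 2, 1, rep(0, 5)),
                       gc_pull = 1, p_insertion = 0.1,
                       max_resection = 3000L, nhej_max_del = 25L,
                       ld_b0 = 0.62, ld_b1 = -0.10, ld_b2 = 0.30,
                       noise_sd = 0.02,
                       efficiency_range = c(0.4, 0.9),
                       read_geom_prob = 0.05, n_alleles = 100L) {
  stopifnot(gc >= 0, gc <= 1, p_mmej >= 0, p_mmej <= 1,
            p_insertion >= 0, p_insertion <= 1,
            length(mh_length_weights) == 10L,
            all(mh_length_weights >= 0), any(mh_length_weights > 0),
            gc_pull >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`; the draw is reproducible given the seed.
#'
#' @param length Genome length in bp (`>= 100`).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param chrom Chromosome name for the single generated sequence.
#' @return An `mh_genome` with one chromosome.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, chrom = "chrS") {
  if (!(gc >= 0 && gc <= 1)) stop("gc must lie in [0, 1]", call. = FALSE)
  stopifnot(length >= 100)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  g <- paste(bases, collapse = "")
  genome(stats::setNames(g, chrom))
}

# sample one MMEJ deletion around a cut: pick a homology length k from the
# configured weights, a left copy position, and a matching right copy
# found by exact search; returns c(start, end, k) or NULL on failure.
sample_mmej_deletion <- function(seq, cut, cfg) {
  w <- cfg$mh_length_weights
  ks <- which(w > 0)
  for (attempt in 1:50) {
    k <- ks[sample.int(length(ks), 1L, prob = w[ks])]
    # left copy fully within [cut - max_resection, cut)
    lo <- max(1L, cut - cfg$max_resection)
    if (cut - k < lo) next
    i <- lo + sample.int(cut - k - lo + 1L, 1L) - 1L  # 1-based copy start
    motif <- substr(seq, i, i + k - 1L)
    if (grepl("N", motif, fixed = TRUE)) next
    # GC preference: accept with prob gc_pull^gc_bases, normalised by the
    # largest weight attainable for a k-mer
    wgt <- cfg$gc_pull^gc_count(motif)
    if (stats::runif(1) > wgt / max(1, cfg$gc_pull^k)) next
    # right copy strictly after the cut, within resection radius
    hi <- min(nchar(seq) - k + 1L, cut + cfg$max_resection)
    if (hi <= cut) next
    region <- substr(seq, cut + 1L, hi + k - 1L)
    hits <- gregexpr(paste0("(?=", motif, ")"), region, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    j <- cut + as.integer(hits[sample.int(length(hits), 1L)])  # 1-based
    # annealing at the two copies deletes [i-1, j-1) (0-based half-open):
    # the left copy is consumed, the right copy survives at the junction
    start0 <- i - 1L
    end0 <- j - 1L
    if (end0 - start0 < 1L) next
    # require the cut inside the deleted interval
    if (!(start0 < cut && cut <= end0)) next
    return(c(start0, end0, k))
  }
  NULL
}

#' Simulate repair-outcome alleles at a cut site
#'
#' Draws `cfg$n_alleles` repair outcomes at one double-strand-break
#' position. With probability `p_mmej` an allele resolves by MMEJ: a
#' microhomology pair flanking the cut is sampled (length from
#' `mh_length_weights`, composition biased by `gc_pull`) and the
#' sequence between the two copies, plus one copy, is deleted — so
#' re-scoring the emitted deletion recovers a junction microhomology at
#' least as long as the sampled one. Otherwise the allele is an
#' NHEJ-style small deletion (1..`nhej_max_del` bp spanning the cut).
#' Independently, with probability `p_insertion` the allele carries a
#' short insertion. Read counts are geometric.
#'
#' @param g An `mh_genome`.
#' @param cut_site 0-based between-base cut position (must leave
#'   `max_resection` headroom inside the chromosome where possible).
#' @param cfg A [sim_config()].
#' @param chrom Chromosome to cut (default the first).
#' @return List with `alleles` (alleles-schema table), `deletions`
#'   (deletions-schema table) and `mh_sampled` (the intended
#'   microhomology length per allele, `NA` for NHEJ).
#' @export
simulate_repair_alleles <- function(g, cut_site, cfg = sim_config(),
                                    chrom = names(g)[1L]) {
  stopifnot(inherits(g, "mh_genome"), inherits(cfg, "sim_config"))
  seq <- unclass(g)[[chrom]]
  L <- nchar(seq)
  cut <- as.integer(cut_site)
  if (cut < 10L || cut > L - 10L) {
    stop("cut_site must leave at least 10 bp on each side", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(cfg$seed))

  n <- cfg$n_alleles
  starts <- integer(n); ends <- integer(n); sampled_k <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    mmej <- stats::runif(1) < cfg$p_mmej
    placed <- FALSE
    if (mmej) {
      d <- sample_mmej_deletion(seq, cut, cfg)
      if (!is.null(d)) {
        starts[i] <- d[1L]; ends[i] <- d[2L]; sampled_k[i] <- d[3L]
        placed <- TRUE
      }
    }
    if (!placed) {
      # NHEJ: small deletion spanning the cut
      dlen <- sample.int(cfg$nhej_max_del, 1L)
      off <- sample.int(dlen, 1L) - 1L  # deleted bases before the cut
      s <- max(0L, min(cut - off, L - dlen))
      starts[i] <- s; ends[i] <- s + dlen
    }
  }
  has_ins <- stats::runif(n) < cfg$p_insertion
  reads <- stats::rgeom(n, cfg$read_geom_prob) + 1L
  sample_id <- paste0("allele", seq_len(n))
  alleles <- data.frame(
    sample = sample_id,
    allele_seq = ".",
    del_start = starts, del_end = ends,
    has_insertion = has_ins,
    has_proximal_mutation = FALSE,
    reads = reads,
    modified = TRUE,
    stringsAsFactors = FALSE)
  deletions <- data.frame(
    chrom = chrom, start = starts, end = ends, sample = sample_id,
    modality = "nuclease_1x", source = "pool", stringsAsFactors = FALSE)
  list(alleles = alleles, deletions = deletions, mh_sampled = sampled_k,
       cut_site = cut, seed = cfg$seed)
}

#' Simulate a ddPCR deletion-frequency table
#'
#' For each sample an efficiency is drawn uniformly from
#' `cfg$efficiency_range`; at every requested distance the true deletion
#' frequency `b0 + b1 log(x) + b2 a` plus Gaussian noise (clipped to
#' `[0, 1]`) is converted to sample/control concentrations consistent
#' with the one-minus-ratio frequency definition (control fixed at 1).
#' One extra amplicon per sample is placed directly on the sgRNA
#' midpoint carrying the sample's efficiency, so
#' [ddpcr_to_points()] can recover it.
#'
#' @param cfg A [sim_config()].
#' @param distances Amplicon distances in bp (`> 0`).
#' @param samples Number of samples.
#' @param sg_mid 0-based sgRNA midpoint position used for amplicon
#'   placement (default 50000).
#' @param chrom Chromosome name written in the table.
#' @return List with `ddpcr` (ddpcr-schema table), `truth` (per-sample
#'   efficiency) and `points` (the noiseless design).
#' @export
simulate_ddpcr <- function(cfg = sim_config(),
                           distances = c(250, 500, 750, 1000, 1500),
                           samples = 8L, sg_mid = 50000L, chrom = "chrS") {
  stopifnot(inherits(cfg, "sim_config"), all(distances > 0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(cfg$seed))
  eff <- stats::runif(samples, cfg$efficiency_range[1L],
                      cfg$efficiency_range[2L])
  rows <- list()
  for (s in seq_len(samples)) {
    sid <- paste0("s", s)
    # response amplicons
    f <- cfg$ld_b0 + cfg$ld_b1 * log(distances) + cfg$ld_b2 * eff[s] +
      stats::rnorm(length(distances), 0, cfg$noise_sd)
    f <- pmin(1, pmax(0, f))
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sid, chrom = chrom,
      amplicon_mid = as.integer(sg_mid + distances),
      rel_conc = 1 - f, control_conc = 1, stringsAsFactors = FALSE)
    # efficiency amplicon at the sgRNA midpoint
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sid, chrom = chrom, amplicon_mid = as.integer(sg_mid),
      rel_conc = 1 - eff[s], control_conc = 1, stringsAsFactors = FALSE)
  }
  ddpcr <- do.call(rbind, rows)
  list(ddpcr = ddpcr,
       truth = data.frame(sample = paste0("s", seq_len(samples)),
                          efficiency = eff),
       coefficients = c(b0 = cfg$ld_b0, b1 = cfg$ld_b1, b2 = cfg$ld_b2),
       sg_mid = sg_mid, seed = cfg$seed)
}
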