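test_that("junction context windows tile the reference and truncate at edges", {
  g <- genome(c(c = "TTGCAAAAGCAGG"))
  ctx <- junction_context(g, data.frame(chrom = "c", start = 2, end = 8))
  expect_identical(ctx$up_inside, "GCAAAA")   # first min(10, 6) deleted bases
  expect_identical(ctx$up_outside, "TT")      # truncated at the contig start
  expect_identical(ctx$down_inside, "GCAAAA")
  expect_identical(ctx$down_outside, "GCAGG")
  # outside windows concatenate to the repaired junction's local sequence
  expect_identical(paste0(ctx$up_outside, ctx$down_outside), "TTGCAGG")
  # deletion at position 0: no upstream flank at all
  ctx0 <- junction_context(g, data.frame(chrom = "c", start = 0, end = 3))
  expect_identical(ctx0$up_outside, "")
  # window 0 empties every field
  ctxw <- junction_context(g, data.frame(chrom = "c", start = 2, end = 8),
                           window = 0)
  expect_identical(unlist(ctxw[, c("up_inside", "up_outside", "down_inside",
                                   "down_outside")], use.names = FALSE),
                   rep("", 4))
})

test_that("scoring matches spec'd worked cases", {
  g <- genome(c(c = "AAAACCCC"))
  r <- score_microhomology(g, data.frame(chrom = "c", start = 2, end = 6))
  expect_equal(r$mh_length, 0L)
  expect_identical(r$direction, "none")
  expect_identical(r$mh_seq, "")

  g <- genome(c(c = "TTGCAAAAGCAGG"))
  r <- score_microhomology(g, data.frame(chrom = "c", start = 2, end = 8))
  expect_equal(r$mh_length, 3L)
  expect_identical(r$mh_seq, "GCA")
  expect_identical(r$direction, "right_extension")
  expect_equal(r$gc_count, 2L)

  # homopolymer: capped at the window
  g <- genome(c(c = strrep("A", 30)))
  r <- score_microhomology(g, data.frame(chrom = "c", start = 5, end = 20))
  expect_equal(r$mh_length, 10L)
  expect_identical(r$mh_seq, strrep("A", 10))

  # window 0 always returns length 0
  r0 <- score_microhomology(g, data.frame(chrom = "c", start = 5, end = 20),
                            window = 0)
  expect_equal(r0$mh_length, 0L)

  # N never matches, even against another N
  g <- genome(c(c = "CANTTTTGNATT"))
  r <- score_microhomology(g, data.frame(chrom = "c", start = 2, end = 9),
                           window = 10)
  expect_equal(r$mh_length, 0L)
})

test_that("vectorised scorer agrees with the brute-force oracle on random cases", {
  set.seed(11)
  cases <- random_scoring_cases(300)
  for (cs in cases) {
    g <- genome(c(chr = paste(cs$chars, collapse = "")))
    got <- score_microhomology(
      g, data.frame(chrom = "chr", start = cs$start, end = cs$end))
    want <- oracle_score(cs$chars, cs$start, cs$end)
    expect_equal(got$mh_length, want$length,
                 info = sprintf("del [%d,%d)", cs$start, cs$end))
    expect_identical(got$mh_seq, want$seq)
    expect_identical(got$direction, want$direction)
  }
})

test_that("a right-extension of length k makes the junction k-fold ambiguous", {
  set.seed(23)
  found <- 0L
  while (found < 25L) {
    chars <- random_genome_chars(120)
    g <- genome(c(chr = paste(chars, collapse = "")))
    start <- sample(20:60, 1); end <- start + sample(10:40, 1)
    r <- score_microhomology(g, data.frame(chrom = "chr", start = start,
                                           end = end))
    if (r$direction != "right_extension" || r$mh_length < 1) next
    found <- found + 1L
    ref <- paste(chars, collapse = "")
    repaired0 <- paste0(substr(ref, 1, start), substr(ref, end + 1, 120))
    for (j in seq_len(r$mh_length)) {
      repaired_j <- paste0(substr(ref, 1, start + j),
                           substr(ref, end + j + 1, 120))
      expect_identical(repaired_j, repaired0)
    }
  }
})

test_that("deletions with no flanking identity score zero", {
  g <- genome(c(c = paste0(strrep("A", 20), strrep("C", 20),
                           strrep("G", 20), strrep("T", 20))))
  # junction joins the A block to the G block: no shared abutting base
  r <- score_microhomology(g, data.frame(chrom = "c", start = 10, end = 50))
  expect_equal(r$mh_length, 0L)
})

test_that("classification applies the ED/LD distance and primer rules", {
  sg <- data.frame(chrom = "chr1", proto_start = 1000L, proto_end = 1020L,
                   pam_end = 1023L, strand = "+", cut_site = 1017L)
  primers <- data.frame(chrom = "chr1", start = c(700L, 1300L),
                        end = c(720L, 1320L), tier = c("SR", "SR"))
  dels <- data.frame(
    chrom = "chr1",
    start = c(990L, 600L, 840L),
    end = c(1033L, 1350L, 1180L),
    sample = c("ed", "ld", "other"),
    modality = "nuclease_1x", source = "clone")
  cls <- classify_deletion(dels, sg, primers)
  # ends within 25 bp beyond the PAM -> ED
  expect_identical(cls$class, c("ED", "LD", "other"))
  expect_identical(cls$ablates_sr_primer, c(FALSE, TRUE, FALSE))
  # without a primer table the distance criterion alone makes an LD
  cls2 <- classify_deletion(dels, sg)
  expect_identical(cls2$class[3], "other")  # 160 bp is still under 200
  expect_identical(cls2$class[2], "LD")
  expect_true(all(is.na(cls2$ablates_sr_primer)))
  # literature rule: >80 bp from the cut site
  cls3 <- classify_deletion(dels, sg, mode = "literature")
  expect_identical(cls3$class, c("other", "LD", "LD"))
  expect_error(classify_deletion(dels, sg[0, ]), "at least one sgRNA")
})

test_that("alternative microhomology counting subtracts the junction copy and honours exclusions", {
  # deleted sequence GCATTGCAAGCA carries GCA at offsets 0, 5 and 9
  ref <- paste0("TT", "GCATTGCAAGCA", "GCAGG")
  g <- genome(c(c = ref))
  del <- data.frame(chrom = "c", start = 2L, end = 14L)
  mh <- score_microhomology(g, del)
  expect_identical(mh$mh_seq, "GCA")
  expect_identical(mh$direction, "right_extension")
  # 3 internal occurrences, minus the junction-consumed copy at offset 0
  expect_equal(count_alternative_microhomologies(g, del, mh), 2L)
  # excluding the whole deleted interval leaves none
  expect_equal(
    count_alternative_microhomologies(g, del, mh, excluded = c(2L, 14L)), 0L)
  # exclusion growth never increases the count
  prev <- Inf
  for (hi in c(4L, 8L, 11L, 14L)) {
    cnt <- count_alternative_microhomologies(g, del, mh,
                                             excluded = c(2L, hi))
    expect_lte(cnt, prev)
    prev <- cnt
  }
  # zero-length homology warns and returns 0
  mh0 <- list(mh_length = 0L, mh_seq = "", direction = "none")
  expect_warning(n0 <- count_alternative_microhomologies(g, del, mh0),
                 "no junction microhomology")
  expect_equal(n0, 0L)
})

test_that("length distributions normalise and respect weights", {
  d <- length_distribution(c(0L, 2L, 2L, 3L), window = 10)
  expect_equal(d$proportion[d$length %in% c(0, 2, 3)], c(.25, .5, .25))
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  empty <- length_distribution(integer(), window = 10)
  expect_true(all(empty$count == 0))
  w <- length_distribution(c(1L, 2L), window = 5, weights = c(3, 1))
  expect_equal(w$proportion[w$length %in% 1:2], c(.75, .25))
})
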