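# Independent brute-force microhomology oracle: enumerates every k in
# 0..window for both the left and right matched run on explicit
# character vectors and combines them into the junction block. Kept
# deliberately separate from the package's vectorised scorer.

oracle_score <- function(chars, start, end, window = 10L) {
  L <- length(chars)
  match_run <- function(pos_a, pos_b, k) {
    # pos_a/pos_b are 0-based starts of two k-length blocks
    if (pos_a < 0L || pos_b < 0L || pos_a + k > L || pos_b + k > L) {
      return(FALSE)
    }
    a <- chars[(pos_a + 1L):(pos_a + k)]
    b <- chars[(pos_b + 1L):(pos_b + k)]
    all(a == b) && !any(a == "N") && !any(b == "N")
  }
  kr <- 0L
  for (k in seq_len(window)) {
    if (match_run(start, end, k)) kr <- k
  }
  kl <- 0L
  for (k in seq_len(window)) {
    if (match_run(start - k, end - k, k)) kl <- k
  }
  total <- min(kl + kr, window)
  direction <- if (total == 0L) "none"
    else if (kl == 0L) "right_extension"
    else if (kr == 0L) "left_extension"
    else "spanning"
  seq <- if (total == 0L) "" else {
    paste(chars[(start - kl + 1L):(start - kl + total)], collapse = "")
  }
  list(length = total, k_left = kl, k_right = kr, seq = seq,
       direction = direction)
}

random_genome_chars <- function(length, gc = 0.5) {
  sample(c("A", "T", "G", "C"), length, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# n random (genome, deletion) pairs on fresh random sequences
random_scoring_cases <- function(n, len = 200L) {
  lapply(seq_len(n), function(i) {
    chars <- random_genome_chars(len)
    start <- sample.int(len - 2L, 1L) - 1L
    end <- start + sample.int(min(len - start, 60L) - 1L, 1L)
    list(chars = chars, start = start, end = end)
  })
}
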