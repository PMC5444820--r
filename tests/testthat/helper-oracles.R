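# Independent reference implementations ("oracles") and small fixtures used
# across the test files. These deliberately use the most direct possible
# algorithms, so agreement with the package implementations is meaningful.

## exhaustive Hamming aligner: compare a read against every probe 50-mer over
## the read's own length; best distance <= max_mm wins, ties are ambiguous
## (index 0), reads shorter than min_len are unmapped
oracle_align_one <- function(read, probes, max_mm = 2L, min_len = 40L) {
  w <- nchar(read)
  if (w < min_len || w > 50L) {
    return(list(index = 0L, mismatches = NA_integer_))
  }
  d <- vapply(probes, function(p) {
    sum(utf8ToInt(read) != utf8ToInt(substr(p, 1L, w)))
  }, integer(1))
  best <- min(d)
  if (best > max_mm || sum(d == best) > 1L) {
    return(list(index = 0L, mismatches = NA_integer_))
  }
  list(index = which.min(d), mismatches = best)
}

## brute-force Benjamini-Hochberg step-up, written as the textbook loop
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(ranked, 1)
  out
}

## brute-force tail extraction from a named median-rank vector
oracle_tails <- function(medians, frac) {
  k <- floor(frac * length(medians))
  s <- medians[order(medians, names(medians))]
  list(up = names(s)[seq_len(k)], down = rev(names(s))[seq_len(k)])
}

## a small deterministic probe pool with hand-readable sequences
tiny_pool <- function(n = 6L, seed = 42L) {
  random_pool(n, seed = seed, name = "tiny")
}

## sim_config with every noise source switched off
noise_free_config <- function(reads = 1000, seed = 1L) {
  sim_config(reads_per_sample = reads, chimera_rate = 0,
             background_rate_per_probe = 0, partial_read_rate = 0,
             seq_error_rate_per_base = 0, seed = seed)
}

## one sample-sheet row usable by simulate_sample
sheet_row <- function(sample_id = "s1") {
  data.frame(sample_id = sample_id,
             index1 = "ACGTACGTA", index2 = "TTGGCCAAT",
             stringsAsFactors = FALSE)
}

## flip one base of a sequence at position pos to a fixed different base
flip_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- c(A = "C", C = "G", G = "T", T = "A")[[old]]
  substr(seq, pos, pos) <- new
  seq
}
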