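# shared in-code fixtures for the test suite

# a small step experiment: `n` transcripts with a known onset
step_spec <- function(n = 1L, len = 200L, onset = 50L, fold = 4,
                      depth = 5, dispersion = 0.3, reps = 4L) {
  serp_sim_spec(n_transcripts = n, orf_length = len, onset_codon = onset,
                enrichment_fold = fold, mean_depth = depth,
                nb_dispersion = dispersion, n_replicates = reps)
}

# noise-free enrichment profile with a hard step at `onset`
step_profile <- function(len = 200L, onset = 130L, base = 1, fold = 4,
                         id = "TX0001") {
  tibble::tibble(
    transcript_id = id,
    codon = seq_len(len),
    enrichment = ifelse(seq_len(len) >= onset, base * fold, base))
}

# independent brute-force oracles ------------------------------------------

# windowed mean with truncated edges, computed position by position
brute_gliding_average <- function(x, w) {
  half <- (w - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  }, numeric(1))
}

# step-up BH from its definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive onset scan: first codon whose run of r codons all clear thr
brute_onset <- function(E, thr, r) {
  L <- length(E)
  if (r > L) return(NA_integer_)
  for (c in seq_len(L - r + 1)) {
    if (all(E[c:(c + r - 1)] >= thr)) return(c)
  }
  NA_integer_
}
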