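# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive traversal of an SWC table: recomputes tips, bifurcations and
# total dendritic length from the raw parent pointers.
morph_traversal_oracle <- function(tree) {
  tree <- as.data.frame(tree)
  kids <- split(seq_len(nrow(tree)), factor(tree$parent, levels = tree$id))
  n_children <- vapply(as.character(tree$id), function(id) {
    k <- kids[[id]]
    if (is.null(k)) 0L else length(k)
  }, integer(1L))
  dend <- tree$type == 3L
  tips <- 0L; bifs <- 0L; len <- 0
  for (i in seq_len(nrow(tree))) {
    if (!dend[i]) next
    if (n_children[i] == 0L) tips <- tips + 1L
    if (n_children[i] >= 2L) bifs <- bifs + 1L
    j <- match(tree$parent[i], tree$id)
    if (!is.na(j))
      len <- len + sqrt(sum((c(tree$x[i], tree$y[i], tree$z[i]) -
                               c(tree$x[j], tree$y[j], tree$z[j]))^2))
  }
  list(n_tips = tips, n_bifurcations = bifs, total_length = len)
}

# Brute-force two-sided Fisher p by full enumeration of the hypergeometric
# distribution with fixed margins, using exact binomial coefficients
# (exact in doubles for the small margins used in tests).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Fraction of `truth` times matched by a detection within `tol` seconds.
match_fraction <- function(detected, truth, tol = 1.5e-3) {
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(t) any(abs(detected - t) < tol), logical(1L)))
}

# Amplitude of the frequency component nearest `f0` in a trace (FFT bin
# magnitude normalized to sinusoid amplitude).
component_amplitude <- function(x, fs, f0) {
  n <- length(x)
  sp <- abs(stats::fft(x))[seq_len(floor(n / 2) + 1L)] * 2 / n
  freqs <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  sp[which.min(abs(freqs - f0))]
}
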