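# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
boxcar_smooth <- function(x, width) {
  # centered moving average; width in samples, forced odd, edges padded by
  # replication so the output has the same length and no phase shift
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(width):(length(xp))] - c(0, cs[seq_len(length(xp) - width)])) / width
}

#' @keywords internal
#' @noRd
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("trace too short for a derivative estimate")
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

# Local maxima of x above `min_height`, thinned so accepted peaks are at
# least `min_sep` samples apart; ties resolved by keeping the larger peak
# (greedy in descending amplitude).
#' @keywords internal
#' @noRd
find_peaks <- function(x, min_height = -Inf, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  idx <- idx[x[idx] >= min_height]
  if (length(idx) <= 1L || min_sep <= 1L) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_sep)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

# Topographic prominence of a peak at index i: height above the higher of
# the two minima separating it from higher ground (or the trace edge).
#' @keywords internal
#' @noRd
peak_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  left <- if (i > 1L) x[seq_len(i - 1L)] else numeric(0)
  right <- if (i < n) x[(i + 1L):n] else numeric(0)
  # strictly higher ground, so flat-topped peaks keep their prominence
  lmin <- if (length(left)) {
    higher <- which(left > h)
    if (length(higher)) min(left[(max(higher)):length(left)]) else min(left)
  } else h
  rmin <- if (length(right)) {
    higher <- which(right > h)
    if (length(higher)) min(right[seq_len(min(higher))]) else min(right)
  } else h
  h - max(lmin, rmin)
}

#' @keywords internal
#' @noRd
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
#' @noRd
assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Draw Poisson event times on (0, duration) with an absolute refractory
# period: times closer than `refractory` to the previously kept event are
# dropped (thinning, keeps the earlier event).
#' @keywords internal
#' @noRd
poisson_times <- function(rate, duration, refractory = 0) {
  if (rate <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * duration)
  t <- sort(stats::runif(n, 0, duration))
  if (refractory > 0 && length(t) > 1L) {
    keep <- rep(TRUE, length(t))
    last <- t[1L]
    for (i in seq_along(t)[-1L]) {
      if (t[i] - last < refractory) keep[i] <- FALSE else last <- t[i]
    }
    t <- t[keep]
  }
  t
}
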