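#' Parameters for synthetic extracellular Purkinje-cell recordings
#'
#' Purkinje cells fire high-rate biphasic simple spikes (20-80 Hz) and
#' rarer, larger multiphasic complex spikes driven by climbing-fiber input
#' from the inferior olive. The generator places both event types at
#' Poisson times with an absolute refractory period and superimposes
#' Gaussian noise.
#'
#' @param ss_rate simple-spike rate, Hz.
#' @param cs_rate complex-spike rate, Hz.
#' @param ss_amplitude simple-spike peak amplitude, a.u.
#' @param cs_amplitude complex-spike peak amplitude, a.u.; must exceed
#'   `ss_amplitude`, otherwise the amplitude criterion used downstream is
#'   unidentifiable.
#' @param duration recording duration, s.
#' @param noise_sd noise SD, a.u.
#' @param sampling_rate Hz.
#' @param refractory absolute refractory period between planted events, s
#'   (>= 2 ms).
#' @param seed integer seed.
#' @return an object of class `synth_extracell_params`.
#' @export
synth_extracell_params <- function(ss_rate = 50, cs_rate = 1,
                                   ss_amplitude = 1, cs_amplitude = 2,
                                   duration = 60, noise_sd = 0.05,
                                   sampling_rate = 25000,
                                   refractory = 0.002, seed = 1L) {
  assert_scalar_num(ss_rate, "ss_rate", nonneg = TRUE)
  assert_scalar_num(cs_rate, "cs_rate", nonneg = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (refractory < 0.002) stop("refractory must be at least 2 ms")
  if (cs_amplitude <= ss_amplitude)
    stop("cs_amplitude must exceed ss_amplitude: the amplitude criterion ",
         "cannot identify complex spikes otherwise")
  structure(
    list(ss_rate = ss_rate, cs_rate = cs_rate, ss_amplitude = ss_amplitude,
         cs_amplitude = cs_amplitude, duration = duration,
         noise_sd = noise_sd, sampling_rate = sampling_rate,
         refractory = refractory, seed = as.integer(seed)),
    class = "synth_extracell_params")
}

# biphasic simple-spike waveform: one sine period, peak first.
# returns waveform and the index of its positive peak.
#' @keywords internal
#' @noRd
ss_waveform <- function(amp, fs, period_ms = 1.0) {
  n <- max(8L, round(period_ms / 1000 * fs))
  w <- amp * sin(2 * pi * seq_len(n) / n)
  list(w = w, i_peak = which.max(w))
}

# multiphasic complex-spike waveform: a wider biphasic main spike followed
# by damped spikelets; total support confined to 2 ms after the main peak
# so the detector's minimum-separation rule absorbs the spikelets.
#' @keywords internal
#' @noRd
cs_waveform <- function(amp, fs) {
  main <- ss_waveform(amp, fs, period_ms = 1.2)  # peak 0.3 ms in, ends 0.9 ms after peak
  n_tail <- max(4L, round(0.0011 * fs))
  tail <- numeric(n_tail)
  tt <- seq_len(n_tail) / fs * 1000           # ms after main waveform end
  for (k in seq_len(3L)) {
    centre <- 0.15 + 0.3 * (k - 1L)           # 1.05/1.35/1.65 ms after peak
    tail <- tail + 0.45 * amp * exp(-k / 2) * exp(-((tt - centre) / 0.1)^2)
  }
  # smooth truncation to zero at the 2 ms post-peak boundary
  ramp <- pmin(1, (n_tail - seq_len(n_tail)) / max(1, round(n_tail / 8)))
  list(w = c(main$w, tail * ramp), i_peak = main$i_peak)
}

#' Generate an extracellular recording with planted event times
#'
#' @param params a [synth_extracell_params()].
#' @return list with `trace` (an extracellular [ts_trace()]),
#'   `true_ss_times` and `true_cs_times` (s, times of the planted waveform
#'   peaks after refractory thinning).
#' @export
gen_extracellular_recording <- function(params) {
  stopifnot(inherits(params, "synth_extracell_params"))
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  set.seed(params$seed)
  cs_t <- poisson_times(params$cs_rate, params$duration)
  ss_t <- poisson_times(params$ss_rate, params$duration)
  # joint refractory thinning across both trains; complex spikes win ties
  ev <- rbind(
    if (length(cs_t)) data.frame(t = cs_t, cs = TRUE) else NULL,
    if (length(ss_t)) data.frame(t = ss_t, cs = FALSE) else NULL)
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(ev$t, -ev$cs), ]
    # refractory enforced on the discretized peak samples, so downstream
    # minimum-separation detection can never straddle a rounding boundary
    sep_samples <- round(params$refractory * fs)
    keep <- rep(TRUE, nrow(ev))
    last <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (round(ev$t[i] * fs) - last <= sep_samples) keep[i] <- FALSE
      else last <- round(ev$t[i] * fs)
    }
    ev <- ev[keep, , drop = FALSE]
  } else {
    ev <- data.frame(t = numeric(0), cs = logical(0))
  }
  x <- numeric(n)
  ssw <- ss_waveform(params$ss_amplitude, fs)
  csw <- cs_waveform(params$cs_amplitude, fs)
  place <- function(x, t_peak, wf) {
    i_pk <- round(t_peak * fs) + 1L
    i0 <- i_pk - wf$i_peak + 1L
    i1 <- i0 + length(wf$w) - 1L
    if (i0 < 1L || i1 > n) return(list(x = x, ok = FALSE, t = NA_real_))
    x[i0:i1] <- x[i0:i1] + wf$w
    list(x = x, ok = TRUE, t = (i_pk - 1L) / fs)
  }
  ss_out <- cs_out <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    wf <- if (ev$cs[i]) csw else ssw
    res <- place(x, ev$t[i], wf)
    if (res$ok) {
      x <- res$x
      if (ev$cs[i]) cs_out <- c(cs_out, res$t) else ss_out <- c(ss_out, res$t)
    }
  }
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
  list(trace = ts_trace(x, fs, "extracellular"),
       true_ss_times = ss_out, true_cs_times = cs_out)
}

# Zero-phase filtering by applying a squared analog Butterworth magnitude
# response in the frequency domain, with reflection padding against edge
# artifacts. Equivalent in magnitude to forward-backward (filtfilt)
# application of the corresponding filter and exactly zero-phase; avoids
# the coefficient ill-conditioning of time-domain IIR designs at very low
# normalized cutoffs (10 Hz at 100 kHz sampling).
#' @keywords internal
#' @noRd
fft_filter <- function(trace, gain2_fun) {
  x <- trace$samples
  n <- length(x)
  pad <- min(n - 1L, max(16L, round(n / 4)))
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1L, -1L)) *
    trace$sampling_rate / m
  g <- gain2_fun(abs(f))
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  trace$samples <- y[(pad + 1L):(pad + n)]
  trace
}

#' 10 Hz zero-phase high-pass filter
#'
#' Removes DC and slow drift before event detection (extracellular analyses
#' were performed in 10 Hz high-pass filtered traces). Fourth-order
#' Butterworth response applied forward-backward (zero phase), so event
#' times are not shifted; the output mean is approximately zero.
#'
#' @param trace an extracellular [ts_trace()]; `sampling_rate` must exceed
#'   20 Hz.
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order.
#' @return the filtered [ts_trace()].
#' @export
highpass_10hz <- function(trace, cutoff = 10, order = 4L) {
  stopifnot(inherits(trace, "ts_trace"))
  if (trace$sampling_rate <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff frequency")
  fft_filter(trace, function(f) {
    r <- (f / cutoff)^(2L * order)
    (r / (1 + r))^2  # squared magnitude: forward + backward pass
  })
}

#' 58-62 Hz zero-phase notch filter
#'
#' Band-stop around mains frequency, for display parity only; the analysis
#' path never uses it.
#'
#' @param trace an extracellular [ts_trace()].
#' @param band two-element stop band, Hz.
#' @param order filter order.
#' @return the filtered [ts_trace()].
#' @export
notch_60hz <- function(trace, band = c(58, 62), order = 4L) {
  stopifnot(inherits(trace, "ts_trace"))
  f0sq <- band[1L] * band[2L]
  bw <- band[2L] - band[1L]
  fft_filter(trace, function(f) {
    ratio <- ifelse(f^2 == f0sq, Inf, (f * bw) / abs(f0sq - f^2))
    (1 / (1 + ratio^(2L * order)))^2
  })
}

#' Classify extracellular events into simple and complex spikes
#'
#' All candidate events are peaks exceeding `noise_k` times the robust
#' (median-absolute-deviation) noise level, separated by at least
#' `min_sep_ms`. The amplitude criterion — a complex spike must exceed the
#' maximum simple-spike peak of the entire trace — is circular as stated,
#' so the classifier first splits the sorted peak-amplitude distribution at
#' its largest gap: the amplitude threshold is the maximum peak of the
#' provisional simple-spike class, and complex spikes are the events
#' strictly above it. If the relative gap is below `min_gap_ratio` the
#' distribution is considered unimodal and no complex spikes are reported.
#' A `manual_threshold` overrides the automatic split.
#'
#' @param trace a filtered extracellular [ts_trace()] (see
#'   [highpass_10hz()]); at least 60 s is recommended (a warning is issued
#'   below that).
#' @param noise_k detection threshold in robust-noise units.
#' @param min_sep_ms minimum event separation, ms.
#' @param min_gap_ratio minimal amplitude ratio across the split gap.
#' @param manual_threshold optional explicit amplitude threshold (a.u.).
#' @return list of class `unit_classification`: `simple_spike_times`,
#'   `complex_spike_times` (s, disjoint), `ss_frequency`, `cs_frequency`
#'   (Hz), `amplitude_threshold_used` (a.u.), `duration` (s).
#' @export
classify_events <- function(trace, noise_k = 4, min_sep_ms = 2,
                            min_gap_ratio = 1.2, manual_threshold = NULL) {
  stopifnot(inherits(trace, "ts_trace"))
  fs <- trace$sampling_rate
  dur <- trace_duration(trace)
  if (dur < 60)
    warning("less than 60 s of activity; frequency estimates will be noisy")
  x <- trace$samples
  noise <- stats::mad(x)
  # floor at 5% of the largest excursion: on (near-)noise-free traces the
  # MAD degenerates to ~0 and filter ripple would otherwise be detected
  thr_detect <- max(noise_k * noise, 0.05 * max(abs(x)))
  sep <- max(1L, round(min_sep_ms / 1000 * fs))
  peaks <- find_peaks(x, min_height = thr_detect, min_sep = sep)
  empty <- function(thr) {
    out <- list(simple_spike_times = numeric(0),
                complex_spike_times = numeric(0),
                ss_frequency = 0, cs_frequency = 0,
                amplitude_threshold_used = thr, duration = dur)
    class(out) <- "unit_classification"
    out
  }
  if (!length(peaks)) return(empty(NA_real_))
  amps <- x[peaks]
  times <- trace$start_time + (peaks - 1L) / fs
  if (!is.null(manual_threshold)) {
    thr <- manual_threshold
  } else if (length(peaks) == 1L) {
    thr <- amps
  } else {
    s <- sort(amps)
    gaps <- diff(s)
    # complex spikes are the rare upper class: search for the split in the
    # upper half of the amplitude distribution only, so stray low-amplitude
    # detections cannot hijack the largest gap
    lo_bound <- max(1L, floor(length(s) / 2))
    gaps[seq_len(lo_bound - 1L)] <- -Inf
    i_gap <- which.max(gaps)
    if (s[i_gap] <= 0 || s[i_gap + 1L] / s[i_gap] < min_gap_ratio) {
      warning("unimodal amplitude distribution: no complex spikes identified")
      thr <- max(amps)
    } else {
      thr <- s[i_gap]
    }
  }
  is_cs <- amps > thr
  out <- list(simple_spike_times = times[!is_cs],
              complex_spike_times = times[is_cs],
              ss_frequency = sum(!is_cs) / dur,
              cs_frequency = sum(is_cs) / dur,
              amplitude_threshold_used = thr,
              duration = dur)
  class(out) <- "unit_classification"
  out
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf(
    "Unit classification: %d simple (%.2f Hz), %d complex (%.3f Hz), amplitude threshold %.3g\n",
    length(x$simple_spike_times), x$ss_frequency,
    length(x$complex_spike_times), x$cs_frequency,
    x$amplitude_threshold_used))
  invisible(x)
}

#' Complex-spike frequency
#'
#' @param classification a `unit_classification` (see [classify_events()]).
#' @param duration recording duration, s (> 0); defaults to the duration
#'   recorded in the classification.
#' @return complex-spike frequency in Hz.
#' @export
cs_frequency <- function(classification, duration = classification$duration) {
  assert_scalar_num(duration, "duration", positive = TRUE)
  length(classification$complex_spike_times) / duration
}
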