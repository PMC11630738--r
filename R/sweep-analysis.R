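#' F-I (input-output) curve from a sweep set
#'
#' Counts spikes per current step, one point per sweep. With
#' `exclude_low_threshold = TRUE` the narrow initial low-threshold spikes
#' are excluded from the counts, as in the typical-spike analyses.
#'
#' @param sweeps a [sweep_set()] with step metadata.
#' @param exclude_low_threshold drop spikes classed `"low_threshold"`.
#' @param config a [feature_config()].
#' @return data frame of class `fi_curve` with columns `injected_current`
#'   (pA) and `spike_count`; `step_duration` attached as an attribute.
#' @export
fi_curve <- function(sweeps, exclude_low_threshold = FALSE,
                     config = feature_config()) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(sweeps$injected_current))
    stop("sweep set carries no injected-current metadata")
  proto <- sweeps$protocol
  counts <- vapply(seq_along(sweeps$sweeps), function(i) {
    fe <- extract_spike_features(sweeps$sweeps[[i]], config,
                                 step_start = proto$onset,
                                 step_end = proto$onset + proto$duration)
    if (exclude_low_threshold)
      fe <- fe[fe$spike_class != "low_threshold", , drop = FALSE]
    nrow(fe)
  }, integer(1L))
  out <- data.frame(injected_current = sweeps$injected_current,
                    spike_count = counts)
  attr(out, "step_duration") <- proto$duration
  class(out) <- c("fi_curve", class(out))
  out
}

#' Quantify spontaneous subthreshold oscillations
#'
#' Implements the SSTO measurements: the resting potential estimate is the
#' mean over a 10 s spike-masked window (spikes masked `+/- mask_ms` and
#' linearly interpolated); SSTO frequency is the maximal spectral peak of
#' the masked, mean-subtracted trace within `config$band`, reported as 0
#' (with amplitude 0) when the peak does not exceed `config$peak_snr` times
#' the median in-band power; SSTO amplitude is the mean peak-to-trough
#' excursion over detected oscillation cycles; the spontaneous spike rate is
#' the detected spike count divided by the duration.
#'
#' @param trace a voltage [ts_trace()] of at least 10 s.
#' @param config a [feature_config()].
#' @return list of class `ssto_metrics`: `resting_vm_estimate` (mV),
#'   `ssto_frequency` (Hz), `ssto_amplitude` (mV peak-to-trough),
#'   `spontaneous_spike_rate` (Hz).
#' @export
ssto_metrics <- function(trace, config = feature_config()) {
  stopifnot(inherits(trace, "ts_trace"))
  fs <- trace$sampling_rate
  dur <- trace_duration(trace)
  if (dur < 10) stop("ssto_metrics requires at least 10 s of recording")
  ev <- detect_spikes(trace, config)
  rate <- nrow(ev) / dur

  x <- trace$samples
  n <- length(x)
  if (nrow(ev)) {
    mask <- rep(FALSE, n)
    half <- round(config$mask_ms / 1000 * fs)
    for (i in ev$peak_index) {
      mask[max(1L, i - half):min(n, i + half)] <- TRUE
    }
    x[mask] <- NA_real_
    x <- stats::approx(seq_len(n)[!is.na(x)], x[!is.na(x)], xout = seq_len(n),
                       rule = 2)$y
  }
  # resting Vm: mean across the first 10 s of the masked trace
  n10 <- min(n, round(10 * fs))
  vm <- mean(x[seq_len(n10)])

  xc <- x - mean(x)
  spec <- stats::fft(xc)
  pow <- Mod(spec[seq_len(floor(n / 2) + 1L)])^2
  freqs <- (seq_along(pow) - 1L) * fs / n
  in_band <- freqs >= config$band[1L] & freqs <= config$band[2L]
  if (!any(in_band)) stop("trace too short to resolve the SSTO band")
  pb <- pow[in_band]; fb <- freqs[in_band]
  i_pk <- which.max(pb)
  # peak-vs-noise decision on a segment-averaged (Welch) spectrum: raw
  # periodogram bins are exponentially distributed, so their maximum always
  # dwarfs the median even for white noise; averaging across segments makes
  # the peak_snr ratio discriminative
  n_seg <- 8L
  seg_len <- floor(n / n_seg)
  wp <- 0
  for (s in seq_len(n_seg)) {
    seg <- xc[((s - 1L) * seg_len + 1L):(s * seg_len)]
    sp <- Mod(stats::fft(seg - mean(seg))[seq_len(floor(seg_len / 2) + 1L)])^2
    wp <- wp + sp / n_seg
  }
  wf <- (seq_along(wp) - 1L) * fs / seg_len
  w_band <- wf >= config$band[1L] & wf <= config$band[2L]
  w_at_peak <- wp[w_band][which.min(abs(wf[w_band] - fb[i_pk]))]
  w_med <- stats::median(wp[w_band])
  has_peak <- pb[i_pk] > 0 &&
    (w_med == 0 || w_at_peak / w_med >= config$peak_snr)
  if (!has_peak) {
    out <- list(resting_vm_estimate = vm, ssto_frequency = 0,
                ssto_amplitude = 0, spontaneous_spike_rate = rate)
    class(out) <- "ssto_metrics"
    return(out)
  }
  f0 <- fb[i_pk]

  # cycle segmentation: upward mean-crossings of a lightly smoothed trace
  w <- max(1L, round(fs / (10 * f0)))
  xs <- boxcar_smooth(xc, w)
  up <- which(xs[-1L] >= 0 & xs[-length(xs)] < 0)
  amp <- 0
  if (length(up) >= 2L) {
    # per-cycle excursions on a lightly smoothed trace (window 1/40 of the
    # cycle): raw max-min would report the noise extremes of each cycle
    xa <- boxcar_smooth(xc, max(1L, round(fs / (40 * f0))))
    exc <- vapply(seq_len(length(up) - 1L), function(k) {
      seg <- xa[up[k]:(up[k + 1L])]
      max(seg) - min(seg)
    }, numeric(1L))
    amp <- mean(exc)
  }
  out <- list(resting_vm_estimate = vm, ssto_frequency = f0,
              ssto_amplitude = amp, spontaneous_spike_rate = rate)
  class(out) <- "ssto_metrics"
  out
}

#' @export
print.ssto_metrics <- function(x, ...) {
  cat(sprintf(
    "SSTO metrics: Vm %.2f mV | f %.2f Hz | amplitude %.2f mV p-t | spikes %.3f Hz\n",
    x$resting_vm_estimate, x$ssto_frequency, x$ssto_amplitude,
    x$spontaneous_spike_rate))
  invisible(x)
}

#' Input resistance from subthreshold current steps
#'
#' Least-squares slope of the steady-state voltage deflection (mean over the
#' last 20% of the step, relative to the pre-step baseline) against injected
#' current, over spike-free steps; reported in MOhm (1 mV/pA = 1000 MOhm).
#' The source protocol injected -100 and -50 pA steps at the start of the
#' evoked-firing protocol for exactly this purpose.
#'
#' @param sweeps a [sweep_set()].
#' @param config a [feature_config()]; steps containing detected spikes are
#'   excluded from the fit.
#' @return input resistance in MOhm.
#' @export
input_resistance <- function(sweeps, config = feature_config()) {
  stopifnot(inherits(sweeps, "sweep_set"))
  proto <- sweeps$protocol
  fs <- sweeps$sampling_rate
  i_on <- round(proto$onset * fs) + 1L
  i_off <- i_on + round(proto$duration * fs) - 1L
  use <- vapply(seq_along(sweeps$sweeps), function(i) {
    ev <- try(detect_spikes(sweeps$sweeps[[i]], config), silent = TRUE)
    if (inherits(ev, "try-error")) return(TRUE)
    !nrow(ev)
  }, logical(1L))
  if (sum(use) < 2L)
    stop("fewer than 2 spike-free steps with distinct currents; cannot fit input resistance")
  defl <- vapply(which(use), function(i) {
    x <- sweeps$sweeps[[i]]$samples
    base <- mean(x[seq_len(max(1L, i_on - 1L))])
    ss_lo <- i_off - max(1L, round(0.2 * (i_off - i_on + 1L))) + 1L
    mean(x[ss_lo:i_off]) - base
  }, numeric(1L))
  cur <- sweeps$injected_current[use]
  if (length(unique(cur)) < 2L) stop("need at least two distinct currents")
  slope <- sum((cur - mean(cur)) * (defl - mean(defl))) /
    sum((cur - mean(cur))^2)                 # mV per pA
  slope * 1000                                # MOhm
}

#' @keywords internal
#' @noRd
locate_vc_step <- function(x, fs) {
  d <- abs(diff(x))
  if (!length(d) || max(d) <= 0) stop("step boundaries not identifiable")
  noise <- stats::mad(diff(x[seq_len(max(10L, round(length(x) * 0.05)))]))
  if (max(d) < max(10 * noise, 1e-9)) stop("step boundaries not identifiable")
  i_on <- which.max(d) + 1L  # first sample after the jump (the peak)
  # a second, opposite jump marks the step end; otherwise the trace end
  rest <- d
  guard <- round(0.001 * fs)
  rest[seq_len(min(length(rest), i_on + guard))] <- 0
  i_off <- if (max(rest) > 0.5 * d[i_on - 1L]) which.max(rest) else length(x)
  list(onset = i_on, offset = i_off)
}

#' Cell capacitance from a voltage-clamp step transient
#'
#' `C = Q / dV`: the capacitative charge `Q` is the area between the
#' current transient and its steady state (trapezoidal integration from the
#' step onset to the first sustained, >= 1 ms, return to within noise of the
#' steady state); the steady state is the mean over the last 20% of the
#' step. Units: pA*s / mV -> nF, reported in pF. The source protocol used a
#' 10 mV step from -80 mV.
#'
#' @param current_trace a current [ts_trace()] (pA), voltage-clamp response
#'   to a square command step.
#' @param step_amplitude command step, mV (default 10).
#' @param onset,offset optional sample indices of the step boundaries;
#'   detected from the largest current jumps when omitted.
#' @return capacitance in pF.
#' @export
capacitance_from_step <- function(current_trace, step_amplitude = 10,
                                  onset = NULL, offset = NULL) {
  stopifnot(inherits(current_trace, "ts_trace"))
  if (step_amplitude == 0) stop("zero step amplitude")
  x <- current_trace$samples
  fs <- current_trace$sampling_rate
  if (is.null(onset) || is.null(offset)) {
    loc <- locate_vc_step(x, fs)
    if (is.null(onset)) onset <- loc$onset
    if (is.null(offset)) offset <- loc$offset
  }
  if (offset - onset < 10L) stop("step too short to integrate the transient")
  ss_lo <- offset - max(1L, round(0.2 * (offset - onset + 1L))) + 1L
  i_ss <- mean(x[ss_lo:offset])
  dev <- x[onset:offset] - i_ss
  i_peak <- dev[which.max(abs(dev))]
  tol <- max(stats::mad(dev[(length(dev) - round(0.1 * length(dev))):length(dev)]) * 3,
             1e-4 * abs(i_peak))
  run <- max(2L, round(0.001 * fs))  # sustained = 1 ms
  inside <- abs(dev) <= tol
  cs <- cumsum(inside)
  runsum <- cs - utils::head(c(rep(0, run), cs), length(cs))
  sustained <- which(runsum == run)
  i_end <- if (length(sustained)) sustained[1L] else length(dev)
  seg <- dev[seq_len(i_end)]
  q <- sum((seg[-1L] + seg[-length(seg)]) / 2) / fs   # pA*s = pC
  1000 * abs(q / step_amplitude)                      # pF
}

#' Series (access) resistance from a voltage-clamp transient
#'
#' `Rs = dV / I_peak` where `I_peak` is the extremal transient current
#' relative to the pre-step baseline; reported in MOhm.
#'
#' @param current_trace a current [ts_trace()] (pA).
#' @param step_amplitude command step, mV.
#' @param onset optional step-onset sample index.
#' @return series resistance in MOhm.
#' @export
series_resistance <- function(current_trace, step_amplitude, onset = NULL) {
  stopifnot(inherits(current_trace, "ts_trace"))
  if (step_amplitude == 0) stop("zero step amplitude: no transient")
  x <- current_trace$samples
  fs <- current_trace$sampling_rate
  if (is.null(onset)) onset <- locate_vc_step(x, fs)$onset
  base <- mean(x[seq_len(max(1L, onset - 2L))])
  win <- onset:min(length(x), onset + round(0.005 * fs))
  i_peak <- max(abs(x[win] - base))
  if (i_peak <= 0) stop("no transient found")
  1000 * abs(step_amplitude) / i_peak
}

#' Specific resistance
#'
#' Input resistance divided by cell capacitance, MOhm/pF.
#'
#' @param input_resistance MOhm.
#' @param capacitance pF (> 0).
#' @return specific resistance in MOhm/pF.
#' @export
specific_resistance <- function(input_resistance, capacitance) {
  assert_scalar_num(input_resistance, "input_resistance", nonneg = TRUE)
  if (!is.numeric(capacitance) || length(capacitance) != 1L ||
      !is.finite(capacitance) || capacitance == 0)
    stop("capacitance must be a nonzero finite number")
  input_resistance / capacitance
}
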