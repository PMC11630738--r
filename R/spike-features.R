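#' Configuration for intracellular spike feature extraction
#'
#' @param dvdt_min minimum smoothed dV/dt for spike candidacy, mV/ms.
#' @param min_prominence minimum peak prominence, mV.
#' @param refractory minimum separation between detected events, ms.
#' @param smooth_ms boxcar window used to stabilize dV/dt on high-rate
#'   acquisitions, ms.
#' @param lt_halfwidth_max half-width below which a step's first spike is
#'   classed as low-threshold, ms.
#' @param adp_min_prominence minimum prominence for an afterdepolarization
#'   hump, mV.
#' @param recovery_fraction fraction of the AHP-to-baseline gap that ends
#'   the recovery-rate fit window.
#' @param mask_ms half-width of the spike mask used by [ssto_metrics()], ms.
#' @param band frequency band searched for the SSTO spectral peak, Hz.
#' @param peak_snr minimum ratio of the spectral peak to the median in-band
#'   power for the peak to count.
#' @return a named list of configuration values.
#' @export
feature_config <- function(dvdt_min = 10, min_prominence = 20,
                           refractory = 2, smooth_ms = 0.1,
                           lt_halfwidth_max = 1.0, adp_min_prominence = 1,
                           recovery_fraction = 0.9, mask_ms = 20,
                           band = c(0.5, 15), peak_snr = 3) {
  list(dvdt_min = dvdt_min, min_prominence = min_prominence,
       refractory = refractory, smooth_ms = smooth_ms,
       lt_halfwidth_max = lt_halfwidth_max,
       adp_min_prominence = adp_min_prominence,
       recovery_fraction = recovery_fraction, mask_ms = mask_ms,
       band = band, peak_snr = peak_snr)
}

#' @keywords internal
#' @noRd
smoothed_dvdt <- function(trace, config) {
  fs <- trace$sampling_rate
  w <- max(1L, round(config$smooth_ms * fs / 1000))
  xs <- boxcar_smooth(trace$samples, w)
  central_diff(xs, 1000 / fs)  # mV per ms
}

#' Detect action potentials in a voltage trace
#'
#' Candidate events are samples where the boxcar-smoothed dV/dt exceeds
#' `config$dvdt_min`, each followed (within 10 ms) by a local maximum with
#' topographic prominence of at least `config$min_prominence`; events closer
#' than `config$refractory` are merged, keeping the larger peak.
#'
#' @param trace a voltage [ts_trace()].
#' @param config a [feature_config()].
#' @return data frame with one row per event: `peak_index`, `peak_time` (s),
#'   `peak_voltage` (mV). Further features are added by
#'   [extract_spike_features()].
#' @export
detect_spikes <- function(trace, config = feature_config()) {
  stopifnot(inherits(trace, "ts_trace"))
  fs <- trace$sampling_rate
  w <- max(1L, round(config$smooth_ms * fs / 1000))
  if (length(trace$samples) <= 3L * max(3L, w))
    stop("trace shorter than the smoothing window")
  x <- trace$samples
  dv <- smoothed_dvdt(trace, config)
  fast <- dv >= config$dvdt_min
  if (!any(fast)) return(empty_spike_events())
  sep <- max(1L, round(config$refractory * fs / 1000))
  look <- round(0.010 * fs)  # 10 ms search window after a fast upstroke
  peaks <- find_peaks(x, min_sep = sep)
  if (!length(peaks)) return(empty_spike_events())
  keep <- vapply(peaks, function(i) {
    lo <- max(1L, i - look)
    any(fast[lo:i]) && peak_prominence(x, i) >= config$min_prominence
  }, logical(1L))
  peaks <- peaks[keep]
  if (!length(peaks)) return(empty_spike_events())
  data.frame(peak_index = peaks,
             peak_time = trace$start_time + (peaks - 1L) / fs,
             peak_voltage = x[peaks])
}

#' @keywords internal
#' @noRd
empty_spike_events <- function() {
  data.frame(peak_index = integer(0), peak_time = numeric(0),
             peak_voltage = numeric(0))
}

# Index of the start of the rising phase: the last local minimum of the
# (smoothed) trace preceding the peak, bounded by `max_back` samples.
#' @keywords internal
#' @noRd
rising_phase_start <- function(x, i_peak, max_back) {
  lo <- max(1L, i_peak - max_back)
  seg <- x[lo:i_peak]
  n <- length(seg)
  if (n < 3L) return(lo)
  mins <- which(seg[2:(n - 1L)] < seg[1:(n - 2L)] &
                  seg[2:(n - 1L)] <= seg[3:n]) + 1L
  if (length(mins)) lo + mins[length(mins)] - 1L else lo
}

#' Spike threshold from the 10%-of-maximum-dV/dt criterion
#'
#' The threshold is the voltage at the earliest sample of the rising phase
#' (last local minimum before the peak, to the peak) where the smoothed
#' dV/dt first reaches 10% of that spike's maximum dV/dt. Because the
#' criterion is a ratio of slopes it is invariant to uniform time rescaling
#' and to additive voltage offsets.
#'
#' @param trace a voltage [ts_trace()].
#' @param spike one row of the [detect_spikes()] output (or any list with
#'   `peak_index`).
#' @param config a [feature_config()].
#' @param fraction criterion fraction of the maximum dV/dt (default 0.1).
#' @return list with `threshold_voltage` (mV), `threshold_index`,
#'   `threshold_time` (s) and `max_dvdt` (mV/ms).
#' @export
compute_threshold <- function(trace, spike, config = feature_config(),
                              fraction = 0.1) {
  stopifnot(inherits(trace, "ts_trace"))
  fs <- trace$sampling_rate
  i_peak <- spike$peak_index
  dv <- smoothed_dvdt(trace, config)
  max_back <- round(0.020 * fs)  # rising phase begins within 20 ms of peak
  i0 <- rising_phase_start(boxcar_smooth(trace$samples,
                                         max(1L, round(config$smooth_ms * fs / 1000))),
                           i_peak, max_back)
  seg <- i0:i_peak
  mx <- max(dv[seg])
  if (mx <= 0) stop("maximum dV/dt in the rising phase is not positive; not a spike")
  hit <- seg[dv[seg] >= fraction * mx]
  i_thr <- hit[1L]
  # voltage read off the smoothed trace: at high sampling rates the raw
  # sample adds avoidable noise to the reported threshold
  xs <- boxcar_smooth(trace$samples,
                      max(1L, round(config$smooth_ms * fs / 1000)))
  list(threshold_voltage = xs[i_thr],
       threshold_index = i_thr,
       threshold_time = trace$start_time + (i_thr - 1L) / fs,
       max_dvdt = mx)
}

#' Afterhyperpolarization voltage and depth
#'
#' The AHP is the most negative membrane potential in the post-spike period,
#' i.e. the minimum sample in `(peak_time, window_end]` where `window_end`
#' is the earlier of the next spike's threshold time and the end of the
#' current step. Depth is measured either from that spike's threshold
#' (`reference = "threshold"`) or from a stated baseline potential
#' (`reference = "baseline"`, e.g. -60 mV).
#'
#' @param trace a voltage [ts_trace()].
#' @param spike list/row with `peak_index`; when `reference = "threshold"` a
#'   `threshold_voltage` field is required (see [compute_threshold()]).
#' @param window_end end of the post-spike search window, seconds.
#' @param reference `"threshold"` or `"baseline"`.
#' @param baseline_vm baseline potential in mV (used when
#'   `reference = "baseline"`).
#' @param smooth_ms boxcar window (ms) applied before taking the minimum;
#'   the AHP is a slow feature and the smoothed minimum avoids reporting a
#'   single noise excursion. Set 0 for the raw sample minimum.
#' @return list with `ahp_voltage`, `ahp_time`, `ahp_index`, `depth` (mV,
#'   reference level minus AHP voltage).
#' @export
measure_ahp <- function(trace, spike, window_end,
                        reference = c("threshold", "baseline"),
                        baseline_vm = NULL, smooth_ms = 0.5) {
  reference <- match.arg(reference)
  stopifnot(inherits(trace, "ts_trace"))
  fs <- trace$sampling_rate
  i_peak <- spike$peak_index
  i_end <- min(length(trace$samples),
               floor((window_end - trace$start_time) * fs) + 1L)
  if (i_end <= i_peak) stop("empty post-spike window")
  xs <- if (smooth_ms > 0)
    boxcar_smooth(trace$samples, max(1L, round(smooth_ms * fs / 1000)))
  else trace$samples
  seg <- (i_peak + 1L):i_end
  i_min <- seg[which.min(xs[seg])]
  ahp_v <- xs[i_min]
  ref_level <- switch(reference,
    threshold = {
      if (is.null(spike$threshold_voltage))
        stop("spike has no threshold_voltage; run compute_threshold first")
      spike$threshold_voltage
    },
    baseline = {
      if (is.null(baseline_vm)) stop("baseline_vm required")
      baseline_vm
    })
  list(ahp_voltage = ahp_v,
       ahp_time = trace$start_time + (i_min - 1L) / fs,
       ahp_index = i_min,
       depth = ref_level - ahp_v)
}

#' Spike half-width
#'
#' Full width at the voltage midway between threshold and peak, with linear
#' interpolation at the two crossings.
#'
#' @param trace a voltage [ts_trace()].
#' @param spike list/row with `peak_index` and `threshold_voltage`.
#' @param search_ms how far around the peak to search for crossings, ms.
#' @return half-width in ms.
#' @export
spike_half_width <- function(trace, spike, search_ms = 25) {
  fs <- trace$sampling_rate
  x <- trace$samples
  i_peak <- spike$peak_index
  mid <- (spike$threshold_voltage + x[i_peak]) / 2
  back <- round(search_ms / 1000 * fs)
  # rising crossing
  lo <- max(1L, i_peak - back)
  below <- which(x[lo:i_peak] < mid)
  if (!length(below)) stop("no rising half-amplitude crossing found")
  iA <- lo + below[length(below)] - 1L
  t_rise <- iA + (mid - x[iA]) / (x[iA + 1L] - x[iA])
  # falling crossing
  hi <- min(length(x), i_peak + back)
  after <- which(x[i_peak:hi] < mid)
  if (!length(after)) stop("no falling half-amplitude crossing found")
  iB <- i_peak + after[1L] - 1L
  t_fall <- (iB - 1L) + (x[iB - 1L] - mid) / (x[iB - 1L] - x[iB])
  (t_fall - t_rise) * 1000 / fs
}

#' Classify a spike as low-threshold or typical
#'
#' A spike is classed `"low_threshold"` iff it is the first spike of its
#' current step and its half-width is below `config$lt_halfwidth_max`
#' (narrow initial spikes from hyperpolarized holding are excluded from
#' typical-spike analyses); otherwise `"typical"`.
#'
#' @param half_width spike half-width, ms.
#' @param is_first is this the first spike in its step?
#' @param config a [feature_config()].
#' @return `"low_threshold"` or `"typical"`.
#' @export
classify_spike <- function(half_width, is_first, config = feature_config()) {
  if (isTRUE(is_first) && half_width < config$lt_halfwidth_max)
    "low_threshold" else "typical"
}

#' Detect an afterdepolarization hump
#'
#' `TRUE` iff a local maximum with prominence at least
#' `config$adp_min_prominence` exists strictly between the spike peak and
#' the AHP minimum, or the repolarization dV/dt changes sign before the
#' voltage first falls back to threshold level.
#'
#' @param trace a voltage [ts_trace()].
#' @param spike list/row with `peak_index` and `threshold_voltage`.
#' @param ahp_index index of the AHP minimum (see [measure_ahp()]).
#' @param config a [feature_config()].
#' @return logical flag.
#' @export
detect_adp <- function(trace, spike, ahp_index, config = feature_config()) {
  x <- trace$samples
  i_peak <- spike$peak_index
  if (ahp_index <= i_peak + 2L) return(FALSE)
  seg <- (i_peak + 1L):(ahp_index - 1L)
  xs <- x[seg]
  n <- length(xs)
  if (n >= 3L) {
    loc <- which(xs[2:(n - 1L)] > xs[1:(n - 2L)] &
                   xs[2:(n - 1L)] >= xs[3:n]) + 1L
    for (i in loc) {
      if (peak_prominence(xs, i) >= config$adp_min_prominence) return(TRUE)
    }
  }
  # sign change of repolarization slope above threshold level
  above <- xs > spike$threshold_voltage
  if (any(above)) {
    d <- diff(xs[above])
    if (length(d) > 1L && any(d[-1L] > 0 & d[-length(d)] < 0)) return(TRUE)
  }
  FALSE
}

#' Post-AHP recovery rate
#'
#' Slope (mV/ms) of the least-squares line fitted to the voltage from the
#' AHP minimum to the first sample that recovers `config$recovery_fraction`
#' of the gap back to the pre-spike baseline (or to `window_end` if that
#' fraction is never reached).
#'
#' @param trace a voltage [ts_trace()].
#' @param ahp_index index of the AHP minimum.
#' @param baseline_vm pre-spike baseline, mV (by convention the mean voltage
#'   over the 50 ms before the threshold crossing).
#' @param window_end end of the permissible window, seconds.
#' @param config a [feature_config()].
#' @return slope in mV/ms.
#' @export
ahp_recovery_rate <- function(trace, ahp_index, baseline_vm, window_end,
                              config = feature_config()) {
  fs <- trace$sampling_rate
  x <- trace$samples
  i_end <- min(length(x), floor((window_end - trace$start_time) * fs) + 1L)
  if (i_end - ahp_index < 2L) stop("recovery window shorter than 3 samples")
  seg <- ahp_index:i_end
  target <- x[ahp_index] +
    config$recovery_fraction * (baseline_vm - x[ahp_index])
  hit <- if (baseline_vm >= x[ahp_index]) which(x[seg] >= target)
         else which(x[seg] <= target)
  if (length(hit)) seg <- ahp_index:(ahp_index + hit[1L] - 1L)
  if (length(seg) < 3L) seg <- ahp_index:(ahp_index + 2L)
  t_ms <- (seg - seg[1L]) * 1000 / fs
  y <- x[seg]
  # closed-form least squares slope
  sum((t_ms - mean(t_ms)) * (y - mean(y))) / sum((t_ms - mean(t_ms))^2)
}

#' Extract full per-spike feature tables from a trace
#'
#' Runs [detect_spikes()] and fills in threshold, half-width, AHP (from
#' threshold and, when `baseline_vm` is given, from baseline), ADP flag,
#' recovery rate and spike class for every event. The post-spike window for
#' each spike ends at the next spike's threshold crossing or at `step_end`.
#'
#' @param trace a voltage [ts_trace()].
#' @param config a [feature_config()].
#' @param step_end end of the analysis window (e.g. current-step offset),
#'   seconds; defaults to the end of the trace.
#' @param step_start start of the analysis window, seconds; events before it
#'   are ignored.
#' @param baseline_vm optional baseline for `ahp_depth_from_baseline`, mV.
#' @return data frame with one row per spike: times, voltages, `half_width`,
#'   `ahp_voltage`, `ahp_depth_from_threshold`, `ahp_depth_from_baseline`,
#'   `adp_present`, `recovery_rate`, `spike_class`.
#' @export
extract_spike_features <- function(trace, config = feature_config(),
                                   step_start = NULL, step_end = NULL,
                                   baseline_vm = NULL) {
  fs <- trace$sampling_rate
  if (is.null(step_end))
    step_end <- trace$start_time + length(trace$samples) / fs
  ev <- detect_spikes(trace, config)
  if (!is.null(step_start)) ev <- ev[ev$peak_time >= step_start, , drop = FALSE]
  ev <- ev[ev$peak_time <= step_end, , drop = FALSE]
  n <- nrow(ev)
  if (!n) {
    out <- cbind(empty_spike_events(),
                 data.frame(threshold_voltage = numeric(0),
                            threshold_time = numeric(0),
                            half_width = numeric(0),
                            ahp_voltage = numeric(0), ahp_time = numeric(0),
                            ahp_depth_from_threshold = numeric(0),
                            ahp_depth_from_baseline = numeric(0),
                            adp_present = logical(0),
                            recovery_rate = numeric(0),
                            spike_class = character(0)))
    return(out)
  }
  thr <- lapply(seq_len(n), function(i)
    compute_threshold(trace, ev[i, ], config))
  ev$threshold_voltage <- vapply(thr, `[[`, numeric(1L), "threshold_voltage")
  ev$threshold_time <- vapply(thr, `[[`, numeric(1L), "threshold_time")
  ev$half_width <- vapply(seq_len(n), function(i)
    spike_half_width(trace, ev[i, ]), numeric(1L))
  win_end <- c(ev$threshold_time[-1L], step_end)
  ahp <- lapply(seq_len(n), function(i)
    measure_ahp(trace, ev[i, ], win_end[i], reference = "threshold"))
  ev$ahp_voltage <- vapply(ahp, `[[`, numeric(1L), "ahp_voltage")
  ev$ahp_time <- vapply(ahp, `[[`, numeric(1L), "ahp_time")
  ev$ahp_depth_from_threshold <- ev$threshold_voltage - ev$ahp_voltage
  ev$ahp_depth_from_baseline <- if (!is.null(baseline_vm))
    baseline_vm - ev$ahp_voltage else NA_real_
  ahp_idx <- vapply(ahp, `[[`, numeric(1L), "ahp_index")
  ev$adp_present <- vapply(seq_len(n), function(i)
    detect_adp(trace, ev[i, ], ahp_idx[i], config), logical(1L))
  pre_base <- vapply(seq_len(n), function(i) {
    i_thr <- floor((ev$threshold_time[i] - trace$start_time) * fs) + 1L
    lo <- max(1L, i_thr - round(0.05 * fs))
    mean(trace$samples[lo:i_thr])
  }, numeric(1L))
  ev$recovery_rate <- vapply(seq_len(n), function(i) {
    out <- try(ahp_recovery_rate(trace, ahp_idx[i], pre_base[i], win_end[i],
                                 config), silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }, numeric(1L))
  ev$spike_class <- vapply(seq_len(n), function(i)
    classify_spike(ev$half_width[i], i == 1L, config), character(1L))
  ev
}
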