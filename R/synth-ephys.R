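#' Parameters for synthetic intracellular recordings
#'
#' Bundles the generative parameters for inferior-olive-like intracellular
#' traces: a passive RC membrane, a sinusoid-like subthreshold oscillation
#' (SSTO), Gaussian noise and a parametric spike template. The template is a
#' sum/splice of exponential and cosine pieces (approach, fast upstroke,
#' repolarization, optional afterdepolarization hump, afterhyperpolarization
#' and recovery), not the solution of a biophysical membrane model: the
#' downstream analyses implement measurement rules, and the generator's job
#' is to plant events whose threshold, peak and AHP minimum are known
#' exactly.
#'
#' @param sampling_rate Hz (default 1e5, the acquisition rate of the source
#'   recordings).
#' @param ssto_frequency SSTO frequency, Hz (IO neurons oscillate at roughly
#'   1-10 Hz).
#' @param ssto_amplitude SSTO amplitude, mV peak-to-trough. Defaults to 0 so
#'   current-step protocols run from a flat baseline (holding at -80 mV
#'   suppresses SSTOs); set it explicitly when generating spontaneous
#'   activity.
#' @param baseline_vm resting membrane potential, mV.
#' @param spike_template named list as produced by [spike_template()].
#' @param noise_sd Gaussian noise SD, mV.
#' @param membrane_R input resistance, MOhm.
#' @param membrane_C capacitance, pF. The default R and C give a specific
#'   resistance of 2.3 MOhm/pF, the wild-type scale.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return an object of class `synth_ephys_params`.
#' @export
synth_ephys_params <- function(sampling_rate = 1e5,
                               ssto_frequency = 5,
                               ssto_amplitude = 0,
                               baseline_vm = -60,
                               spike_template = NULL,
                               noise_sd = 0.2,
                               membrane_R = 230,
                               membrane_C = 100,
                               seed = 1L) {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(ssto_frequency, "ssto_frequency", nonneg = TRUE)
  assert_scalar_num(ssto_amplitude, "ssto_amplitude", nonneg = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(membrane_R, "membrane_R", positive = TRUE)
  assert_scalar_num(membrane_C, "membrane_C", positive = TRUE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(spike_template)) {
    f <- get("spike_template", envir = asNamespace("olivetools"),
             mode = "function")
    spike_template <- f()
  }
  structure(
    list(sampling_rate = sampling_rate, ssto_frequency = ssto_frequency,
         ssto_amplitude = ssto_amplitude, baseline_vm = baseline_vm,
         spike_template = spike_template, noise_sd = noise_sd,
         membrane_R = membrane_R, membrane_C = membrane_C,
         seed = as.integer(seed)),
    class = "synth_ephys_params")
}

#' Parametric spike template
#'
#' @param threshold spike threshold, mV (absolute).
#' @param peak spike peak, mV; must exceed `threshold`.
#' @param tau_rise_ms upstroke time constant, ms (sets the maximum dV/dt,
#'   `(peak - threshold) / tau_rise_ms`).
#' @param tau_fall_ms repolarization time constant, ms.
#' @param adp_amplitude afterdepolarization hump amplitude, mV (0 disables
#'   the hump).
#' @param adp_duration_ms ADP hump duration, ms.
#' @param ahp_depth AHP depth below threshold, mV (> 2; the AHP minimum sits
#'   at `threshold - ahp_depth`).
#' @param ahp_tau_ms recovery time constant from the AHP minimum, ms.
#' @return a named list of template parameters.
#' @export
spike_template <- function(threshold = -45, peak = 25,
                           tau_rise_ms = 0.3, tau_fall_ms = 0.5,
                           adp_amplitude = 5, adp_duration_ms = 5,
                           ahp_depth = 17, ahp_tau_ms = 10) {
  if (peak <= threshold) stop("spike peak must exceed threshold")
  assert_scalar_num(tau_rise_ms, "tau_rise_ms", positive = TRUE)
  assert_scalar_num(tau_fall_ms, "tau_fall_ms", positive = TRUE)
  assert_scalar_num(adp_amplitude, "adp_amplitude", nonneg = TRUE)
  assert_scalar_num(adp_duration_ms, "adp_duration_ms", positive = TRUE)
  assert_scalar_num(ahp_tau_ms, "ahp_tau_ms", positive = TRUE)
  if (ahp_depth <= 2)
    stop("ahp_depth must exceed 2 mV (the repolarization undershoot)")
  list(threshold = threshold, peak = peak, tau_rise_ms = tau_rise_ms,
       tau_fall_ms = tau_fall_ms, adp_amplitude = adp_amplitude,
       adp_duration_ms = adp_duration_ms, ahp_depth = ahp_depth,
       ahp_tau_ms = ahp_tau_ms)
}

#' A narrow low-threshold-like spike template
#'
#' Convenience preset for the narrow-half-width initial spike seen when
#' depolarizing from hyperpolarized potentials; half-width well below 1 ms,
#' no ADP hump, shallow AHP.
#' @param threshold,peak as in [spike_template()].
#' @export
narrow_spike_template <- function(threshold = -52, peak = 15) {
  spike_template(threshold = threshold, peak = peak,
                 tau_rise_ms = 0.08, tau_fall_ms = 0.12,
                 adp_amplitude = 0, adp_duration_ms = 1,
                 ahp_depth = 5, ahp_tau_ms = 4)
}

# Build one spike template as absolute voltages. Returns samples plus the
# (1-based) indices and exact voltages of threshold, peak and AHP minimum.
# v_pre / v_post are the underlying trace values at the splice boundaries.
#' @keywords internal
#' @noRd
build_spike_wave <- function(tpl, fs, v_pre, v_post) {
  dt_ms <- 1000 / fs
  thr <- tpl$threshold; pk <- tpl$peak
  A <- pk - thr
  ahp_v <- thr - tpl$ahp_depth
  l1 <- thr - 2  # repolarization undershoot level the ADP hump sits on

  # approach: half-cosine from v_pre to threshold; slope tapers to zero at
  # the junction so the 10%-of-max-dV/dt criterion lands on the threshold
  t_app <- 4
  n_app <- max(4L, round(t_app / dt_ms))
  k <- seq_len(n_app)
  approach <- v_pre + (thr - v_pre) * (1 - cos(pi * k / n_app)) / 2
  approach[n_app] <- thr
  i_thr <- n_app

  # upstroke: saturating exponential to 90% of the amplitude ...
  t90 <- tpl$tau_rise_ms * log(10)
  n_up <- max(2L, round(t90 / dt_ms))
  tu <- seq_len(n_up) * dt_ms
  up <- pk - A * exp(-tu / tpl$tau_rise_ms)
  # ... then a short cosine cap onto the exact peak sample
  t_cap <- max(2 * dt_ms, tpl$tau_rise_ms)
  n_cap <- max(2L, round(t_cap / dt_ms))
  kc <- seq_len(n_cap - 1L)
  a_cap <- pk - up[n_up]
  cap <- pk - a_cap * (1 + cos(pi * kc / n_cap)) / 2
  up <- c(up, cap, pk)
  i_peak <- i_thr + length(up)

  # repolarization toward the undershoot level
  t_fall <- tpl$tau_fall_ms * log((pk - l1) / 0.1)
  n_fall <- max(2L, round(t_fall / dt_ms))
  tf <- seq_len(n_fall) * dt_ms
  fall <- l1 + (pk - l1) * exp(-tf / tpl$tau_fall_ms)

  # ADP hump: half-sine riding on the undershoot level
  adp <- numeric(0)
  if (tpl$adp_amplitude > 0) {
    n_adp <- max(4L, round(tpl$adp_duration_ms / dt_ms))
    ka <- seq_len(n_adp)
    adp <- l1 + tpl$adp_amplitude * sin(pi * ka / (n_adp + 1L))
  }

  # descent into the AHP minimum (exact sample at the planted minimum)
  tau_desc <- 1.5
  t_desc <- tau_desc * log((l1 - ahp_v) / 0.05)
  n_desc <- max(2L, round(t_desc / dt_ms))
  td <- seq_len(n_desc) * dt_ms
  desc <- ahp_v + (l1 - ahp_v) * exp(-td / tau_desc)
  desc <- c(desc, ahp_v)
  i_ahp <- i_peak + length(fall) + length(adp) + length(desc)

  # recovery toward the post-splice level, then a short linear taper so the
  # trace is continuous at the right boundary
  gap <- v_post - ahp_v
  rec <- numeric(0)
  if (abs(gap) > 0.1) {
    t_rec <- tpl$ahp_tau_ms * log(abs(gap) / 0.1)
    n_rec <- max(2L, round(t_rec / dt_ms))
    tr <- seq_len(n_rec) * dt_ms
    rec <- v_post - gap * exp(-tr / tpl$ahp_tau_ms)
  }
  n_tap <- max(2L, round(0.5 / dt_ms))
  last <- if (length(rec)) rec[length(rec)] else ahp_v
  taper <- last + (v_post - last) * seq_len(n_tap) / n_tap

  samples <- c(approach, up, fall, adp, desc, rec, taper)
  list(samples = samples, i_threshold = i_thr, i_peak = i_peak,
       i_ahp = i_ahp, threshold = thr, peak = pk, ahp_voltage = ahp_v)
}

# Splice spike templates into a clean (noise-free) trace at the given onset
# indices. Returns the modified trace plus a ground-truth data frame.
#' @keywords internal
#' @noRd
splice_spikes <- function(x, fs, onsets, tpl, narrow_first = FALSE) {
  gt <- list()
  for (j in seq_along(onsets)) {
    i0 <- onsets[j]
    use_tpl <- if (narrow_first && j == 1L) narrow_spike_template() else tpl
    # provisional wave to learn the support length
    w <- build_spike_wave(use_tpl, fs, v_pre = x[i0],
                          v_post = x[i0])
    i1 <- i0 + length(w$samples) - 1L
    if (i1 > length(x))
      stop("spike template does not fit in the trace at the requested time")
    w <- build_spike_wave(use_tpl, fs, v_pre = x[i0], v_post = x[i1])
    i1 <- i0 + length(w$samples) - 1L
    if (i1 > length(x))
      stop("spike template does not fit in the trace at the requested time")
    x[i0:i1] <- w$samples
    gt[[j]] <- data.frame(
      onset_time = (i0 - 1L) / fs,
      threshold_time = (i0 + w$i_threshold - 2L) / fs,
      threshold = w$threshold,
      peak_time = (i0 + w$i_peak - 2L) / fs,
      peak_voltage = w$peak,
      ahp_time = (i0 + w$i_ahp - 2L) / fs,
      ahp_voltage = w$ahp_voltage,
      adp_present = use_tpl$adp_amplitude > 0,
      narrow = narrow_first && j == 1L)
  }
  list(trace = x,
       truth = if (length(gt)) do.call(rbind, gt) else empty_spike_truth())
}

#' @keywords internal
#' @noRd
empty_spike_truth <- function() {
  data.frame(onset_time = numeric(0), threshold_time = numeric(0),
             threshold = numeric(0), peak_time = numeric(0),
             peak_voltage = numeric(0), ahp_time = numeric(0),
             ahp_voltage = numeric(0), adp_present = logical(0),
             narrow = logical(0))
}

# Length (in samples) of a template spliced between equal boundary levels.
#' @keywords internal
#' @noRd
template_support <- function(tpl, fs, v_level) {
  length(build_spike_wave(tpl, fs, v_level, v_level)$samples)
}

#' Generate intracellular current-step sweeps with known ground truth
#'
#' Emulates the evoked-firing protocol: from the protocol's holding
#' potential, square current steps are injected in successive sweeps (the
#' source protocol used 1 s steps from 0 to 800 pA in 50 pA increments from
#' -80 mV, preceded by -100 and -50 pA steps for input-resistance
#' estimation). Each sweep is the passive single-exponential RC response
#' (tau = R*C) plus spliced spike templates, the SSTO sinusoid and Gaussian
#' noise.
#'
#' Spikes are only planted in sweeps whose steady-state plateau lies at
#' least 2 mV above the template's AHP minimum; otherwise the post-spike
#' minimum would be the plateau rather than the AHP and the planted AHP
#' ground truth would be meaningless. With `spikes_per_sweep = NULL` the
#' planted count grows with the injected current above that rheobase.
#'
#' @param params a [synth_ephys_params()].
#' @param protocol a [step_protocol()].
#' @param spikes_per_sweep integer vector (recycled) of planted spike counts
#'   per sweep, or `NULL` for the default current-dependent rule.
#' @param narrow_first if `TRUE`, the first planted spike of each sweep uses
#'   the narrow low-threshold template.
#' @return a list with elements `sweeps` (a [sweep_set()]) and `truth` (a
#'   list of per-sweep data frames of planted spike times, thresholds, peaks
#'   and AHP minima).
#' @export
gen_intracellular_sweeps <- function(params, protocol,
                                     spikes_per_sweep = NULL,
                                     narrow_first = FALSE) {
  stopifnot(inherits(params, "synth_ephys_params"),
            inherits(protocol, "step_protocol"))
  fs <- params$sampling_rate
  total_s <- protocol$onset + protocol$duration + protocol$tail
  n <- round(total_s * fs)
  if (round(protocol$onset * fs) + round(protocol$duration * fs) > n)
    stop("protocol step does not fit in the trace length")
  tau_s <- params$membrane_R * params$membrane_C * 1e-6  # MOhm * pF -> s
  tpl <- params$spike_template
  ahp_v <- tpl$threshold - tpl$ahp_depth
  hold <- protocol$holding_potential
  tt <- (seq_len(n) - 1L) / fs
  i_on <- round(protocol$onset * fs) + 1L
  i_off <- i_on + round(protocol$duration * fs) - 1L

  if (is.null(spikes_per_sweep)) {
    plateau <- hold + params$membrane_R * protocol$amplitudes / 1000
    rheo_ok <- plateau >= ahp_v + 2 & protocol$amplitudes > 0
    i_rheo <- if (any(rheo_ok)) min(protocol$amplitudes[rheo_ok]) else Inf
    spikes_per_sweep <- ifelse(
      rheo_ok, 1L + pmin(7L, floor((protocol$amplitudes - i_rheo) / 100)), 0L)
  } else {
    spikes_per_sweep <- rep_len(as.integer(spikes_per_sweep),
                                protocol$sweep_count)
  }

  set.seed(params$seed)
  ssto <- if (params$ssto_amplitude > 0) {
    (params$ssto_amplitude / 2) * sin(2 * pi * params$ssto_frequency * tt)
  } else 0

  sweeps <- vector("list", protocol$sweep_count)
  truth <- vector("list", protocol$sweep_count)
  for (s in seq_len(protocol$sweep_count)) {
    amp <- protocol$amplitudes[s]
    defl <- params$membrane_R * amp / 1000  # mV
    x <- rep(hold, n)
    seg <- i_on:i_off
    x[seg] <- hold + defl * (1 - exp(-(tt[seg] - tt[i_on]) / tau_s))
    # relaxation back to holding after the step
    if (i_off < n) {
      v_off <- x[i_off]
      post <- (i_off + 1L):n
      x[post] <- hold + (v_off - hold) * exp(-(tt[post] - tt[i_off]) / tau_s)
    }
    x <- x + ssto

    n_spk <- spikes_per_sweep[s]
    if (n_spk > 0L) {
      plateau <- hold + defl
      if (plateau < ahp_v + 2)
        stop(sprintf(
          "sweep %d: steady-state plateau (%.1f mV) is below the AHP minimum + 2 mV (%.1f mV); cannot plant spikes with well-defined AHP ground truth",
          s, plateau, ahp_v + 2))
      settle <- max(0.05, 6 * tau_s)
      support <- max(template_support(tpl, fs, plateau),
                     if (narrow_first) template_support(
                       narrow_spike_template(), fs, plateau) else 0L)
      avail <- round(protocol$duration * fs) - round(settle * fs) - support
      gap <- if (n_spk > 1L) floor(avail / (n_spk - 1L)) else 0L
      if (avail < 0L || (n_spk > 1L && gap < support + round(0.005 * fs)))
        stop(sprintf("sweep %d: %d spikes do not fit in the step", s, n_spk))
      onsets <- i_on + round(settle * fs) + (seq_len(n_spk) - 1L) * gap
      sp <- splice_spikes(x, fs, onsets, tpl, narrow_first = narrow_first)
      x <- sp$trace
      truth[[s]] <- sp$truth
    } else {
      truth[[s]] <- empty_spike_truth()
    }
    if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
    sweeps[[s]] <- ts_trace(x, fs, "voltage")
  }
  list(sweeps = sweep_set(sweeps, protocol$amplitudes, protocol),
       truth = truth)
}

#' Generate a spontaneous-activity trace with SSTOs
#'
#' Baseline plus a sinusoidal subthreshold oscillation
#' (`baseline_vm + (ssto_amplitude/2) * sin(2*pi*f*t)`), Gaussian noise, and
#' optional spontaneous spikes at a Poisson rate (thinned so templates never
#' overlap).
#'
#' @param params a [synth_ephys_params()].
#' @param duration trace duration, seconds (> 0).
#' @param spont_rate spontaneous spike rate, Hz.
#' @return list with `trace` (a voltage [ts_trace()]) and `truth` (planted
#'   spike data frame as in [gen_intracellular_sweeps()]).
#' @export
gen_ssto_trace <- function(params, duration, spont_rate = 0) {
  stopifnot(inherits(params, "synth_ephys_params"))
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(spont_rate, "spont_rate", nonneg = TRUE)
  fs <- params$sampling_rate
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  set.seed(params$seed)
  x <- params$baseline_vm +
    (params$ssto_amplitude / 2) * sin(2 * pi * params$ssto_frequency * tt)
  truth <- empty_spike_truth()
  if (spont_rate > 0) {
    support_s <- template_support(params$spike_template, fs,
                                  params$baseline_vm) / fs
    times <- poisson_times(spont_rate, duration - 2 * support_s,
                           refractory = support_s + 0.01)
    onsets <- round(times * fs) + 1L
    onsets <- onsets[onsets > 1L]
    if (length(onsets)) {
      sp <- splice_spikes(x, fs, onsets, params$spike_template)
      x <- sp$trace
      truth <- sp$truth
    }
  }
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
  list(trace = ts_trace(x, fs, "voltage"), truth = truth)
}

#' Generate a voltage-clamp step current transient
#'
#' Ideal single-compartment response to a square command step `delta_v`
#' recorded through access resistance `R_s`: instantaneous peak
#' `delta_v / R_s`, exponential decay with time constant
#' `C * (R_s * R_m) / (R_s + R_m)` to the steady state
#' `delta_v / (R_s + R_m)`. Used as ground truth for [capacitance_from_step()]
#' and [series_resistance()].
#'
#' @param R_m membrane resistance, MOhm.
#' @param C capacitance, pF.
#' @param R_s series (access) resistance, MOhm.
#' @param delta_v command step, mV (default 10, as in the capacitance
#'   protocol: a 10 mV step from -80 mV).
#' @param sampling_rate Hz.
#' @param pre,dur pre-step baseline and step durations, seconds.
#' @param noise_sd current noise SD, pA.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return a current [ts_trace()] (baseline-subtracted, pA).
#' @export
gen_vc_transient <- function(R_m = 230, C = 100, R_s = 1, delta_v = 10,
                             sampling_rate = 1e5, pre = 0.02, dur = 0.2,
                             noise_sd = 0, seed = 1L) {
  assert_scalar_num(R_m, "R_m", positive = TRUE)
  assert_scalar_num(C, "C", positive = TRUE)
  assert_scalar_num(R_s, "R_s", positive = TRUE)
  if (delta_v == 0) stop("zero command step: transient undefined")
  fs <- sampling_rate
  n_pre <- round(pre * fs); n_dur <- round(dur * fs)
  i_peak <- 1000 * delta_v / R_s                 # pA
  i_ss <- 1000 * delta_v / (R_s + R_m)           # pA
  tau <- C * (R_s * R_m / (R_s + R_m)) * 1e-6    # s
  t <- (seq_len(n_dur) - 1L) / fs
  x <- c(rep(0, n_pre), i_ss + (i_peak - i_ss) * exp(-t / tau))
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(length(x), 0, noise_sd)
  }
  ts_trace(x, fs, "current")
}
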