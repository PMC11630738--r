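fs_test <- 2e4

gen_fi_sweeps <- function(noise_sd, seed, amplitudes = seq(0, 800, by = 50)) {
  p <- synth_ephys_params(sampling_rate = fs_test, noise_sd = noise_sd,
                          membrane_R = 100, membrane_C = 100, seed = seed)
  proto <- step_protocol(amplitudes, onset = 0.1, duration = 1,
                         holding_potential = -80)
  gen_intracellular_sweeps(p, proto)
}

test_that("spike detection recovers planted events at planted times", {
  g <- gen_fi_sweeps(noise_sd = 0.2, seed = 1)
  for (i in seq_along(g$sweeps$sweeps)) {
    ev <- detect_spikes(g$sweeps$sweeps[[i]])
    ev <- ev[ev$peak_time >= 0.1 & ev$peak_time <= 1.1, , drop = FALSE]
    tru <- g$truth[[i]]
    expect_equal(nrow(ev), nrow(tru))
    if (nrow(tru))
      expect_lt(max(abs(ev$peak_time - tru$peak_time)), 5e-4)
  }
})

test_that("a flat trace yields no spikes and short traces error", {
  tr <- ts_trace(rep(-70, 2000), fs_test, "voltage")
  expect_equal(nrow(detect_spikes(tr)), 0)
  expect_error(detect_spikes(ts_trace(rep(-70, 5), fs_test, "voltage")),
               "short")
})

test_that("two spikes within the refractory window merge into one event", {
  # two triangular 30 mV spikes 1 ms apart, refractory 2 ms
  fs <- 5e4
  x <- rep(-70, 5000)
  mk <- function(x, i0) {
    up <- seq(0, 60, length.out = 16); down <- seq(60, 0, length.out = 31)[-1]
    x[i0:(i0 + 45)] <- -70 + c(up, down)
    x
  }
  x <- mk(x, 2000)                  # peak ~ t = 40.3 ms
  x <- mk(x, 2000 + round(0.001 * fs))  # 1 ms later
  ev <- detect_spikes(ts_trace(x, fs, "voltage"))
  expect_equal(nrow(ev), 1)
})

test_that("threshold criterion lands at the known 10% dV/dt crossing", {
  # piecewise-linear rise: 5 mV/ms to -48 mV, then 100 mV/ms to 0 mV
  fs <- 1e5
  seg1 <- seq(-60, -48, by = 5 / (fs / 1000))
  seg2 <- seq(-48, 0, by = 100 / (fs / 1000))
  seg3 <- seq(0, -65, by = -2 / (fs / 1000))
  x <- c(rep(-60, 1000), seg1, seg2, seg3, rep(-65, 1000))
  tr <- ts_trace(x, fs, "voltage")
  ev <- detect_spikes(tr)
  expect_equal(nrow(ev), 1)
  thr <- compute_threshold(tr, ev[1, ])
  expect_equal(thr$threshold_voltage, -48, tolerance = 0.5)
  # uniform time rescaling (same samples, half the rate) leaves it unchanged
  tr2 <- ts_trace(x, fs / 2, "voltage")
  ev2 <- detect_spikes(tr2)
  thr2 <- compute_threshold(tr2, ev2[1, ])
  expect_equal(thr2$threshold_voltage, thr$threshold_voltage,
               tolerance = 0.25)
  # additive offset shifts the threshold by exactly the offset
  tr3 <- ts_trace(x + 7, fs, "voltage")
  thr3 <- compute_threshold(tr3, detect_spikes(tr3)[1, ])
  expect_equal(thr3$threshold_voltage, thr$threshold_voltage + 7,
               tolerance = 0.05)
})

test_that("threshold recovery matches generator ground truth within 0.5 mV", {
  g <- gen_fi_sweeps(noise_sd = 0, seed = 2, amplitudes = c(300, 600))
  for (i in 1:2) {
    tr <- g$sweeps$sweeps[[i]]
    fe <- extract_spike_features(tr, step_start = 0.1, step_end = 1.1)
    expect_equal(fe$threshold_voltage, g$truth[[i]]$threshold,
                 tolerance = 0.5)
  }
})

test_that("AHP depth is the reference level minus the window minimum", {
  g <- gen_fi_sweeps(noise_sd = 0, seed = 3, amplitudes = 400)
  tr <- g$sweeps$sweeps[[1]]
  fe <- extract_spike_features(tr, step_start = 0.1, step_end = 1.1)
  tru <- g$truth[[1]]
  # planted: threshold -45, AHP minimum -62 -> depth from threshold 17
  expect_equal(fe$ahp_voltage, tru$ahp_voltage, tolerance = 0.05)
  expect_equal(fe$ahp_depth_from_threshold,
               fe$threshold_voltage - fe$ahp_voltage)
  expect_equal(fe$ahp_depth_from_threshold[1], 17, tolerance = 0.1)
  # depth from a stated baseline: -60 baseline, -66 minimum -> 6 mV
  fs <- 1e4
  x <- c(rep(-60, 1000), seq(-60, 20, length.out = 20),
         seq(20, -66, length.out = 40), seq(-66, -60, length.out = 2000),
         rep(-60, 1000))
  trb <- ts_trace(x, fs, "voltage")
  ev <- detect_spikes(trb)
  ahp <- measure_ahp(trb, ev[1, ], window_end = length(x) / fs,
                     reference = "baseline", baseline_vm = -60,
                     smooth_ms = 0)
  expect_equal(ahp$depth, 6, tolerance = 1e-6)
  # monotonically depolarizing post-spike segment: minimum is the first
  # post-peak sample
  xm <- c(rep(-70, 500), seq(-70, 10, length.out = 10),
          seq(-40, -20, length.out = 3000))
  trm <- ts_trace(xm, fs, "voltage")
  evm <- data.frame(peak_index = 510L)
  ahpm <- measure_ahp(trm, evm, window_end = length(xm) / fs,
                      reference = "baseline", baseline_vm = -70,
                      smooth_ms = 0)
  expect_equal(ahpm$ahp_index, 511L)
  expect_error(measure_ahp(trm, evm, window_end = 505 / fs,
                           reference = "baseline", baseline_vm = -70),
               "empty")
})

test_that("spike classification applies the narrow-first-spike rule", {
  cfg <- feature_config()
  expect_equal(classify_spike(0.4, is_first = TRUE, cfg), "low_threshold")
  expect_equal(classify_spike(2.5, is_first = TRUE, cfg), "typical")
  expect_equal(classify_spike(0.4, is_first = FALSE, cfg), "typical")
})

test_that("ADP hump detection follows the prominence rule", {
  mk <- function(adp) {
    tpl <- spike_template(adp_amplitude = adp)
    p <- synth_ephys_params(sampling_rate = fs_test, noise_sd = 0,
                            membrane_R = 100, membrane_C = 100,
                            spike_template = tpl, seed = 4)
    proto <- step_protocol(400, onset = 0.1, duration = 1,
                           holding_potential = -80)
    g <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = 1)
    extract_spike_features(g$sweeps$sweeps[[1]], step_start = 0.1,
                           step_end = 1.1)$adp_present
  }
  expect_true(mk(5))
  expect_false(mk(0))
  expect_false(mk(0.5))  # below the 1 mV default prominence
})

test_that("F-I curve reproduces planted counts and the exclusion rule", {
  p <- synth_ephys_params(sampling_rate = fs_test, noise_sd = 0.2,
                          membrane_R = 100, membrane_C = 100, seed = 5)
  proto <- step_protocol(c(0, 100, 300, 500, 700), onset = 0.1, duration = 1,
                         holding_potential = -80)
  g <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = c(0, 0, 1, 3, 5))
  fi <- fi_curve(g$sweeps)
  expect_equal(fi$spike_count, c(0, 0, 1, 3, 5))
  expect_true(all(fi$spike_count >= 0))
  # all-subthreshold sweeps -> all zeros
  g0 <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = 0)
  expect_equal(fi_curve(g0$sweeps)$spike_count, rep(0L, 5))
  # planted narrow initial spike + 3 typical, exclusion on -> 3
  g1 <- gen_intracellular_sweeps(p, step_protocol(500, onset = 0.1,
                                                  duration = 1,
                                                  holding_potential = -80),
                                 spikes_per_sweep = 4, narrow_first = TRUE)
  fi_all <- fi_curve(g1$sweeps, exclude_low_threshold = FALSE)
  fi_ex <- fi_curve(g1$sweeps, exclude_low_threshold = TRUE)
  expect_equal(fi_all$spike_count, 4)
  expect_equal(fi_ex$spike_count, 3)
})

test_that("AHP recovery rate matches a least-squares oracle", {
  fs <- 1e4
  # linear recovery: 5 mV over 10 ms -> 0.5 mV/ms
  x <- c(rep(-60, 100), seq(-65, -60, length.out = 101),
         rep(-60, 500))
  tr <- ts_trace(x, fs, "voltage")
  r <- ahp_recovery_rate(tr, ahp_index = 101L, baseline_vm = -60,
                         window_end = length(x) / fs)
  expect_equal(r, 0.5, tolerance = 1e-6)
  # flat post-AHP segment: 0 mV/ms
  xf <- c(rep(-60, 100), rep(-65, 2000))
  rf <- ahp_recovery_rate(ts_trace(xf, fs, "voltage"), 150L, -60,
                          window_end = length(xf) / fs)
  expect_equal(rf, 0)
  # exponential recovery: slope equals an explicit regression oracle
  t_ms <- seq(0, 50, by = 1000 / fs / 10)
  xe <- c(rep(-60, 10), -60 - 8 * exp(-t_ms / 8))
  tre <- ts_trace(xe, fs, "voltage")
  r_pkg <- ahp_recovery_rate(tre, 11L, -60, window_end = length(xe) / fs)
  # oracle: lm on the same window definition, built independently
  gap <- -60 - xe[11]
  target <- xe[11] + 0.9 * gap
  i_end <- 10L + which(xe[-(1:10)] >= target)[1]
  tt <- (seq(11L, i_end) - 11L) * 1000 / fs
  r_lm <- unname(stats::coef(stats::lm(xe[11:i_end] ~ tt))[2])
  expect_equal(r_pkg, r_lm, tolerance = 0.02 * abs(r_lm))
})

test_that("SSTO metrics recover the planted oscillation and spike rate", {
  p <- synth_ephys_params(sampling_rate = 1e4, ssto_amplitude = 10,
                          ssto_frequency = 5, baseline_vm = -60,
                          noise_sd = 0, seed = 1)
  m <- ssto_metrics(gen_ssto_trace(p, 10)$trace)
  expect_equal(m$resting_vm_estimate, -60, tolerance = 0.01)
  expect_equal(m$ssto_frequency, 5, tolerance = 0.11)
  expect_equal(m$ssto_amplitude, 10, tolerance = 0.1)
  expect_equal(m$spontaneous_spike_rate, 0)
  # planted spontaneous spikes over 100 s: rate equals planted count/duration
  p2 <- synth_ephys_params(sampling_rate = 1e4, ssto_amplitude = 8,
                           ssto_frequency = 4, baseline_vm = -60,
                           noise_sd = 0.2, seed = 2)
  g2 <- gen_ssto_trace(p2, 100, spont_rate = 2)
  m2 <- ssto_metrics(g2$trace)
  expect_equal(m2$spontaneous_spike_rate, nrow(g2$truth) / 100,
               tolerance = 1e-8)
  expect_gt(nrow(g2$truth), 2 * 100 - 4 * sqrt(200))  # Poisson-range planting
  # white noise: no spectral peak -> frequency and amplitude reported as 0
  pn <- synth_ephys_params(sampling_rate = 1e4, ssto_amplitude = 0,
                           baseline_vm = -60, noise_sd = 0.5, seed = 3)
  mn <- ssto_metrics(gen_ssto_trace(pn, 12)$trace)
  expect_equal(mn$ssto_frequency, 0)
  expect_equal(mn$ssto_amplitude, 0)
  expect_error(ssto_metrics(gen_ssto_trace(pn, 5)$trace), "10 s")
})
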