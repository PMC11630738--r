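test_that("passive step response obeys Ohm's law exactly", {
  p <- synth_ephys_params(sampling_rate = 2e4, noise_sd = 0,
                          membrane_R = 100, membrane_C = 100, seed = 1)
  proto <- step_protocol(-100, onset = 0.1, duration = 1,
                         holding_potential = -80)
  g <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = 0)
  x <- g$sweeps$sweeps[[1]]$samples
  i_end <- round(1.1 * 2e4)
  expect_equal(x[i_end] - (-80), -10, tolerance = 1e-12)
})

test_that("generators are bit-identical for identical seeds", {
  p <- synth_ephys_params(sampling_rate = 1e4, seed = 42)
  proto <- step_protocol(seq(0, 400, by = 200), onset = 0.05, duration = 0.4,
                         tail = 0.05)
  g1 <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = c(0, 1, 2))
  g2 <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = c(0, 1, 2))
  expect_identical(g1$sweeps$sweeps[[3]]$samples, g2$sweeps$sweeps[[3]]$samples)
  expect_identical(g1$truth, g2$truth)
  e <- synth_extracell_params(duration = 5, seed = 7)
  expect_identical(gen_extracellular_recording(e)$trace$samples,
                   gen_extracellular_recording(e)$trace$samples)
  m <- synth_morph_params(seed = 9)
  expect_identical(gen_morphology(m)$tree, gen_morphology(m)$tree)
})

test_that("planted spikes carry the constructed threshold and AHP truth", {
  tpl <- spike_template(threshold = -45, peak = 25, ahp_depth = 17)
  p <- synth_ephys_params(sampling_rate = 2e4, noise_sd = 0,
                          membrane_R = 100, membrane_C = 100,
                          spike_template = tpl, seed = 3)
  proto <- step_protocol(400, onset = 0.1, duration = 1,
                         holding_potential = -80)
  g <- gen_intracellular_sweeps(p, proto, spikes_per_sweep = 5)
  tru <- g$truth[[1]]
  expect_equal(nrow(tru), 5)
  expect_equal(tru$threshold, rep(-45, 5))
  expect_equal(tru$ahp_voltage, rep(-62, 5))
  expect_equal(tru$peak_voltage, rep(25, 5))
  # conservation: event count equals ground-truth length
  expect_equal(nrow(tru), 5L)
})

test_that("SSTO trace is the stated sinusoid", {
  p <- synth_ephys_params(sampling_rate = 1e4, ssto_amplitude = 10,
                          ssto_frequency = 5, baseline_vm = -60,
                          noise_sd = 0, seed = 1)
  g <- gen_ssto_trace(p, 10)
  x <- g$trace$samples
  expect_equal(max(x) - min(x), 10, tolerance = 1e-6)
  # duration 10 s at 3 Hz -> exactly 30 full cycles (upward crossings)
  p3 <- synth_ephys_params(sampling_rate = 1e4, ssto_amplitude = 6,
                           ssto_frequency = 3, baseline_vm = -60,
                           noise_sd = 0, seed = 1)
  x3 <- gen_ssto_trace(p3, 10)$trace$samples - (-60)
  up <- sum(x3[-1] > 0 & x3[-length(x3)] <= 0)
  expect_equal(up, 30)
})

test_that("parameter invariants are enforced", {
  expect_error(synth_ephys_params(sampling_rate = 0), "sampling_rate")
  expect_error(synth_ephys_params(noise_sd = -1), "noise_sd")
  expect_error(spike_template(threshold = -45, peak = -50), "exceed")
  expect_error(synth_extracell_params(ss_amplitude = 2, cs_amplitude = 1),
               "cs_amplitude")
  expect_error(synth_extracell_params(refractory = 0.0005), "refractory")
  expect_error(gen_ssto_trace(synth_ephys_params(), duration = -1),
               "duration")
})

test_that("extracellular generator respects rates and amplitude ordering", {
  # cs_rate 1 Hz over 300 s: planted count within Poisson sampling error
  e <- synth_extracell_params(ss_rate = 0.01, cs_rate = 1, duration = 300,
                              noise_sd = 0, sampling_rate = 1e4, seed = 5)
  g <- gen_extracellular_recording(e)
  expect_gt(length(g$true_cs_times), 300 - 4 * sqrt(300))
  expect_lt(length(g$true_cs_times), 300 + 4 * sqrt(300))
  # noise-free: every planted CS peak exceeds every planted SS peak
  e2 <- synth_extracell_params(ss_rate = 40, cs_rate = 1, ss_amplitude = 1,
                               cs_amplitude = 2, duration = 20,
                               noise_sd = 0, sampling_rate = 1e4, seed = 6)
  g2 <- gen_extracellular_recording(e2)
  x <- g2$trace$samples
  fs <- g2$trace$sampling_rate
  cs_peaks <- x[round(g2$true_cs_times * fs) + 1L]
  ss_peaks <- x[round(g2$true_ss_times * fs) + 1L]
  expect_true(min(cs_peaks) > max(ss_peaks))
  # ss_rate = 0: only CS waveforms in the trace
  e3 <- synth_extracell_params(ss_rate = 0, cs_rate = 2, duration = 10,
                               noise_sd = 0, sampling_rate = 1e4, seed = 8)
  g3 <- gen_extracellular_recording(e3)
  expect_length(g3$true_ss_times, 0)
  expect_gt(length(g3$true_cs_times), 0)
})

test_that("transcriptome generator plants the stated flag structure", {
  # zero background rate: no DEGs at all
  g0 <- gen_transcriptome(synth_transcriptome_params(
    n_genes = 5000, n_channel_genes = 100, n_intrinsic = 60,
    deg_rate_background = 0, seed = 1))
  expect_equal(sum(g0$is_deg), 0)
  expect_equal(sum(g0$is_rescued), 0)
  # odds multiplier 1: channel DEG proportion matches background
  # (binomial error over 50 seeds)
  n_ch <- 0; n_bg <- 0; ch_deg <- 0; bg_deg <- 0
  for (s in 1:50) {
    g <- gen_transcriptome(synth_transcriptome_params(
      n_genes = 4000, n_channel_genes = 400, n_intrinsic = 200,
      deg_rate_background = 0.05, deg_odds_channels = 1, seed = s))
    ch_deg <- ch_deg + sum(g$is_deg & g$is_channel)
    bg_deg <- bg_deg + sum(g$is_deg & !g$is_channel)
    n_ch <- n_ch + sum(g$is_channel); n_bg <- n_bg + sum(!g$is_channel)
  }
  p_ch <- ch_deg / n_ch; p_bg <- bg_deg / n_bg
  se <- sqrt(0.05 * 0.95 * (1 / n_ch + 1 / n_bg))
  expect_lt(abs(p_ch - p_bg), 4 * se)
  # structural invariants
  g <- gen_transcriptome(synth_transcriptome_params(
    n_genes = 1000, n_channel_genes = 50, n_intrinsic = 30, seed = 2))
  expect_true(all(g$channel_class[g$is_channel] != "none"))
  expect_true(all(!g$is_rescued | g$is_deg))
  expect_equal(sum(g$channel_class == "intrinsic"), 30)
})
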