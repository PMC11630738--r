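---
title: "Methods and design notes for olivetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for olivetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivetools)
```

`olivetools` packages the quantitative procedures used to characterize
inferior olive (IO) neuron hypertrophy and hyperexcitability: intracellular
spike and subthreshold-oscillation feature extraction, passive membrane
properties, complex-spike identification in extracellular Purkinje-cell
recordings, single-neuron morphometrics, design-based stereology, and
ion-channel gene-set enrichment. This vignette explains the measurement
rules, the unit and parameter conventions, the synthetic-data generators
that make the pipeline testable, and the design choices taken where the
underlying procedures are conventionally under-specified.

## Units and conventions

All voltages are mV, currents pA, times s (ms for widths and time
constants), lengths um. Resistances are MOhm via MOhm = 1000 mV/pA;
capacitance is pF, so specific resistance R/C is MOhm/pF and charge
integrates to pC (1 pA s). Depolarizing current is positive. Voltages are
absolute, not baseline-subtracted, and are reported after liquid-junction
correction: `correct_junction_potential()` shifts every voltage sample by
-jp (default 10 mV, the value previously calculated for the recording
solutions) exactly once — a second application errors rather than silently
double-correcting.

## Intracellular spike features

**Detection.** Candidate spikes are local maxima preceded (within 10 ms)
by a smoothed dV/dt above `dvdt_min` (default 10 mV/ms) with topographic
prominence of at least `min_prominence` (default 20 mV); events closer
than `refractory` (default 2 ms) merge, keeping the larger peak. dV/dt is
computed by central differences on a boxcar-smoothed trace (`smooth_ms`,
default 0.1 ms): at 100 kHz acquisition the raw sample-to-sample
derivative is too noisy to anchor a 10%-of-maximum criterion. Two spikes
closer than the refractory window are reported as one event; this is a
documented limitation, not a failure mode, and matches how overlapping
events are treated in practice.

**Threshold.** The threshold is the voltage at the earliest sample of the
rising phase where dV/dt first reaches 10% of that spike's maximum dV/dt.
The rising phase runs from the last local minimum preceding the peak to
the peak, which is unambiguous even on oscillating baselines. Because the
criterion is a ratio of slopes it is invariant to uniform time rescaling
and commutes with additive voltage offsets. The reported voltage is read
off the lightly smoothed trace; at high sampling rates the raw sample
would add avoidable noise to a quantity that is compared across cells at
sub-millivolt resolution.

**AHP and ADP.** The afterhyperpolarization is the most negative membrane
potential in the post-spike window, which ends at the next spike's
threshold crossing or at the step offset. The window starts at the spike
peak (whether it should start at threshold re-crossing instead is not
conventionally fixed; the peak convention is the default and the window is
an explicit argument). Depth is reported from the spike's own threshold
and, when a baseline is given, from that baseline. The minimum is taken on
a 0.5 ms boxcar-smoothed trace: the AHP is a slow feature and the smoothed
minimum measures the trough rather than the single deepest noise
excursion (`smooth_ms = 0` restores the raw rule). The
afterdepolarization "hump" characteristic of IO principal neurons is
flagged when a local maximum with prominence >= 1 mV lies between peak and
AHP minimum, or when the repolarization slope changes sign above threshold
level.

**Half-width and spike classes.** Half-width is the full width at the
voltage midway between threshold and peak (the dominant convention;
crossings are linearly interpolated). A spike is classed `low_threshold`
iff it is the first spike of its step and its half-width is below
`lt_halfwidth_max` (default 1.0 ms — the narrow initial spike evoked from
hyperpolarized holding); F-I curves can exclude these, mirroring analyses
restricted to typical wide IO spikes.

**Recovery rate.** The post-AHP depolarization rate is the least-squares
slope from the AHP minimum to the first sample recovering 90% of the gap
back to the pre-spike baseline (mean voltage over the 50 ms before
threshold crossing), or to the window end if 90% is never reached.

## SSTO metrics

IO neurons show spontaneous subthreshold oscillations, so a resting
potential cannot be read directly; the estimate is the mean over 10 s of
the spike-masked trace (spikes masked +/- 20 ms and linearly
interpolated). The SSTO frequency is the maximal periodogram peak within
0.5-15 Hz. Whether a peak counts at all is decided on a segment-averaged
(8-segment Welch) spectrum: raw periodogram bins are exponentially
distributed, so the largest raw bin exceeds any fixed multiple of the
median even for white noise, whereas after averaging the `peak_snr`
criterion (default 3x the in-band median) cleanly rejects noise — a
noise-only trace reports frequency 0 and amplitude 0. Amplitude is the
mean peak-to-trough excursion over cycles delimited by upward mean
crossings, measured on a trace smoothed over 1/40 of the cycle so the
excursion reflects the oscillation rather than the per-cycle noise
extremes (the attenuation of a sinusoid by that window is 0.1%). A
cycle-counting cross-check of the spectral frequency is implicit in the
cycle segmentation: the two agree on every synthetic fixture tested.

## Passive properties

Input resistance is the least-squares slope of steady-state deflection
(mean over the last 20% of the step, minus the pre-step baseline) against
injected current over spike-free steps — the protocol injects -100 and
-50 pA steps before the depolarizing series precisely so this fit exists;
steps containing detected spikes are excluded. Capacitance comes from a
10 mV voltage-clamp step from -80 mV as C = Q/dV, where Q is the
trapezoidal integral of the transient above the steady state (last 20% of
the step), integrated from the step onset to the first sustained (>= 1 ms)
return to within noise of the steady state, with a floor of 1e-4 of the
peak so the truncated tail is negligible relative to the 0.1% accuracy
verified on ideal fixtures. Series resistance is dV divided by the peak
transient current above the pre-step baseline. On a generated
single-compartment transient the C estimate carries the factor
`(R_m/(R_m+R_s))^2` inherent to the charge method; with the default
R_s = 1 MOhm this is a 0.9% effect.

## Extracellular complex-spike identification

Analysis runs on 10 Hz high-pass filtered traces. The filter applies the
squared magnitude response of a 4th-order Butterworth high-pass in the
frequency domain with reflection padding: this is magnitude-equivalent to
forward-backward (zero-phase) filtering, shifts no event times, and is
numerically robust at very low normalized cutoffs (10 Hz at 100 kHz
sampling), where time-domain IIR coefficients become ill-conditioned. The
58-62 Hz notch exists for display parity only; the analysis path never
uses it.

Events are peaks above `noise_k` (default 4) times the robust noise level
(MAD), with a floor of 5% of the largest excursion so that noise-free
synthetic traces — where the MAD degenerates toward zero — do not admit
filter ripple as events; peaks closer than 2 ms merge. The identification
criterion — a complex spike must exceed the maximum simple-spike peak of
the entire trace — is circular as stated (the simple-spike maximum is only
known once complex spikes are removed). It is made operational by splitting
the sorted peak-amplitude distribution at its largest gap, searched in the
upper half of the distribution (complex spikes are the rare, large class,
so the split cannot be hijacked by stray small detections); the amplitude
threshold is the largest provisional simple-spike peak, complex spikes are
strictly above it, and a relative gap below `min_gap_ratio` (default 1.2)
reports zero complex spikes with a warning. A `manual_threshold` override
is available. Recordings shorter than 60 s warn (an acquisition
guideline, not an analysis gate).

## Morphometry

SWC reconstructions are validated on read (unique ids, a single root,
resolvable parents, no cycles; multi-root files are rejected rather than
silently merged). Tips are childless non-soma nodes, bifurcations nodes
with >= 2 children, total length the sum of Euclidean parent-child
segment lengths over dendrite nodes; width/height/depth are the
bounding-box extents along x/y/z — the axis assignment is a convention,
documented and stable under the rigid-motion invariance tests. Soma
surface area is 4 pi r^2 for a single-node soma and the frustum
lateral-area sum for multi-node somas.

The fractal (Hausdorff) dimension is estimated by box counting: the arbor
is resampled at <= 0.25 um arc-length spacing, occupied boxes N(eps) are
counted over a geometric ladder of >= 8 box sizes, and the dimension is
the negative slope of log N(eps) vs log eps (fit R^2 is reported
alongside). The default ladder spans 1 um to a quarter of the largest
extent. For validation fixtures the ladder is kept well inside the
scaling regime (eps up to 1/20 of the extent): near eps ~ extent/4 the
`+1` boundary boxes flatten the slope of any finite object, a finite-size
effect, not an estimator defect. A 1000 um line scores 0.99, a filled
100 um plane 1.97.

## Stereology

The fractionator estimate is `N_hat = sum(Q-) * (1/ssf) * (1/asf) *
(1/tsf)`. The implemented design mirrors the IO counts: 30 um sections at
evaluation interval 4, a 200 x 200 um counting frame on a 50 x 50 um
grid, 20 um counting depth ("~20 um" is implemented as an exact
configurable 20), 1 um guard zones. A frame larger than its grid step
means asf > 1 — overlapping frames, with cells legitimately counted in
several frames; that is how the design is stated and it is implemented as
such (the constructor warns, since asf <= 1 is the usual arrangement, and
the estimator remains unbiased either way). Counting follows the
top-of-cell rule: a cell counts iff its top lies strictly inside the frame
(left and bottom are exclusion edges, right and top inclusion edges — the
conventional assignment, which the source does not state) and within the
counting depth below the guard zone. The volume companion is the Cavalieri
estimator `V_hat = sum(areas) * interval * thickness`; no volume estimator
is named for the reported nuclear volumes, and Cavalieri is the standard
companion on the same sampled sections — recorded here as an assumption.
The Gundersen-Jensen CE uses the smoothness-class m = 1 variant
(`VarSURS = (3(A - n) - 4B + C)/240`), standard for smoothly varying
structures, with m = 0 behind a flag. The nucleator area is
`pi * mean(l_i^2)` over 4 systematic rays: exact for circles centred on
the reference point and unbiased over isotropic orientations for
star-shaped profiles, verified to 1% over 10^4 random ellipses.

## Enrichment

Gene tables carry per-gene flags (`is_channel`, `channel_class`,
`is_deg`, `is_rescued`). The 2x2 table partitions genes disjointly (set
vs complement, annotated vs not), and fold enrichment is
`(a/(a+b)) / (c/(c+d))` — the annotated proportion in the set over the
proportion in the *complement*. With the published counts (31 channel
genes among 1374 DEGs; 270 channel genes among 30973 transcripts) this
convention yields 2.79; a pooled-background denominator would not, which
anchors the choice. The exact test fixes all margins and sums
hypergeometric probabilities of tables no more likely than the observed
one (minimum-likelihood two-sided convention, 1e-7 relative tie
tolerance), accumulated in log space via the log density — no factorials
are formed. The doubled-one-sided convention is available behind a flag.
The second analysis (intrinsic-excitability channels among
treatment-rescued DEGs) takes its genome-wide IC_intrinsic background
from the annotation column of the input table; that count is not
published and is never hard-coded.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and seed.

*Intracellular sweeps* are baseline + linear RC step response
(single-exponential, tau = RC) + spliced spike templates + SSTO sinusoid +
Gaussian noise. Spike templates are parametric pieces (half-cosine
approach, saturating-exponential upstroke with a cosine cap,
exponential repolarization, half-sine ADP hump, exponential descent to an
exact AHP sample, exponential recovery): the analyses implement
measurement rules, not membrane equations, so templates are built for
exact, known threshold/peak/AHP ground truth rather than biophysical
fidelity. Templates *replace* the underlying trace over their support,
continuous at both ends — the approach tapers into the threshold kink so
the 10%-of-max-dV/dt criterion lands on the planted threshold by
construction. Spikes are only planted where the step plateau sits >= 2 mV
above the template's AHP minimum (otherwise the post-spike minimum would
be the plateau and the planted AHP would be meaningless); the default
planted count grows with current above the rheobase implied by that
constraint. Evoked-protocol defaults use zero SSTO amplitude, matching
the observation that holding at -80 mV yields a baseline free of SSTOs.
The default membrane values (R = 230 MOhm, C = 100 pF) give the
wild-type-scale specific resistance of 2.3 MOhm/pF. The linear passive
model extrapolates unphysiologically at large currents (the plateau can
exceed spike peak); the measurement rules are insensitive to this, and it
keeps the Ohm's-law ground truth exact.

*Extracellular recordings* place biphasic simple-spike and larger
multiphasic complex-spike waveforms (a wider main spike plus three damped
spikelets, all within 2 ms of the main peak so the detector's
minimum-separation rule absorbs them) at Poisson times with a 2 ms
absolute refractory period, enforced on the discretized peak samples so
detector separation can never straddle a rounding boundary. Default rates
(50 Hz simple, 1 Hz complex) sit in the physiological Purkinje range.

*Morphologies* grow a persistent-random-walk tree with per-node
bifurcation probability and truncated-normal segment lengths, tracking
tips/bifurcations/length during construction — ground truth independent
of any traversal of the finished tree. *Tissue* places cell tops uniformly
in a box (or ellipsoid) and applies the full sectioning/frame/guard
machinery. *Transcriptomes* draw Bernoulli DEG flags with odds multiplied
for channel genes, and rescue flags among DEGs with odds multiplied for
IC_intrinsic genes.

Passing the suite therefore shows that every computation is correct on
data satisfying the generators' assumptions (stationary noise, isolated
events, uniform cell placement, independent genes). It does not show
robustness to electrode drift, bursting or overlapping units, tissue
shrinkage, anisotropic cell distributions, or correlated expression —
real-data features deliberately outside the generators' scope.

## Problem sizes and determinism

Feature-recovery checks run the full evoked protocol (17 sweeps, 1 s
steps) at 20 kHz sampling — the tolerances are in millivolts and are
insensitive to sampling above ~10 kHz, while the package defaults keep the
100 kHz acquisition rate. Monte-Carlo suites use 200 replicates for
fractionator/Cavalieri unbiasedness, 10^4 draws for the nucleator, 500
seeds for exact-test calibration and 200 for planted-odds recovery; these
sizes put the Monte-Carlo error comfortably inside the asserted bounds.
All feature extraction is deterministic for a fixed trace and
configuration; all generators are deterministic for a fixed seed.

## Known limitations

- ABF (Axon) files are not read directly; sweeps move through the
  delimited text dialect or the serialized container.
- The amplitude-gap split assumes complex spikes are the rarer, larger
  class; a manual threshold covers units where the assumption fails.
- The box-counting dimension is one estimator of fractal dimension;
  absolute values depend on the ladder and resampling density (both
  reported), so cross-study comparisons should fix the configuration.
- Nucleator unbiasedness holds for star-shaped profiles about the
  reference point, as for the physical probe.
- The enrichment stage treats genes as independent Bernoulli draws under
  the null; calibration is verified under that model only.
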