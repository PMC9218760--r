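---
title: "Methods: simulating and analysing micro-LED opto-electrophysiology sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing micro-LED opto-electrophysiology sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `optoephys`. The package has two halves that test each
other: a synthetic-session generator that produces multi-shank
opto-electrophysiology recordings with complete ground truth, and the
analysis chain a hippocampal circuit study runs on such recordings —
ripple detection, cell-type classification, optogenetic tagging,
cross-correlogram connectivity inference and forward/reverse sequence
readout — plus reduced physical models of the device itself (light
fluence, tissue heating, interconnect crosstalk).

## Probe geometry

The default layout is a four-shank silicon optoelectrode at 300 µm shank
pitch. Each shank carries 64 recording sites in two staggered columns
(40 µm vertical pitch within a column, 27 µm between columns, 20 µm
vertical stagger — the unique stagger that interleaves the rows so that no
site is farther than 40 µm from its nearest neighbour) and 32 micro-LEDs
along the shank midline at 40 µm pitch. Coordinates are x lateral and y
depth (positive down, origin at the topmost site row); only the pitches
are physically meaningful, the origin is a convention.

`span_area()` reports the footprint as horizontal shank-center extent
times the vertical extent of the sampled slots. Each interleaved site row
samples one 40-µm slot, so the vertical extent is
`sites_per_column x row_pitch + stagger` = 32·40 + 20 = 1300 µm; with
900 µm of horizontal extent the default device covers 1.17 mm². Measuring
between outermost site *centers* instead would give 1260 µm; the slot
convention matches the device's stated footprint and is what the package
reports.

## Synthetic sessions

The generator's purpose is statistical, not biophysical: it produces
spike trains, waveforms and field potentials with exactly the structure
the downstream analyses assume, so that every stage can be validated
against known ground truth. What it deliberately does not model:
overlapping raw waveforms (spike sorting is upstream of this pipeline),
compartmental neuron biophysics, stimulation artifacts on the raw traces,
and genuine polysynaptic network dynamics. Passing tests therefore
demonstrate that the analyses recover what they claim to recover under
their own assumptions — not that those assumptions hold in any particular
real recording.

**Spike trains.** Units are renewal processes with a 1.5 ms absolute
refractory period and a recovery hazard
$h(t) = r_h\,(1 - e^{-t/\tau_{rec}})$. The recovery constant shapes the
autocorrelogram (ACG) rise and is the axis along which the interneuron
classes separate: narrow interneurons use $\tau_{rec}$ = 3 ms, wide
interneurons 18 ms, pyramidal cells 0 (refractory only). Pyramidal trains
additionally receive burst spikes: a fraction `burst_propensity`
(default 0.2) of spikes is followed by an extra spike 2.5–6 ms later,
which gives the early ACG bump and an interspike-interval mix resembling
bursty CA1 cells. Baseline rates are log-normal per class (medians 2, 12
and 6 Hz). The underlying hazard rate is calibrated per unit by solving
the renewal mean-ISI equation, so the realized rate matches the drawn
rate regardless of the refractory parameters.

**Waveforms.** Each unit has a biphasic template whose trough-to-peak
latency is drawn per class (narrow 0.15–0.35 ms; pyramidal and wide
0.5–0.9 ms, either side of the 0.425 ms classification boundary);
amplitude decays exponentially with soma–site distance (length constant
28 µm, cut off at the 60 µm recordability radius) and the nearest-site
amplitude is rescaled to at least 200 µV, matching high signal-to-noise
single units on dense probes. Somata are placed within 20 µm of a random
site, so every unit is recordable on 3–5 sites.

**Connections.** Excitatory monosynaptic connections run from pyramidal
cells to interneurons with log-normal transmission probability (median
0.1), latency uniform in 0.5–3 ms and 0.3 ms Gaussian jitter. Injection
is literal: each presynaptic spike adds a postsynaptic spike with
probability *p*, subject to the postsynaptic refractory period, and every
inserted spike is recorded in the ground truth.

**Optical response.** The fluence at a soma follows the
diffusion-approximation point-source kernel (below) with the source on
the reflective probe surface. Above the 0.1 mW mm⁻² activation threshold,
a pulse elicits a first spike within the unit's 5–8 ms latency window
(per-pulse reliability saturating in fluence, max 0.8) followed by
sustained Poisson firing at a Hill gain
$g(\Phi) = g_{max}\Phi^2/(\Phi^2 + \Phi_{50}^2)$ with $g_{max}$ = 100 Hz
and $\Phi_{50}$ = 0.3 mW mm⁻², so a cell 10–20 µm from a typical 7 µW LED
peaks at 50–100 Hz. At a neighbouring shank (300 µm) the fluence is
0.027 mW mm⁻², safely below threshold, so cross-shank stimulation drives
nothing — the spatial-specificity property the optotag tests rely on.

**LFP.** Channels carry unit-variance 1/f-amplitude ("pink") noise scaled
to 50 µV. Ripples are Gaussian-enveloped 110–200 Hz oscillations, 30–100 ms
long, injected on designated pyramidal-layer channels; their amplitude is
expressed in SDs of that channel's own 80–250 Hz-filtered background, so
"6 SD" means the same thing to the generator and to the detector.
Stimulation-evoked oscillatory transients use the same SD unit, with an
amplitude profile over shank distance that emulates either spreading
(recurrent, CA3-like) or local-only (CA1-like) drive. The default LFP
rate is 1250 Hz — the raw acquisition runs at 20 kS/s, but ripple-band
analyses conventionally run on the downsampled trace, and the detector
only requires the rate to exceed twice the analysis band.

## Ripple detection

The detector follows the classic band-pass/power-threshold recipe: a
zero-lag difference-of-Gaussians band-pass (two Gaussian low-pass kernels
with −3 dB cutoffs at the band edges, truncated at 4σ), clipping at 4 SD,
rectification, and a Gaussian low-pass at `mean(band)/p_cycles` Hz — 55 Hz
for the default 80–250 Hz band with p = 3 cycles, the value the package
exposes as `ripple_lowpass_cutoff()`. The clipped power provides the
robust mean/SD; the *non-clipped* power is thresholded at 4 SD, expanded
to the 1 SD edges (overlapping expansions merge), and events shorter than
15 ms are dropped. The estimation epoch for the SD excludes caller-supplied
intervals (stimulation windows) — published detector recipes leave the
estimation epoch open, and excluding evoked power keeps the threshold
honest.

## Cell-type classification

Features: trough-to-peak latency from the peak-site mean waveform, burst
index (fraction of ISIs < 9 ms), and the ACG rise time. The ACG
(0.5 ms bins) is fitted with
$a + b\,e^{-t/\tau_d} - c\,e^{-t/\tau_r}$ by bounded Levenberg–Marquardt
least squares over a 3×3 grid of restarts in $(\tau_r, \tau_d)$ with
amplitude starts read off the histogram; $\tau_r$ is the reported rise
time. The exact parameterization of the "rise time" in the cited
cell-classification pipelines is not published; this family and readout
are therefore configuration, and the recovery property (a rise constant
synthesized into an ACG is recovered within 20%) is what the test suite
pins down. The classification rule itself is verbatim: trough-to-peak
< 0.425 ms → narrow interneuron; > 0.425 ms with rise time > 6 ms → wide
interneuron; everything else — including a latency of exactly 0.425 ms
and units whose fit fails — → pyramidal. Soma localization is the
amplitude-weighted centroid of site positions using peak-to-trough
amplitudes; on default sessions the median error is ~8 µm, well inside
the 20 µm the tests require.

## Optogenetic tagging

The test statistic is the peak 1 ms-binned PSTH rate in the 5–8 ms window
after pulse onset (onset, not power plateau, is the reference). The null
rebuilds that statistic 500 times from surrogate trains restricted to the
span between the first and last pulse, and the unit is tagged when the
observed peak exceeds the 0.999 quantile (order statistic, so the attained
tail with 500 resamples is ≈ 1/500 — the calibration tests use the
matching binomial bound).

The null surrogate is the one genuinely open design choice. A circular
time-shift of the whole train preserves ISI structure and is the natural
reading of "resampling", but it is *self-defeating under a strictly
periodic protocol*: with pulses every 100 ms, a circular shift merely
re-phases the PSTH, the null distribution of the peak statistic becomes
the distribution of the PSTH over phases, and its extreme quantile
coincides with the true peak — no unit can ever be tagged, however strong
its response. Published confidence intervals an order of magnitude below
observed peaks are only consistent with a rate-preserving null. The
package therefore defaults to count-preserving uniform resampling of
spike times within the span (`method = "resample"`), which destroys all
temporal structure while fixing the rate; the circular shift remains
available (`method = "shift"`) for irregular pulse trains. The resampling
null treats bursty trains as Poisson and is slightly anticonservative for
strongly bursting units; the calibration guarantee is stated for
Poisson-like discharge.

## Monosynaptic inference

CCGs are exact pair counts per 1 ms lag bin (bins centered on integer
lags; the +2 ms bin covers lags in (1.5, 2.5] ms), computed by binary
search rather than histogram approximation, so time-reversal symmetry
holds exactly. Significance uses the convolution null: the observed CCG
over a ±50 ms baseline window is convolved with a partially hollow
Gaussian kernel (SD 10 ms, central bin down-weighted by 0.6, edges
renormalized) to form the expected count per bin, and a pair is an
excitatory edge when any bin in the 0.5–3 ms detection window exceeds the
Poisson `1 - alpha/3` quantile of its expectation (Bonferroni over the
three detection bins; alpha = 0.001). These kernel parameters follow the
published defaults of the ground-truth-validated convolution method the
field uses; the exact interval construction is not restated in the
methods literature this pipeline descends from, so per-bin Poisson tails
with Bonferroni correction were chosen and are configurable. Spike
transmission probability is the summed observed-minus-expected count over
the detection window per reference spike; the type-I error on independent
Poisson ensembles matches alpha (slightly conservative through Poisson
discreteness) and STP is recovered within ±0.01 for injected
probabilities of 0.05–0.2 at 600 s. Spikes inside stimulation pulses are
excluded by default so light-driven common input cannot imitate a
synapse.

## Sequence readout

Per stimulation event, each participating unit contributes the center of
mass of its spikes, min–max normalized to the event window; silent units
drop out of that event and events with fewer than two active units are
skipped. Rank-order correlation between two events is Pearson correlation
of the shared units' ranks (Spearman-type; "rank order" and "Pearson" are
both used in the field's descriptions, and ranking first makes the
statistic invariant to any monotone time distortion within an event). The
within- versus between-condition comparison uses all event pairs, a
one-sided rank-sum test, and a unit-identity shuffle null; inside the
shuffle loop correlations are computed on within-event ranks with
pairwise-complete sharing, a vectorized variant of the pairwise statistic.
Only units shared by both events (≥ 3) enter a correlation; no imputation
is attempted for silent units.

The decoder is a linear SVM (cost 1, no feature scaling) on concatenated
per-unit 10 ms binned counts, trained on a stratified half of the events
and scored on the other half; significance is the fraction of label
shuffles whose held-out accuracy reaches the observed one (shuffled
labels are used for training, predictions are scored against the true
ones). The feature window is configurable: the full
first-onset-to-last-offset span, or a fixed 120 ms from the first onset —
the stimulation-pulse duration, which is the window the acceptance
analyses use.

## Device physics

All three solvers are reduced models with analytic oracles, not
general-purpose field solvers.

**Fluence.** Steady-state photon diffusion
$-\nabla\!\cdot\!(D\nabla\Phi) + \mu_a\Phi = S$ with
$D = 1/(3(\mu_a+\mu_s'))$, $\mu_a$ = 4.47 cm⁻¹, $\mu_s'$ = 50.5 cm⁻¹,
solved by finite volumes on a graded axisymmetric (r, z) grid (1.5 µm
cells at the source growing geometrically to 40 µm), with the probe
surface as an ideal reflector (zero-flux plane) and absorbing far
boundaries. Against the infinite-medium Green's function
$\Phi = P e^{-\mu_{eff} r}/(4\pi D r)$ the solution is within 0.5% over
20–200 µm (the tests require 5%). With the stated optical constants and a
7.03 µW source, the 0.1 mW mm⁻² contour sits at ≈ 130 µm — confined well
inside one shank pitch, though not within a single site spacing; the
package reports what the stated constants imply.

**Bioheat.** Steady Pennes equation
$-\nabla\!\cdot\!(k\nabla T) + \omega\rho_b c_b T = q$ on a 7 mm tissue
cube containing the 6 mm, 30 µm-thick silicon shank, solved by finite
volumes on a graded tensor grid (cells from 0.5 µm at the source to
350 µm at the boundary, ~135k cells) with harmonic face conductances, a
supernodal sparse Cholesky solve, an insulating top surface (where the
shank enters) and isothermal far boundaries. The 300 µW source occupies
an 8 × 17 × 0.5 µm volume at the lowermost LED, embedded in contact with
the silicon surface — the LED stack's conductivity is silicon-like, which
is also why the stack can otherwise be ignored; the 1 µm oxide cap
appears as an extra series resistance on the remaining silicon–tissue
interface. Thermal parameters are literature values standing in for
unpublished ones: tissue k = 0.51 W m⁻¹K⁻¹, perfusion
ω·ρ_b·c_b = 0.008 s⁻¹ × 1050 kg m⁻³ × 3600 J kg⁻¹K⁻¹, silicon 150, oxide
1.4. The shank's width taper (50 µm at the bottommost LED, 140 µm above
the top LED, widening to ~250 µm toward the backend, read off the device
drawings) matters: the silicon is the dominant heat spreader, and with
the taper included the maximum tissue temperature rise at 300 µW is
≈ 0.50 °C, inside the 0.6 °C safe-operation bound; a constant-width
50 µm needle would overshoot it. The conduction-only configuration
(no shank, no perfusion) reproduces $\Delta T = P/(4\pi k r)$ within 10%
at mid-range distances, and grid refinement changes the maximum by < 2%.

**Interconnect T-network.** Two coupled RC ladders (32 cells over 6 mm)
under nodal analysis: series trace resistance 0.35 MΩ total (from the
0.7 µm × 100 nm gold cross-section), source behind the 1.4 MΩ median
electrode impedance, shunt 0.15 pF to tissue, line-to-line coupling
0.35 fF, recording chain 1.3 GΩ ∥ 0.5 pF. Insertion loss is
$20\log_{10}|V_{o1}|$ and far-end crosstalk $20\log_{10}|V_{o2}|$ with a
unit source on line 1 and line 2's electrode end grounded. The shunt and
coupling capacitances are placeholder estimates — the measured values
live in unpublished supporting material — chosen to be consistent with
the device-level claims (loss < 1 dB, crosstalk < −88 dB over
0.1 Hz–10 kHz); conclusions about the real device require the measured
R/C values, and every element is a config parameter.

## Problem sizes and runtime choices

Default analyses run at the sizes the statistics need, not larger:
600 s sessions with 100 units for classification and connectivity
(enough spikes for stable ACG fits and CCG baselines), 200 surrogate
units for null calibrations (binomial resolution ≈ the CI tail), 240
stimulation events for the sequence analyses (the event count the
experiment design uses), 1000 independent pairs for the connectivity
type-I check, and 10000 label shuffles for the decoder p-value. The
bioheat and fluence grids are graded so the finest cells sit at the
source; refining them further changes the reported quantities by under
2%.

## Known limitations

- The generator's evoked-response scale is order-of-magnitude: absolute
  evoked rates per LED distance are configuration, anchored to typical
  50–100 Hz peak discharge near the LED.
- The resampling optotag null assumes Poisson-like discharge within the
  pulse span; strong bursting makes it anticonservative.
- The convolution-null detection window treats the three 1 ms bins
  centered at 1–3 ms as the monosynaptic window; sub-bin latency
  structure is not modeled.
- The device solvers use structured grids and literature tissue
  constants; they bound and cross-check the device claims rather than
  reproduce any particular finite-element mesh.
- ICA-based dendritic-sublayer decomposition and spike sorting are out of
  scope; the pipeline starts from sorted spikes.
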