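---
title: "Models and methods behind calciphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind calciphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciphen)
```

calciphen quantifies the functional and morphological phenotypes of mixed
neural cultures (neurons plus glia, as obtained from hiPSC-derived cortical
differentiation) and brain organoids: spontaneous calcium activity at
network scale, agonist-evoked responses in single cells, synaptic puncta
and their colocalization, background-corrected marker intensity, and
organoid morphometry. Because no public raw recordings exist for this class
of experiment, the package ships a first-class synthetic-data generator
with complete ground truth; every pipeline stage is validated against that
truth.

## The transient model

A calcium transient is modelled as a single-exponential rise multiplied by
a single-exponential decay,

$$I(t) = a\,e^{-(t-t_0)/\tau_{\mathrm{off}}}\left(1-e^{-(t-t_0)/\tau_{\mathrm{on}}}\right),
\qquad t \ge t_0,$$

and zero before the onset $t_0$. Recorded traces are treated as linear
superpositions of such transients on a slowly varying baseline — the
standard assumption that calcium responses to individual action potentials
add linearly. The model peaks at
$t_0 + \tau_{\mathrm{on}}\log(1+\tau_{\mathrm{off}}/\tau_{\mathrm{on}})$
(`transient_peak_time()`), and the generator rescales `a` so that the
ground-truth "amplitude" is always the model peak in dF/F0 units.

Fitting is two-step, following the structure used with this model in the
calcium-imaging literature: `fit_onset()` fits the pure rise
$I(t)=k(1-e^{-(t-t_0)/\tau_{\mathrm{on}}})$ from just before the detected
onset to the local peak, giving starting values for $t_0$ and
$\tau_{\mathrm{on}}$; `fit_full_transient()` then fits the full model.
Two refinements matter in practice and are on by default:

* the full fit re-estimates $\tau_{\mathrm{on}}$ — a pure-rise fit taken up
  to the observed peak sees a rise already attenuated by the decay factor
  and underestimates $\tau_{\mathrm{on}}$ roughly threefold for slow
  signals, enough to flip a glial cell across the 2 s classification
  threshold;
* the full fit re-estimates $t_0$ within ±0.5 s of the step-1 value — a
  frozen step-1 $t_0$ is biased late for sub-second rises at 4 Hz, and the
  bias propagates into every other parameter. A wider search window is
  deliberately not used: it lets $t_0$ slide early while
  $\tau_{\mathrm{on}}$ inflates to compensate.

`refine_tau_on = FALSE` / `refine_t0 = FALSE` restore the literal two-step
scheme.

### Degenerate fits and overlapping events

The model has an unphysiological branch: for
$\tau_{\mathrm{on}} \gg \tau_{\mathrm{off}}$ it degenerates into a
gamma-like pulse whose scale `a` can grow arbitrarily while the peak stays
finite. Fits ending there (peak factor below 0.05), or with a time
constant pinned near its box bound, are flagged `converged = FALSE`: the
event still counts towards the rate, but its kinetics are excluded from
statistics, exactly as a supervised reviewer would discard a visibly wrong
fit.

Overlapping transients are handled by peeling under the superposition
assumption. `fit_events()` runs three passes per trace:

1. sequential fitting in time order, each fit on the residual after
   subtracting earlier fitted transients, with the window cut at the next
   candidate onset;
2. a refinement pass that refits every event on the trace minus all
   *other* fitted events, over a window no longer truncated by the
   neighbour (this is what stabilizes $\tau_{\mathrm{off}}$ for events
   closely followed by another);
3. a rescue pass that re-runs candidate detection on the final residual,
   recovering events that the smoothed-trace detector merged into a
   neighbour.

When a single fit of a candidate is degenerate or leaves a residual RMS
well above the trace noise over the transient's own support, a joint
two-transient refit is attempted ("split"). A split is accepted only if
both components have comparable amplitude and the split clearly beats the
single fit; otherwise a slow transient could be carved into two fast
halves. With these rules, two noiseless 0.3-dF/F0 events 2 s apart are both
recovered with exact amplitudes, and on full simulated recordings the mean
event-rate error is about −5% (the residual loss is pairs closer than
~1.5 s, unresolvable at 4 Hz after 0.75 s smoothing — a documented
limitation).

## Detection rules and their thresholds

`normalize_dff()` computes dF/F0 with a baseline from a rolling
10th-percentile window. The default width is 60 s: slow glia-like
transients last ~30 s, and a 30 s window lets the percentile ride up into
the event, clipping its amplitude. An iteratively trimmed low-order
polynomial baseline is available as an alternative.

`detect_events()` implements the onset/offset rules on the smoothed trace
(moving average, default 0.75 s): an onset opens where the slope exceeds
`slope_eps` (default 0.004 dF/F0·s⁻¹, low enough that a 1.1%-amplitude
transient with a gentle rise still triggers), the offset is where the slope
turns negative, and a candidate is kept only if the onset-to-offset
interval reaches 0.5 s and the local peak amplitude reaches the threshold.

The amplitude threshold is 1% of baseline — read as dF/F0 ≥ 0.01 — applied
as `max(0.01, 6 * sigma_s)` where `sigma_s` is the estimated noise SD of
the smoothed trace. On noiseless data this is exactly the 1% rule (a
0.9%-peak transient yields no event; 1.1% yields one). On noisy data the
adaptive floor stands in for the human review step of the original
workflow: with ~0.004 dF/F0 pixel noise in a 200-cell field, a bare 1%
absolute threshold admits several noise-triggered events per recording,
while the factor 6 keeps the expected count below one.

Per-cell summaries (`summarize_cells()`) count every detected event in the
rate, but compute kinetic statistics as a 20% trimmed mean over converged
fits of representative amplitude (≥ 30% of the cell's median peak).
Per-event time-constant errors at 4 Hz are heavy-tailed; without trimming,
a single contaminated fit flips ~5% of fast cells across the
classification threshold.

## Active-cell detection

`compute_activity_map()` collapses the movie into the cumulative absolute
difference of each pixel's signal between frames, low-pass filtered in the
2D Fourier domain (default cutoff 0.2 × the spatial Nyquist frequency,
which passes soma-scale structure and removes pixel noise) and clipped at
zero. Each pixel's signal is first smoothed with a 1 s moving average and
differenced at a lag of one window; with a one-frame window this reduces
exactly to the consecutive-frame difference, but without smoothing a slow
rise contributes per-frame increments far below the pixel noise and slow
cells disappear from the map. The map is invariant to a constant intensity
offset, and a constant movie maps to zero.

`detect_rois()` selects local maxima above
`median(map) + threshold_frac * (max(map) - median(map))` (default 0.10);
the median term matters because the cumulative-difference map of a noisy
recording sits on a uniform noise floor proportional to recording length,
so a threshold relative to the raw maximum would never separate somata
from floor. Maxima are kept greedily in descending map value with a
minimum-separation exclusion (12 px default; row-major order breaks exact
ties) and capped at 200 cells per field of view. `edit_rois()` supports
the manual add/remove correction step; `extract_traces()` averages over a
fixed-radius disc (3 px default), clipping at image edges with a warning.
Pixel coordinates are 1-based `(row, col)` throughout, the R convention.

## Classification, synchrony, evoked responses

Active cells are split at $\tau^* = 2$ s on the mean rise time: strictly
below is FAST (neuron-like), at or above is SLOW (glia-like or
store-release signals); cells whose every fit failed are reported
UNCLASSIFIED and count as active but join neither class. The synchrony
index bins all onsets at one frame (0.25 s at 4 Hz) and reports the
fraction of events sharing a bin with an event of a different cell —
1 when all cells fire together, undefined (flagged, excluded from group
statistics) with fewer than two eligible cells. Synchrony is computed per
class, matching how the population figures are laid out. Evoked responses
use `(F - F0)/F0` with `F0` the mean over a 5-minute pre-puff window at
1 Hz; a cell is a responder if its post-puff peak reaches 0.05 dF/F0 (the
protocol defines no criterion; the value is exposed in the configuration).

`compare_groups()` is a thin reporting layer: Shapiro–Wilk per group, then
a two-sided Mann–Whitney test unless both groups look normal (then
Student's t), plus a Kolmogorov–Smirnov test on the empirical
distributions; metrics with fewer than three observations per group are
skipped with a notice.

## Image quantification

Puncta counting follows the standard plugin workflow: maximum-intensity
z-projection, top-hat background removal (image minus its grayscale
opening with a disc larger than a punctum, default radius 10 px), Otsu or
absolute thresholding per channel, 8-connected component labelling and an
area filter. A channel-1 punctum is colocalized when ≥ 25% of its pixels
overlap channel-2 foreground (the plugin's internal rule is not public;
the fraction is configurable). The colocalized count can never exceed
either channel count.

The background-corrected intensity measure is the exact arithmetic
$[\mathrm{integrated\ density} - (\mathrm{area} \times \mathrm{mean\ background})]/\mathrm{area}$
in µm⁻² units.

Organoid morphometry reports area (pixel count × pixel area), perimeter
and maximum Feret diameter of the largest foreground component. The
perimeter is the marching-squares contour at the 0.5 level of the mask
after a light Gaussian smoothing (σ = 1 px): the raw binary contour
overestimates curved perimeters by ~5% (staircase bias), while the
smoothed half-level set tracks the true boundary within ~1% for circles,
ellipses and squares alike. Results are exactly scale-equivariant in the
pixel size.

## The synthetic-data generator

`simulate_movie()` emulates the acquisition this analysis is designed for:
a 5-minute, 4 Hz recording of a ~260 × 200 µm field. Defaults are the
study conditions: 28 fast, 56 slow and 60 silent cells (144 total, the
population counts reported for wild-type fields), per-class event rates
0.035 / 0.025 Hz and onset constants 1.3 / 5.2 s (the reported rise
times), decay constants 3 / 8 s, peak amplitudes 0.2 / 0.3 dF/F0, baseline
100 counts with 5% polynomial drift, Gaussian pixel noise (SD 2 counts,
i.e. dF/F0 SNR ≈ 10 after ROI averaging), and 40% of events synchronized
onto shared network-burst frames (the reported synchrony indices are
0.4–0.6). Values the study does not state — noise level, drift shape,
footprint size — are stated assumptions, not reproductions.

Design choices worth knowing:

* somata are isotropic Gaussian discs (σ = `cell_radius_px`, truncated at
  3σ), normalised so the footprint's mean over the default ROI-extraction
  disc is 1 — disc-averaged traces are then directly comparable to
  ground-truth amplitudes, so amplitude-recovery tests measure estimator
  bias rather than an arbitrary attenuation factor;
* baseline drift is a low-order polynomial, which forces the baseline
  estimator to be non-trivial;
* synchronized firing moves each event, with probability `sync_fraction`,
  onto one of a pool of shared burst frames; a cell joins a given burst at
  most once (two simultaneous onsets in one soma are unphysical), and the
  pool is large enough to hold the largest event train, so
  `sync_fraction = 1` really synchronizes everything;
* noise is additive Gaussian, the simplest model consistent with camera
  readout at these intensities; Poisson shot noise, photobleaching, motion
  and an optical PSF are deliberately not modelled.

What passing tests therefore show: the pipeline recovers cells, classes,
rates, amplitudes and synchrony from data whose statistical structure
matches its assumptions. What they do not show: robustness to motion
artifacts, bleaching trends, shot-noise statistics or overlapping somata —
real-data properties the generator does not emulate.

`simulate_puncta()` places Gaussian puncta with an exact colocalized count
(`round(coloc_fraction * min(n1, n2))` concentric pairs; all other
cross-channel centers farther than twice the punctum radius), and
`simulate_organoid_mask()` rasterizes circles, ellipses and squares whose
diameter, perimeter (complete elliptic integral for the ellipse) and area
are known analytically.

## Problem sizes and reproducibility

The validation suite runs on one CPU in a few minutes: the end-to-end
recovery benchmark uses one 200 × 256 px, 1200-frame movie with 120 active
cells; the threshold-cap check uses a 250-cell, 2-minute movie; puncta
recovery uses 2000 puncta per channel on 1024² images; Monte-Carlo checks
use 100–500 replicates. All analysis stages are deterministic given the
input and configuration (fit restarts use a fixed jitter table, not random
draws), every generator takes an explicit seed, and every result file
embeds the hash of the configuration that produced it.

## Known limitations

* Events of one cell closer than ~1.5 s are not reliably resolved at 4 Hz
  with the default smoothing; the event rate is accordingly biased low by
  a few percent at the simulated rates.
* A merged pair whose joint refit fails is kept as a single flagged event:
  right count for one of the two, kinetics excluded.
* The 1%-of-baseline amplitude rule is meaningful only relative to the
  noise floor; the adaptive multiplier (`noise_mult`) governs the
  trade-off and 6 is calibrated for fields of ~200 ROIs.
* Puncta analysis is 2D (on the z-projection); genuinely 3D colocalization
  is out of scope.
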