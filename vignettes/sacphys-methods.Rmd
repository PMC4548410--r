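---
title: "Detecting synaptic and autaptic connections in starburst amacrine cell recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting synaptic and autaptic connections in starburst amacrine cell recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacphys)
```

## Scope and conventions

`sacphys` implements the quantitative analyses used to characterise the
GABAergic circuitry of retinal starburst amacrine cells (SACs): detection of
synaptic connections in paired voltage-clamp recordings, detection of
autapses from single-cell recordings, vector-sum direction-selectivity
statistics for ganglion-cell spike trains, distance-binned connection
probabilities with a Monte-Carlo null for reciprocity, and the geometry of
SAC mosaics and dendritic overlap. Because raw recordings of this kind are
rarely shared, the package pairs every estimator with a seeded synthetic
generator that emits its ground truth, so the whole pipeline is testable
end to end.

Units are fixed package-wide: currents in pA with **outward current
positive** (inhibitory postsynaptic currents recorded at depolarised
holding potentials appear as positive deflections), times in ms, potentials
in mV, distances in µm. Validators enforce these at construction.

## The connection classifier

A presynaptic SAC is stepped from −70 to +20 mV for 200 ms while the
postsynaptic cell is held at +30 mV; roughly ten repetitions are averaged.
A pair is deemed connected when three criteria all hold on the averaged,
artifact-blanked trace:

1. **Peak**: the averaged trace has a peak in the first 30 ms after the
   presynaptic step onset that is more than 2 standard deviations from the
   baseline established in the 50 ms before onset.
2. **Trial presence**: a current deflection is present in at least 80% of
   trials.
3. **Kinetics**: the peak has short onset latency (< 12 ms) and fast 10–90%
   rise time (< 4 ms).

Boundary conventions follow the printed operators (strictly > 2 SD,
≥ 80%, strictly < 12 ms and < 4 ms); measured values essentially never land
exactly on a boundary.

Several operational details are deliberate choices:

* **Peak reading.** At 20 kHz the extreme value of ~600 raw noise samples
  sits near 3.8 baseline SD, so a literal "any sample > 2 SD" peak test
  would fire on pure noise. The peak is therefore read from a 1 ms
  boxcar-smoothed averaged trace (noise extremes shrink to well under the
  threshold, while millisecond-scale synaptic peaks are barely attenuated),
  and the 2-SD threshold uses the unsmoothed averaged-trace baseline SD.
* **Trial presence.** "A deflection is present in a trial" is
  operationalised as a 2-per-trial-SD excursion from the per-trial baseline
  in the polarity of the averaged peak, sustained for at least 1 ms, on
  0.5 ms-smoothed traces. Without smoothing, white noise at 20 kHz breaks
  sustained runs and the test loses power; with it, false per-trial hits
  are rare (a 1 ms run of smoothed noise above 2 SD is a multi-sigma
  event). A zero-variance baseline (possible only in degenerate synthetic
  input) is an explicit error, since the 2-SD rule cannot be calibrated.
* **Artifact blanking.** 1 ms after each step transition is excluded from
  peak search and presence testing. The value is a default: long enough to
  cover capacitive transients, far shorter than the 12 ms latency bound.
* **Anomaly flag.** Each result carries a post-hoc flag marking averaged
  baselines with samples more than 5 SD from the baseline mean, mirroring
  the practice of re-checking recordings with large baseline deviations.

### Onset latency

Latency is measured by fitting a Boltzmann sigmoid
$I(t) = \mathrm{base} + \mathrm{amp} / (1 + e^{(t_{1/2} - t)/k})$
to the rising phase (from the last baseline crossing before the peak to the
peak sample) and reporting where the maximal-slope tangent of the fit meets
the baseline, $t_{1/2} - 2k$, relative to stimulus onset. A sigmoid never
touches its own baseline asymptote, so the tangent intercept is the natural
reading of "the intersection of this line with the baseline"; for data that
are exactly Boltzmann the estimate is exact (a rise with $t_{1/2}$ 8 ms
after onset and $k = 0.5$ ms gives 7.0 ms).

Two numerical choices stabilise the fit. The asymptotes are pinned to the
measured baseline mean and baseline-subtracted peak, leaving only
$t_{1/2}$ and $k$ free: with all four parameters free, the least-squares
sigmoid trades amplitude against slope on non-sigmoidal rises and the
tangent intercept drifts early by about a millisecond for
difference-of-exponentials synaptic waveforms. Traces with measurable
baseline noise are smoothed with a 0.5 ms boxcar before fitting. With both
in place the planted 7 ms latency of synthetic events is recovered within
0.2 ms at the benchmark signal-to-noise ratio, and a 13 ms planted latency
is measured above the 12 ms criterion, as it must be for the criterion to
be falsifiable. The fit uses Levenberg–Marquardt least squares
(`minpack.lm`), initialised at the half-max crossing with
$k_0 = (t_{90} - t_{10})/4.4$, bounded $k > 0$, relative tolerance
$10^{-8}$, at most 500 iterations. Negative latencies are flagged invalid
rather than clipped.

### Rise time and reversal

The 10–90% rise time takes the first crossings of 10% and 90% of the
baseline-subtracted peak (scanning forward from the start of the rising
phase, linear interpolation between samples): a linear 5 ms ramp measures
4.0 ms exactly. The reversal potential of an I–V series is the
piecewise-linear zero crossing; with no sign change the value is
extrapolated from a least-squares line and flagged.

## Autapse detection

A brief (2–4 ms) step to +60 mV followed by a return to −20 mV evokes an
intrinsic depolarisation-activated transient that decays within 100 ms;
autaptic GABAergic currents ride on this decay. The first 30 ms after the
return are fit with a double exponential
$\mathrm{offset} + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$; cells whose fit
residuals exceed 2 pre-stimulus-baseline SD are candidates, and candidates
are then passed through the three connection criteria applied to the
residual trace, with latency referenced to the start of the +60 mV step.

The residual substrate needs care, because an event occupying most of the
30 ms window is partially absorbed by an unconstrained least-squares
double exponential. The detector therefore works in two passes: the plain
fit of the averaged trace defines an event-support region (outward
residuals above both 4 baseline SD and half the residual peak, grown by
1 ms), and the transient is then refit with that region excluded, so the
refit residual carries the event. Per-trial presence refits each trial the
same way (with the support region fixed from the average) and applies the
smoothed 2-SD excursion test per trial. Double-exponential fits are
initialised by log-linear peeling (slow component from the decay tail,
fast component from the early remainder) with a fixed grid of fallback
starts, keeping the whole procedure deterministic. Trials with currents
beyond a saturation bound (default 2000 pA, the regime of the large inward
calcium currents that preclude autapse measurements in young retinas) are
excluded with a flag rather than classified.

Population summaries (`classify_population()`) report per-genotype autapse
frequencies with the binomial standard error
$\sqrt{\hat p (1 - \hat p)/n}$.

## Direction selectivity

Spike trains are recorded in loose patch while a bright bar moves across
the receptive field in 8 directions (0°–315° in 45° steps) at 1000 µm/s.
Spikes are detected by simple thresholding (default: median + 5 MAD, 1 ms
refractory period), binned into 50 ms peristimulus histograms anchored at
stimulus onset (partial trailing bins dropped), and the peak firing rate is
the maximal bin inside the ON epoch (leading edge crossing a 300 µm window
centred on the soma) and the OFF epoch (trailing edge crossing).

The direction-selective index is the normalised vector sum
$\mathrm{DSI} = \left| \sum_i r_i e^{i\theta_i} \right| / \sum_i r_i$,
whose argument is the preferred direction. This is the standard
normalisation, bounded in [0, 1]; equal rates give 0, a single nonzero
direction gives 1. Derived summaries: deviation of the preferred angle from
ventral (270° by convention, stored explicitly in every spike-train set),
absolute ON–OFF differences in angle and magnitude, and the ventral
projection of the DSI vector computed from per-direction ON+OFF summed
rates. Angle pooling across ON and OFF responses is left to the caller:
both appear separately in every `tuning_result`, so either pooled or
independent treatments can be assembled.

## Connectivity statistics

The unit of analysis is the **directed test**: a bidirectionally tested
pair contributes two tests. Connection probability is estimated per
distance bin (default edges 35, 100, 175 µm; left-closed bins, so 100 µm
falls in the far bin, matching the "separated by > 100 µm" reading) with
the binomial standard error. The reciprocity null pools a single directed
probability $\hat p$ across distances and directions by default — a
distance- or genotype-stratified variant is available via an argument —
and simulates $10^5$ datasets in which the two directions of every pair
are independent Bernoulli($\hat p$); the per-simulation category counts
are equivalently (and efficiently) drawn from the multinomial
$(\hat p^2,\, 2\hat p(1-\hat p),\, (1-\hat p)^2)$, which the closed-form
`analytic_reciprocity()` provides as an independent oracle. Two-sided
percentile p-values use add-one smoothing, $(r + 1)/(n_{\mathrm{sim}}+1)$,
so no p-value is exactly zero. With the plug-in $\hat p$ these p-values
are slightly conservative for small tables; calibration checks in the test
suite therefore use tables of several hundred pairs, where the plug-in
effect is negligible.

## Mosaic geometry

The density recovery profile counts, for every reference cell lying at
least $r_{\max}$ inside the field boundary, neighbours in concentric
annuli (default 10 µm width out to 150 µm), normalised by annulus area and
reference count. Interior-buffer edge handling is simpler than analytic
edge correction and unbiased; the cost is discarding border cells as
references. The effective radius is reported as the inner edge of the
first annulus whose density reaches the mean density — definitions vary in
the literature, so the full profile is always returned alongside. A flat
profile at the mean density indicates complete spatial randomness; a
central trough indicates an exclusion zone. Because neighbour counts are
correlated between reference cells, the flatness checks in the test suite
calibrate per-annulus standard errors by Monte-Carlo over replicate random
mosaics rather than with the (too tight) naive Poisson formula.

Dendritic overlap between two SACs modelled as circles of radius
$R = 100$ µm at soma distance $d$ is the lens area
$2R^2 \cos^{-1}\!\big(\tfrac{d}{2R}\big) - \tfrac{d}{2}\sqrt{4R^2 - d^2}$
for $d < 2R$ and 0 beyond: $\pi R^2 \approx 31\,416$ µm² at $d = 0$ and
$\approx 12\,284$ µm² at $d = R$.

## The synthetic-data generators

Every generator is a pure function of its parameters and seed (the
caller's RNG state is saved and restored) and writes its ground truth into
metadata, so recovery tests never re-derive what was planted.

* **Postsynaptic currents** are difference-of-exponentials waveforms
  normalised so the continuous-time peak equals the amplitude. Defaults —
  15 pA, 7 ms latency — reproduce the typical SAC–SAC connection;
  $\tau_r = 1$ ms and $\tau_d = 20$ ms give a ~1.6 ms rise time, safely
  inside the 4 ms criterion. Trial-to-trial variability uses an amplitude
  CV of 0.2 and a per-trial failure probability of 0.1, values chosen as
  realistic for GABAergic synapses since the source measurements report
  means only; both are configurable, and detector benchmarks plant
  failure-free events so that the planted condition matches the "connected
  with compliant kinetics" definition rather than mixing in release
  failures.
* **Autaptic recordings** superimpose a 20 pA event (latency referenced to
  the start of the depolarising step) on an intrinsic transient with
  defaults $A_1 = 200$ pA, $\tau_1 = 5$ ms, $A_2 = 50$ pA,
  $\tau_2 = 30$ ms — a shape that decays below 5% of its peak within
  100 ms, which the constructor enforces.
* **Noise** is i.i.d. Gaussian, default SD 2 pA. Real recordings have
  coloured noise, line pickup and drift; Gaussian noise keeps every 2-SD
  criterion analytically checkable, and the smoothing choices above are
  the only places where the white-noise idealisation materially shaped the
  design. Passing tests on these data demonstrate correctness of the
  criteria's logic and calibration under the stated noise model, not
  robustness to every artifact of real rigs — the anomaly and saturation
  flags exist for exactly that gap.
* **Spike trains** are inhomogeneous Poisson with a von Mises-shaped rate,
  $r(\theta) = \mathrm{baseline} + \mathrm{peak}\cdot
  e^{\kappa(\cos(\theta-\mu)-1)}$, constant within the ON and OFF epochs
  derived from bar geometry (1000 µm bar, 300 µm window, 1000 µm/s). The
  tuning shape is a generator choice — the analyses only measure tuning —
  and von Mises is the minimal unimodal circular model. Real spike trains
  have refractoriness and burstiness that Poisson lacks.
* **Mosaics** use random sequential adsorption with a per-point retry cap
  of $10^4$; infeasible packings raise an error rather than silently
  under-filling. RSA produces a slight density pile-up just outside the
  exclusion radius, which is visible in its profile and is expected.
* **Connectivity tables** draw pair distances uniformly over 35–175 µm and
  two independent Bernoulli connections per pair from a probability table
  over distance bin × genotype × age. The default table (juvenile near
  0.60 / far 0.25; adult near 0.10 / far 0.30; single-isoform cells at 20%
  of those values) encodes the qualitative population structure — juvenile
  proximal pairs more than twice as likely to be connected, proximal
  connections lost in adults, single-isoform connectivity at ~20% of
  control — with illustrative magnitudes, since exact probabilities are
  not tabulated in the source measurements.

## Problem sizes and reproducibility

The bundled checks use desk-scale sizes chosen to make their statistical
oracles sharp: 100 + 100 recordings for each detector benchmark, $10^5$
reciprocity simulations against the multinomial closed form, $10^4$ pairs
for the distance-contrast recovery, 500 replicate populations for
confidence-interval coverage, and 20–30 replicate mosaics for profile
flatness. `run_pipeline()` bundles the stages behind a validated YAML
config (see `inst/extdata/demo_config.yaml`) and writes CSV/JSON artifacts
plus a JSON-lines run log keyed by seed and package version; rerunning a
config byte-reproduces the summary. `scripts/acceptance.R` recomputes the
headline quantities from scratch for any seed.

## Known limitations

* The classifiers assume a single event per sweep; trains of events within
  one response window are out of scope, as are deconvolution- or
  template-based detectors.
* The Boltzmann tangent-intercept latency is a convention; other groups
  extrapolate the 20–80% slope or use threshold crossings. On sigmoidal
  rises they agree; on fast non-sigmoidal rises they can differ by a few
  hundred microseconds.
* The reciprocity null conditions on the pooled $\hat p$; for strongly
  distance-structured datasets the stratified variant should be preferred,
  since pooling can mimic an excess of bidirectional pairs.
* Vendor acquisition formats (ABF, Igor) are not read; the on-disk
  container is the package's own JSON layout, chosen for lossless
  round-trips and text-based diffability.
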