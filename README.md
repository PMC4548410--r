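# sacphys

Analysis of synaptic connectivity and direction selectivity in retinal
starburst amacrine cell (SAC) circuits, for electrophysiologists working
with paired whole-cell voltage-clamp recordings and loose-patch spike
recordings from direction-selective ganglion cells (DSGCs).

SACs are GABAergic retinal interneurons whose mutual inhibitory
connections, and whose *absence* of self-synapses (autapses), depend on
gamma-protocadherin-mediated dendritic self-avoidance. Probing that
circuitry requires a consistent, semi-automated battery of measurements,
which this package provides:

* **Connection detection** in paired recordings. A pair is deemed
  connected when, on the averaged artifact-blanked trace, (1) there is a
  peak in the first 30 ms after presynaptic stimulus onset more than 2
  standard deviations from the 50 ms pre-stimulus baseline, (2) a current
  deflection is present in ≥ 80% of trials, and (3) the peak has onset
  latency < 12 ms and 10–90% rise time < 4 ms. Latency comes from a
  Boltzmann fit to the rising phase,
  `I(t) = base + amp / (1 + exp((t½ − t) / k))`, read at the
  maximal-slope tangent's baseline intercept `t½ − 2k`.
* **Autapse detection** from single-cell recordings: the first 30 ms after
  a brief +60 mV step's return to −20 mV is fit with a double exponential
  `offset + A₁·exp(−t/τ₁) + A₂·exp(−t/τ₂)`; residuals exceeding 2
  baseline SD mark candidates, which must then pass the three connection
  criteria on the residual trace.
* **Direction selectivity**: threshold spike detection, 50 ms peristimulus
  histograms, peak ON/OFF rates over 8 motion directions, and the
  vector-sum index `DSI = |Σ rᵢ·exp(iθᵢ)| / Σ rᵢ` with preferred angle,
  deviation from ventral, ON–OFF differences, and ventral projections.
* **Connectivity statistics**: distance-binned connection probabilities
  with binomial standard errors `√(p̂(1−p̂)/n)`, and a Monte-Carlo null for
  reciprocity that draws two independent Bernoulli(p̂) connections per
  pair (closed form `(p̂², 2p̂(1−p̂), (1−p̂)²)` as the analytic oracle).
* **Mosaic geometry**: density recovery profiles of cell mosaics and the
  circle-intersection model of dendritic overlap,
  `2R²·acos(d/2R) − (d/2)·√(4R²−d²)` for 100 µm-radius arbors.
* **Synthetic data**: seeded generators for all of the above — planted
  postsynaptic currents on Gaussian noise, intrinsic transients with
  optional autaptic events, von Mises-tuned Poisson spike trains,
  hard-core mosaics, and population connectivity tables — each emitting
  its ground truth in metadata.

## Worked example

```r
library(sacphys)

# a paired recording with a planted 15 pA, 7 ms-latency IPSC
rec <- simulate_paired_recording(TRUE, seed = 42)
detect_connection(rec)
#> <detection_result> CONNECTED
#>   peak 14.24 pA, latency 6.82 ms, rise 1.91 ms, trials 90%
#>   criteria: peak_2sd pass, presence_80pct pass, latency_rise pass
```

The planted event is recovered: the averaged peak (14.2 pA) sits near the
programmed 15 pA (the shortfall is amplitude jitter and one release
failure, visible as 90% trial presence), the fitted onset latency of
6.8 ms matches the planted 7 ms, and the 1.9 ms rise time is comfortably
inside the 4 ms criterion.

```r
# an autaptic current riding on the depolarisation-evoked transient
detect_autapse(simulate_autapse_recording(TRUE, seed = 42))
#> <detection_result> CONNECTED
#>   peak 8.40 pA, latency 7.07 ms, rise 0.94 ms, trials 100%
#>   criteria: candidate pass, peak_2sd pass, presence_80pct pass, latency_rise pass

# direction tuning of a ventral-preferring cell (270 deg)
sts <- simulate_direction_response(tuning_params(preferred_angle_deg = 270,
                                                 kappa = 2),
                                   n_reps = 8, seed = 42)
analyze_tuning(sts)
#> <tuning_result> ON DSI 0.604 @ 276 deg (6 deg off ventral); OFF DSI 0.576 @ 273 deg

# distance-binned connection probability in a synthetic juvenile cohort
tbl <- simulate_population_connectivity(n_pairs = 200, seed = 42)
connection_probability_by_distance(tbl)
#>         bin n_tested n_connected     p_hat         se
#> 1  [35,100)      172         107 0.6220930 0.03697055
#> 2 [100,175]      228          78 0.3421053 0.03141888

# Monte-Carlo null for reciprocal connectivity
reciprocity_null(tbl, n_sim = 1e4, seed = 43)
#> <reciprocity_null> 200 pairs, p_hat = 0.463, 10000 simulations
#>           bidirectional unidirectional unconnected
#> observed          45.00         95.000      60.000
#> null mean         42.76         99.302      57.938
#> p                  0.75          0.581       0.799

dendritic_overlap_area(100)   # two 100 um arbors, somata 100 um apart
#> [1] 12283.7                 # um^2
```

Closely spaced pairs are roughly twice as likely to be connected as
distant ones, and the observed reciprocity counts of this (independently
generated) table sit inside their null — as they should, since its two
directions were drawn independently.

An end-to-end run over three genotypes, with all artifacts written to a
directory:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "sacphys")
run_pipeline(cfg, "demo_out")
```

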