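# respigate

Respiratory motion blurs PET images: during a multi-minute acquisition the
liver, diaphragm and lung bases travel a centimetre or more, smearing
lesions and depressing their measured uptake. Quiescent-period gating
mitigates this by keeping only the counts acquired during the low-motion
end-expiration part of each breath — typically half the data — trading
motion blur for noise. Whether a *fixed-offset* gate (the same phase
window applied to every breath) or a *cycle-specific amplitude-driven*
gate (seeded at each breath's amplitude minimum and grown until it holds
half that breath's counts) serves a given patient better depends on how
regular their breathing is.

`respigate` is a simulation toolkit for exactly this question, aimed at
medical-physics and image-reconstruction researchers. It provides:

* **Waveform and list-mode simulators** — seeded raised-cosine breathing
  traces with controllable period/depth jitter, noise and drift
  (`simulate_trace()`, `waveform_presets()`), and homogeneous-Poisson
  event streams carrying the axial displacement at each event time
  (`simulate_events()`).
* **Cycle analysis** — prominence-filtered breath-peak detection,
  cycle segmentation, and the breathing-regularity metric **tvar**
  (dispersion of breath durations; `analyze_cycles()`, `compute_tvar()`).
* **Gating** — Method 1, fixed-offset quiescent-period gating: each cycle
  starting at *s* retains `[s + 0.3 T̄, s + 0.8 T̄)` of the scan-mean
  period T̄; and Method 2, amplitude-driven gating: each gate starts at
  the cycle's minimum amplitude and expands sample-by-sample toward the
  lower-amplitude neighbour until it encompasses 50% of that cycle's
  counts (`gate_method1_qpg()`, `gate_method2_adaptive()`). Plus the
  **overlap** fraction (counts selected by both methods, geometric-mean
  normalised) and a spectral **R value** (percent of periodogram power at
  the dominant respiratory frequency; trigger threshold 15).
* **Phantom simulation** — a six-sphere (10–37 mm, 4:1 contrast)
  image-quality phantom in a uniform cylinder, Gaussian PSF, residual
  motion blur from the gated displacement distribution, and Poisson count
  noise per reconstruction arm (`build_static_phantom()`,
  `simulate_arm()`).
* **Image metrics** — per-sphere contrast recovery
  `CR = ((C_H/C_B − 1)/(a_H/a_B − 1))·100`, background variability
  `BV = (SD/C_B)·100`, `CNR = CR/BV`, liver-VOI `SNR = mean/SD` (30 mm
  sphere), and `suv_max()` (`measure_iq()`, `liver_snr()`).
* **Comparison harness** — seeded multi-arm experiments and the standard
  testing chain: Kruskal–Wallis omnibus, gatekept Wilcoxon signed-rank /
  paired-t pairwise tests, Bonferroni correction, overlap-on-tvar
  regression and tvar-threshold stratification (`run_experiment()`,
  `omnibus_then_pairwise()`).

A thin command-line wrapper (`exec/respigate`) exposes the simulators and
gating for shell pipelines.

## Worked example

Gate an irregular breather (4 s mean period, 1 s period jitter, ±15 mm
excursion) and score a Method-2 reconstruction arm:

```r
library(respigate)
presets <- waveform_presets(duration = 120)
presets$irregular$seed <- 1
trace  <- simulate_trace(presets$irregular)
events <- simulate_events(trace, rate = 1000, seed = 2)
cycles <- analyze_cycles(trace)
cycles
#> <cycle_set> 27 breaths, mean period 4.204 s, tvar (sd) = 0.7066

m1 <- gate_method1_qpg(cycles, events)
m2 <- gate_method2_adaptive(cycles, trace, events)
m1; m2
#> <gate_mask> method1: 27 windows, retained fraction 0.471
#> <gate_mask> method2: 27 windows, retained fraction 0.482
compute_overlap(m1, m2, events)
#> <overlap_result> overlap = 0.858 (48935 of 56329/57721 events)
compute_r_value(trace)
#> <r_value> R = 23.34 (band 0.10-0.40 Hz, peak 0.225 Hz): exceeds threshold 15
```

Both gates retain close to the 50% duty target (the shortfall is real:
partial breaths at the scan edges are never gated, and the fixed-offset
window clips on short cycles). The overlap of 0.86 and tvar of 0.71 say
this trace is only moderately irregular — the two methods still select
mostly the same counts. The R value of 23 would trigger gating clinically.

```r
spec <- phantom_spec()
arm  <- recon_arm("method2_gated", count_budget = 1, gate_mask = m2)
vol  <- simulate_arm(spec, trace, arm, seed = 3)
round(measure_iq(vol, spec)[, c("sphere_mm", "CR", "BV", "CNR")], 2)
#>   sphere_mm    CR   BV   CNR
#> 1        10 36.91 7.37  5.01
#> 2        13 37.62 4.59  8.20
#> 3        17 54.46 2.76 19.77
#> 4        22 69.73 2.00 34.91
#> 5        28 75.88 1.93 39.37
#> 6        37 83.21 1.60 52.16
liver_snr(vol)
#> <liver_noise> mean 0.9971, SD 0.2089, SNR 4.773 (739 voxels, 30 mm VOI)
```

Contrast recovery climbs with sphere diameter (partial-volume and residual
motion hit the 10 mm sphere hardest) while background variability falls —
the CR/BV tradeoff all gating decisions are about. `run_experiment()`
automates this over waveform × repeat × arm grids and
`compare_arms()` applies the omnibus-then-pairwise statistics.

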