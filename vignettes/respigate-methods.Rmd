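---
title: "Respiratory gating methods and phantom simulation in respigate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory gating methods and phantom simulation in respigate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respigate)
```

## The problem

Breathing moves the organs of the thorax and upper abdomen by a centimetre
or more during a PET acquisition of several minutes. The reconstruction
integrates counts over that motion, so lesions are smeared, their maximum
uptake is underestimated, and small foci near the diaphragm can disappear
altogether. Quiescent-period gating (QPG) counters this by keeping only the
counts acquired during the low-motion end-expiration part of each breath —
typically half of the data — at the cost of doubling the image noise
contribution per retained count.

`respigate` implements, on simulated data, the two data-driven gating
policies this tradeoff has produced, the waveform-regularity metrics used
to decide between them, a motion-blurred image-quality phantom to quantify
their effect, and the statistical machinery to compare reconstruction arms.

## The breathing model

`simulate_trace()` concatenates raised-cosine breaths. Breath $i$ draws a
period $T_i \sim \mathcal{N}(\mu_T, \sigma_T)$ truncated below at
$\mu_T/2$ and a depth $A_i \sim \mathcal{N}(A, \sigma_A)$ truncated at 0;
within the breath the displacement at phase $p \in [0,1)$ is

$$x(p) = A_i\,\bigl(1 - \cos 2\pi p\bigr),$$

so every breath starts and ends at its end-expiration minimum, peaks
mid-cycle at $2A_i$, and the `amplitude` parameter is half the
peak-to-peak excursion (the default 15 mm reproduces a $\pm$15 mm motion
platform throw). White measurement noise and a random-walk baseline drift
are added per sample at 25 Hz.

`waveform_presets()` fixes the two study conditions: a *typical* breather
($\sigma_T = 0.25$ s, $\sigma_A = 1$ mm) and an *irregular* breather
($\sigma_T = 1$ s, $\sigma_A = 3$ mm), both at a 4 s mean period. The
irregular jitter levels were chosen so that detected tvar values straddle
the conventional 1.5 regularity threshold; they are a modelling choice,
not a fit to any measured waveform.

What the generator deliberately does not emulate: hysteresis (inhale and
exhale follow the same path), apnoea pauses, sighs and body shifts, and
any coupling between breath depth and period. Tests passing on these
traces therefore demonstrate algorithmic correctness, not robustness to
every pathological clinical waveform.

## Cycle detection and tvar

`detect_breath_peaks()` finds local maxima, filters them by topographic
prominence (default threshold: 20% of the trace's dynamic range, chosen
only to exclude noise and artifacts) and enforces a minimum peak spacing.
The 10 ms default spacing follows the tracker convention; it is far below
any physiological breath and so never suppresses a genuine peak — a 1 s
sanity preset exists but is never applied silently.

`segment_cycles()` builds one cycle per consecutive peak pair. Two
conventions coexist on purpose:

* **Gating segments** span peak to peak, so the end-expiration minimum of
  every breath is *interior* to its cycle. This is what lets the adaptive
  gate grow symmetrically around the trough, and it places the trough at
  roughly mid-phase, which is why the fixed-offset method's default
  window (offset 0.3, duty 0.5 of the mean period) brackets it.
* **Durations** are measured between successive end-expiration
  *boundaries* (the amplitude minima between peaks, opened by the minimum
  of the segment before the first peak). Peak-to-peak spacing is the
  average of two adjacent periods and would understate period variability
  by a factor $\sqrt 2$ for independent jitter; minima spacing measures
  each breath once. The suite checks this calibration directly: injected
  period jitter of 0.5 s is recovered within 30% in at least 95% of
  200 seeded scans.

`compute_tvar()` reports the sample standard deviation of the durations by
default (`mode = "sd"`, units s); the variance convention (units s²) used
by some reports is available as `mode = "var"`, and every result carries
the mode that produced it.

## The two gating methods

Both methods aim to keep a duty fraction (default 0.5) of the counts.

**Method 1 — fixed-offset QPG.** With scan-mean period $\bar T$, every
cycle starting at $s$ retains $[s + 0.3\,\bar T,\; s + 0.8\,\bar T)$,
clipped to the cycle. The offset never adapts; that is the method's
defining property and its weakness. On irregular breathing, cycles shorter
than $0.8\,\bar T$ clip the window, and counts falling in the partial
breaths before the first and after the last detected peak are never
gated, so the realised retained fraction falls a few percentage points
below the duty setting (about 47–48% instead of 50% at 1 s period
jitter). The package reports the achieved fraction rather than forcing
the nominal one.

**Method 2 — cycle-specific amplitude-driven gating.** Each gate is
seeded at the cycle's amplitude minimum and expands one trace sample at a
time toward whichever neighbour has the lower amplitude (ties toward the
earlier side), stopping at the first step that encompasses the duty
fraction of *that cycle's* counts. The duty target is enforced per cycle
— the text of the method is per cycle — and the scan-level fraction is
reported for verification; it can overshoot the target by at most one
sample's worth of events per cycle. With uniform event density the greedy
window is exactly the minimal contiguous window containing the minimum
(the suite proves this against an exhaustive-search oracle on 1000
randomised unimodal cycles); with uneven counts it remains
amplitude-optimal — no window with a lower amplitude ceiling can reach
the target — which is the clinically meaningful notion, since amplitude
is what blurs the image.

**Overlap.** The fraction of counts selected by both methods is
`intersection / geometric mean of the two retained counts`. The geometric
mean keeps the metric defined when duty settings differ and reduces to
the intuitive `intersection / n` for equal-size gates. Regular breathing
drives overlap toward 1 (both methods select the same quiescent counts);
rising tvar drives it down — the suite verifies a negative regression
slope over a 50-scan cohort spanning period jitter 0 to 1.5 s.

**R value.** The commercial trigger metric quantifies how much
respiration-like periodicity a signal carries; its exact formula is
proprietary. The surrogate here is the percentage of total periodogram
power (mean removed, 0 to Nyquist) concentrated in the largest bin inside
the 0.1–0.4 Hz respiration band. A formulation based on the ratio of the
in-band peak to the median out-of-band ordinate was rejected: for white
noise the expected maximum of a few dozen exponential periodogram
ordinates is several hundred percent of the median, so that ratio cannot
sit below a trigger threshold of 15 even for pure noise. The
power-fraction surrogate keeps the conventional threshold meaningful:
breathing-like traces score far above 15, broadband noise scores near
zero (below 15 in at least 95% of 200 seeded noise traces).

## Phantom simulation

`build_static_phantom()` voxelises a simplified image-quality phantom:
six hot spheres (10–37 mm diameter, 4:1 contrast) on a 57.2 mm-radius
coplanar ring inside a uniform cylinder, blurred by an isotropic Gaussian
PSF (default FWHM 5 mm) on a 2.7 mm isotropic grid. The true torso
shell, lung insert and CT-based attenuation are omitted; sphere and ROI
positions are configurable.

Motion enters as a 1-D convolution: `residual_displacement_pdf()`
histograms the trace amplitude over the retained samples (all samples
when ungated; bin width half a voxel) and `apply_motion_blur()` convolves
the volume with that distribution along the motion axis. The kernel is
mean-centred first, so gating narrows the blur without shifting the
image — emulating a reconstruction aligned to the gated motion state;
fractional-voxel displacements are split linearly between neighbouring
voxel offsets, conserving activity to better than 0.1% for interior
structures.

`apply_count_noise()` converts activity to expected counts
(`activity x count_budget x retained_fraction x counts_per_unit`, default
50 counts per voxel per activity unit at full budget), Poisson-samples,
and rescales. Reconstruction-engine differences (regularised iterative
versus OSEM, learned denoising) are deliberately *not* modelled: arms
differ only in count budget, gating and an optional Gaussian
post-smoothing stage, so the six familiar arm labels map onto four
physically distinguishable arms (`default_arms()`; `dle_like = TRUE`
appends the two smoothed gated variants).

## Image-quality metrics

Per sphere $j$, with $C_{H,j}$ the mean counts in an in-plane circular
ROI of the sphere's inner diameter on its central slice and $C_{B,j}$
the mean over twelve same-diameter background ROIs interleaving the
sphere angles:

$$\mathrm{CR}_j = \frac{C_{H,j}/C_{B,j} - 1}{a_H/a_B - 1}\times 100,
\qquad
\mathrm{BV}_j = \frac{SD_j}{C_{B,j}}\times 100,
\qquad
\mathrm{CNR}_j = \mathrm{CR}_j / \mathrm{BV}_j.$$

$SD_j$ is, by default, the standard deviation across the twelve
background ROI *means* (the phantom-standard convention); a voxelwise
variant (`bv_mode = "voxel"`, SD over all pooled background voxels) is
provided because the defining text can be read either way, and both are
exercised by the tests. Liver noise uses a 30 mm spherical VOI in
uniform background: `liver_snr()` returns mean, SD and SNR = mean/SD.
`suv_max()` is the maximum voxel value in a VOI — simulator units are
activity-relative, so no dose or weight normalisation applies.

Numerical contracts worth knowing: CNR is reported as `NA` (never
infinity) when BV is zero; a zero-variance VOI is an error; a flat trace
yields an empty peak list with a warning rather than fabricating cycles;
argmin ties break toward the earlier sample everywhere.

## The comparison harness

`run_experiment()` crosses waveforms x repeats x arms (defaults: the two
presets, three repeats each, four arms), simulating each scan once,
gating it with both methods, and scoring every arm's volume. Everything
derives from one base seed, so reports are bit-reproducible.

`omnibus_then_pairwise()` applies the field's procedure: a
Kruskal–Wallis omnibus across arms, pairwise tests only when the omnibus
is significant (gatekeeping; disable with `gatekeep = FALSE`), Wilcoxon
signed-rank for ordinal-like and uptake metrics, paired t for liver
noise, and Bonferroni adjustment `min(1, p x family)` with the family
defaulting to all pairwise comparisons. R's `wilcox.test()` uses exact
p-values for small tie-free samples and the normal approximation
otherwise. Under the null the omnibus fires at its nominal 5% (checked
over 1000 replicates) and gatekeeping keeps the familywise rate at or
below that.

`stratify_by_tvar()` splits cohorts at tvar 1.5 (boundary values count
as regular — irregularity is *strictly above* threshold), and
`regress_overlap_on_tvar()` fits the overlap-versus-tvar line whose
negative slope summarises why the adaptive method matters for irregular
breathers.

## Problem sizes and runtime choices

The test suite and the acceptance script run on deliberately desk-scale
problems: 120 s scans at 1000 events/s for gating fractions, 404 s
(about 100 breaths) for tvar calibration, 200-seed Monte-Carlo loops for
distributional claims, 20-seed averages for Poisson-scaling checks, a
50-scan cohort for the overlap regression, and 1000 replicates for the
null calibration of the statistics. The phantom grid is 121 x 121 x 47
voxels at 2.7 mm. These sizes make every claim reproducible in minutes
on one core while leaving the estimators' Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

* The waveform family is parametric and symmetric; real quiescent
  plateaus are longer than a raised cosine's, which makes the simulated
  setting slightly *harder* for both gating methods than typical
  clinical breathing.
* Method 1's published implementation is proprietary; the fixed-offset
  rule here (fractions of the scan-mean period, defaults offset 0.3,
  duty 0.5, both configurable) captures its defining fixed-phase
  behaviour, not its vendor-specific placement heuristics.
* The R-value surrogate shares the commercial metric's intent and
  threshold semantics, not its formula.
* Image formation is a blur-plus-Poisson emulation: no sinograms,
  scatter, randoms, attenuation or reconstruction nonlinearity. Ordering
  and scaling claims (contrast: static >= gated >= ungated moving; noise
  proportional to inverse square root of counts) are the meaningful
  outputs; absolute CR/BV values are not calibrated to any scanner.

## A minimal session

```{r example, eval = FALSE}
presets <- waveform_presets(duration = 120, seed = 1)
trace <- simulate_trace(presets$irregular)
events <- simulate_events(trace, rate = 1000, seed = 2)
cycles <- analyze_cycles(trace)

m1 <- gate_method1_qpg(cycles, events)
m2 <- gate_method2_adaptive(cycles, trace, events)
compute_overlap(m1, m2, events)
compute_r_value(trace)

spec <- phantom_spec()
arm <- recon_arm("method2_gated", count_budget = 1, gate_mask = m2)
vol <- simulate_arm(spec, trace, arm, seed = 3)
measure_iq(vol, spec)
liver_snr(vol)
```
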