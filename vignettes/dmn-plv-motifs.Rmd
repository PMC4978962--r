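---
title: "Longitudinal DMN connectivity ratios and motif permutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal DMN connectivity ratios and motif permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvmotif)
```

## The analysis this package implements

`plvmotif` implements a longitudinal source-space MEG connectivity analysis
of the default mode network (DMN) in a two-group cohort measured at two
sessions about two years apart: a control group and a binge-drinking (bd)
group. The scientific question is whether the bd group's resting-state DMN
synchronisation *increases* over time while controls show the flat or
slightly decreasing trajectory expected from normal adolescent maturation.

The analysis chain is:

1. **Band-limited connectivity.** Node time series (156 source nodes spread
   over six DMN ROIs: Pc, PCC, ACC, FMC, lIPL, rIPL) are band-pass filtered
   into delta (2–3.9 Hz), theta (4.1–7.9 Hz), alpha (8.1–11.9 Hz) and beta
   (12.1–29.9 Hz) with a two-pass (zero-phase) order-1500 FIR filter at
   1000 Hz, segmented into 4-s trials (at least 15 per subject), and
   summarised per trial by the phase-locking value
   \(\mathrm{PLV}_{ij} = \bigl|\tfrac1T \sum_t e^{i(\varphi_i(t)-\varphi_j(t))}\bigr|\),
   averaged across trials into a symmetric node-by-node matrix per subject,
   session and band.
2. **FC ratio.** Each link's follow-up PLV is divided by its baseline PLV;
   ratios above 1 mean increasing synchronisation.
3. **Link-wise permutation ANCOVA.** Per link, an OLS ANCOVA of the ratio
   on group with sex as covariate; the group F statistic is referred to a
   Freedman–Lane permutation null (5000 permutations by default), keeping
   links with \(p < 0.05\).
4. **Motif extraction.** Connected components of the significant-link graph
   qualify as motifs when, for each ROI of the analysed pair, they contain
   at least 25% of that ROI's nodes, and their significant links are at
   least 10% of the pair's link universe.
5. **Motif-level correction.** A max-statistic permutation test on the
   motif *mass* (sum of member-link F values) controls the family-wise
   error across candidate motifs.
6. **Motif summaries.** Per subject, the motif *degree* is the mean PLV
   ratio over member links; degrees feed a sex-adjusted ANCOVA (p
   multiplied by 5 for the analysed bands), Cohen's d with the pooled SD,
   per-group one-sample t-tests against 1, and a leave-one-out
   logistic-regression classification.
7. **Structural arm.** Per-tract DTI scalars (FA, MD, RD, AD) are tested by
   a sex-adjusted repeated-measures ANCOVA; in the study design this arm is
   a null control: functional change precedes detectable structural change.

Because the original MEG recordings are not available, the package ships a
synthetic cohort generator whose coupling parameters map analytically onto
PLV, so every stage is testable end to end and planted effects have known
ground truth.

## The generator: von Mises phase coupling with known PLV

Each coupled block of nodes shares a latent narrowband driver phase
\(\psi(t)\) (carrier at the band's centre frequency, uniform initial phase
per trial, optional slow frequency drift). A member node's phase is
\(\varphi_n(t) = \psi(t) + \delta_n(t)\) with \(\delta_n(t)\) drawn
independently per sample from a von Mises distribution of concentration
\(\kappa_n\). For a pair of jittered nodes the population PLV is the
product of their mean resultant lengths; the per-node concentration is
calibrated so each pair's PLV equals

\[ R(\kappa) = \frac{I_1(\kappa)}{I_0(\kappa)}, \]

the mean resultant length of a von Mises variable with the block's nominal
concentration \(\kappa\) (`expected_plv()`, inverted by
`plv_concentration()`). Sampling uses the Best–Fisher (1979) rejection
algorithm (`rvon_mises()`).

Two design points deserve emphasis:

* **Fast-mixing jitter.** The phase offsets are redrawn at every sample
  rather than once per trial. With the within-trial time-average PLV
  estimator, a constant per-trial offset would give PLV = 1 for every
  trial regardless of \(\kappa\); ergodic per-sample mixing is what makes
  the time average converge to \(R(\kappa)\) and gives uncoupled pairs the
  single-trial Rayleigh noise floor \(\sqrt{\pi/4T}\) (\(\approx 0.028\)
  at \(T = 1000\) samples). The cost is that the *signal-kind* output is
  only approximately narrowband: after FIR filtering the jitter is
  smoothed and empirical PLV rises toward 1, so group effects survive the
  signal path qualitatively but not with the analytic calibration. All
  calibration claims are therefore made on the phase-kind path; the signal
  path is exercised end to end as an integration surface.
* **Uniform blocks.** A connected coupling component must carry a single
  \(\kappa\); mixed strengths within a block have no consistent per-node
  decomposition and are rejected as invalid plans.

The generator's cohort defaults are the study's: 22 controls (12 female),
17 binge drinkers (8 female), two sessions. Longitudinal defaults multiply
every coupling concentration by 0.95 at the follow-up session for controls
(maturation: ratio slightly below 1) and by 1.15 for the bd group
(hypersynchronisation: ratio above 1). The per-ROI node counts of the
156-node layout are not published; the package allocates 26 nodes per ROI
by default and makes the allocation configurable. Node MNI coordinates are
placed on a 1-cm lattice around the ROI centre coordinates; they feed only
the motif centroid report, never a statistic.

## Numerical and procedural choices

* **Analytic signal and edge trimming.** Phases of signal-kind trials come
  from the FFT-constructed analytic signal. 10% of samples at each trial
  end are discarded before the PLV time average, because the analytic
  signal is unreliable at segment edges. Phase-kind data carry exact
  phases, so no trimming is applied there.
* **Filter scaling.** The FIR band-pass keeps the 1500-tap order at
  1000 Hz and scales the tap count proportionally at other sampling rates
  (rounded to an even count), preserving the transition width in Hz.
* **Permutation scheme.** The nuisance covariate (sex) is handled by
  Freedman–Lane: residuals of the sex-only model are permuted over whole
  subjects and added back to the reduced fit. P-values use the add-one
  estimator \((1+b)/(1+B)\), which is valid and never zero; with the
  strict `p < 0.05` retention rule and \(B\) permutations the *exact*
  size of the discrete test is \(\lceil 0.05 (B+1) \rceil - 1\) over
  \(B+1\) — 0.045 rather than 0.05 at \(B = 199\), which is what the
  calibration suite checks against.
* **Synchronised motif null.** The motif-level correction re-applies the
  link-threshold-plus-extraction procedure to every permutation, using
  pooled ranks within one \((B+1)\)-row F ensemble rather than nesting a
  second permutation loop inside each permutation (the standard
  construction of cluster-based / network-based-statistic tests, at
  \(B\) instead of \(B^2\) cost). The pooled-rank p of the observed row
  reproduces the add-one link p exactly, so the observed significance
  pattern is identical between the two stages at the same seed.
* **Link-density denominator.** "10% of the links" is read against the
  full ROI-pair universe (the analysed set), with a component-internal
  option; the node-coverage rule is applied to *each* ROI of the pair,
  the stricter reading.
* **Ratio guard.** A baseline PLV below `1e-6` is floored (with a
  warning) instead of erroring: exactly zero PLV has measure zero but can
  occur in degenerate synthetic input.
* **Ties in classification.** A leave-one-out predicted probability of
  exactly 0.5 classifies as control, making the procedure deterministic.
* **Cohen's d.** Pooled-SD formula, oriented bd − control. Recomputing
  the published effect sizes from the printed group means and SDs with
  this formula does not reproduce the printed values (e.g. the delta
  FMC–Pc row gives 1.34, printed 1.7), so printed effect sizes are not
  used as reference values anywhere; the printed one-sample t-test
  bounds are used only for the rows where they are internally consistent
  with the printed summary statistics.
* **RM-ANCOVA form.** The repeated-measures ANCOVA is computed in its
  difference-score form (session difference and session mean regressed on
  group + sex). On complete balanced data the interaction F is identical
  to the within-subject stratum of the classical mixed two-way model —
  the suite checks agreement to 1e-8.

## What the synthetic cohort does and does not emulate

The generator reproduces the features the statistics rely on: group and
session structure, narrowband phase coupling with controlled PLV, the
maturation-versus-hypersynchronisation contrast, estimation noise at
realistic trial counts, and a complete DTI table with optional planted
interactions. It does not emulate sensor-level physics (no lead fields, no
volume conduction, no beamforming), amplitude dynamics, artifacts,
between-subject coupling heterogeneity, or spatially correlated noise.
Passing the suite therefore demonstrates the *statistical machinery* is
correct and calibrated under a faithful null; it does not certify
performance on real MEG recordings.

## Problem sizes used by the test and acceptance suites

The suites run at desk scale, chosen so the full set of calibration
replicates completes in minutes while keeping every estimator in its
asymptotically relevant regime: 24-node atlas (4 nodes per ROI) or smaller
purpose-built layouts, 250 Hz sampling, 4-s trials, 20 trials per subject,
199 permutations for replicated calibration loops, the full n = 39 cohort
everywhere a cohort is used. The planted-effect suite calibrates its
effect size from a fixed-seed pilot estimate of the across-subject
per-link ratio SD under the null generator conditions, then sets the
bd-post concentration so the expected ratio is \(1 + 3\,\mathrm{SD}\).
Full-scale settings (156 nodes, 1000 Hz, 5000 permutations) are plain
configuration changes.

## Known limitations

* Alpha-band group effects are not expected (the study design treats alpha
  as a computed-but-null band), and the package plants none by default.
* The signal-kind path compresses ratio effects toward 1 (see above);
  quantitative calibration claims hold on the phase path only.
* The LOO classifier is the study's: a univariate logistic regression on
  motif degree. It is deliberately not a tuned classifier.
* With 199 permutations the smallest attainable corrected p is 1/200;
  studies needing tighter bounds must raise `n_perm`.
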