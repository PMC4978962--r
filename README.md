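# plvmotif

Longitudinal source-space MEG functional connectivity of the default mode
network (DMN), for researchers studying how resting-state synchronisation
changes over time between two groups — here, young binge drinkers followed
over two years against age-matched controls.

The package implements the full statistical chain of that design and a
synthetic phase-coupled cohort generator with analytically known ground
truth, so the entire pipeline runs, and is tested, without any MEG or MRI
recordings.

## The analysis

For node time series spread over six DMN ROIs (Pc, PCC, ACC, FMC, lIPL,
rIPL; 156 nodes at full scale), per band (delta 2–3.9, theta 4.1–7.9,
alpha 8.1–11.9, beta 12.1–29.9 Hz):

1. zero-phase FIR band-pass (order 1500 at 1000 Hz, scaled with the
   sampling rate), segmentation into 4-s trials (≥ 15 per subject);
2. phase-locking value per trial and node pair,
   PLV_ij = |mean_t exp(i(φ_i(t) − φ_j(t)))|, averaged across trials;
3. FC ratio per link: follow-up PLV / baseline PLV (ratio > 1 = rising
   synchronisation);
4. link-wise ANCOVA of the ratio on group with sex as covariate, assessed
   by Freedman–Lane permutation (5000 permutations, p < 0.05 retained);
5. motif extraction: connected significant sub-networks covering ≥ 25% of
   each ROI's nodes and ≥ 10% of the pair's links;
6. motif-level max-mass permutation correction (family-wise error
   control);
7. motif summaries: per-subject degree (mean ratio over motif links),
   sex-adjusted ANCOVA with ×5 band Bonferroni, pooled-SD Cohen's d,
   per-group one-sample t-tests against 1, leave-one-out
   logistic-regression accuracy;
8. a parallel repeated-measures ANCOVA on per-tract DTI scalars
   (FA/MD/RD/AD) — the structural null arm.

The generator couples node blocks through von Mises phase jitter around a
shared driver, so a coupled pair's population PLV is exactly
I1(κ)/I0(κ) (`expected_plv()`); planted group × session coupling changes
therefore have known effect sizes.

## Worked example

```r
library(plvmotif)
report <- run_pipeline(demo_config(seed = 11, n_trials = 15))
m <- report$bands$theta[["FMC-rIPL"]]$motifs[[1]]
```

The demo configuration plants the frontal–parietal hypersynchronisation
(bd-group coupling × 1.15 at follow-up, controls × 0.95) on a 24-node
atlas and recovers it:

```
FMC-rIPL universe: 16 links, 16 significant
motif: 8 nodes, 16 links, mass 26885.6, corrected p = 0.005
  degree bd 1.062 +/- 0.002 | control 0.976 +/- 0.002
  ANCOVA p (x5) = 2.632e-47, Cohen's d = 38.24, LOO accuracy = 100%
  t-test vs 1: bd t = 109.98 (p = 1.82e-24), control t = -51.53 (p = 1.35e-23)
```

Read: the motif spans all 8 coupled nodes with the smallest attainable
corrected p (1/200 at 199 permutations); the bd group's degree mean is
above 1 (synchronisation rose over the two sessions) while controls sit
below 1 (normal maturation); the two groups separate completely. A null
configuration (`null_config()`, both groups maturing alike) returns no
significant motif.

The numbered drivers under `analysis/` walk the same chain step by step
(cohort + calibration, signal-path connectivity, motif statistics,
structural arm) and write their tables under `results/`.

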