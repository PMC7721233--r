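---
title: "Motion opponency in visual cortex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion opponency in visual cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opponency)
```

## The scientific problem

Flicker — any abrupt luminance change — carries omnidirectional motion
energy that early motion detectors process like real motion, even though it
says nothing about direction. Models of cortical motion processing posit a
*motion opponency* stage that pools oppositely directed local signals:
balanced motion (flicker) cancels at this stage, while coherent directional
motion survives. In human fMRI this predicts a specific *multivariate*
signature in motion-sensitive cortex for three dot stimuli built on
identical Glass-pattern geometry:

* **IP (in-phase)**: both dots of a pair translate together along the pair
  axis; half the pairs move one way, half the other. Bidirectional, but not
  locally balanced.
* **CP (counter-phase)**: the two dots of a pair move in opposite
  directions along the axis. Locally balanced — an opponent stage outputs
  nothing.
* **NM (nonmotion)**: dots only appear and disappear (limited-lifetime
  flicker), no translation.

A region implementing opponency should (1) separate IP from both CP and NM,
(2) represent CP and NM almost identically, so a classifier trained on
either against IP absorbs the third condition into its balanced lookalike.
The package implements the full analysis needed to test this: stimulus
generation, block-design BOLD simulation, beta-series GLM, leave-one-run-out
SVM decoding, cross-decoding transfer, within-run permutation inference,
and the univariate percent-change statistics.

## Stimulus engine

All three conditions share one texture: 250 pairs of 3-px white dots on a
grey field, pair axes aligned with the trial's Glass orientation (a cardinal
axis ±15°), within-pair separation at most 8 px, and a 150 ms dot lifetime.
A 12 s block holds six 1.1 s trials separated by 500 ms dot-free intervals;
because 6 × 1.6 s = 9.6 s, the final 2.4 s of each block is fixation only —
the printed trial and block durations are both preserved. Runs alternate
12 s stimulus and 12 s blank blocks; we open each run with a blank so every
block has a pre-onset baseline.

Numerical design choices worth knowing:

* **Exact balance arithmetic.** Dot positions live on an integer grid of
  1/9 px (the per-frame step is 8 px per 9-frame lifetime, i.e. 8 units per
  frame). Every frame-to-frame displacement is therefore exactly
  representable, and `motion_energy_balance()` returns *exactly* zero for
  balanced blocks instead of a rounding residue. The grid is ~0.003° of
  visual angle — far below a pixel, so this is not a visible quantisation.
* **Age-yoked IP staggering.** The +axis and −axis halves of the IP pairs
  receive the same multiset of random initial lifetimes. Each pair's
  replotting is still uniformly staggered, but the two direction groups
  replot in lockstep, making the bidirectional stimulus balanced on every
  single frame — the 125/125 split holds exactly, frame by frame.
* **Confinement instead of edge replotting.** A pair's random centre is
  drawn so that its entire lifetime trajectory (at most 8 px of travel plus
  the 8 px separation) stays on screen. No dot ever exits mid-life, which
  keeps the exact balance bookkeeping intact; the excluded border is ≤12 px
  of a 1024×768 display.
* **CP phase.** A CP pair starts 8 px apart, each dot moving 8/9 px per
  frame toward and then past its partner; when separation regains 8 px
  (after 9 frames) the pair is replotted at a random position, with a
  random initial phase per pair.

One known tension in the printed stimulus parameters: 8 px of travel per
150 ms at 0.027–0.031 °/px implies a dot speed of ≈1.4–1.7 °/s, not the
2.3–2.6 °/s quoted alongside those numbers. The geometry (travel, lifetime,
pixel size) is internally consistent and is taken as ground truth; the
package nowhere asserts the quoted speed range. Relatedly, the quoted
localizer speed bound of 7.4 °/s and ring radius of 10.4° are reproduced
only when the per-pixel angle is first rounded to its printed two
significant figures (0.031 and 0.027); `speed_deg_per_s()` therefore
accepts an explicit `deg_per_px` for computations at printed precision.

## Synthetic BOLD model

`simulate_participant()` builds each run as

```
data = baseline
     + Σ_blocks response(condition) ⊗ HRF-convolved boxcar
     + linear drift + motion leakage + AR(1) Gaussian noise
```

with the condition response vector `amplitude_c · 1 + s · p_c`. The `p_c`
are unit-norm voxel patterns orthogonal to the uniform vector, constructed
(not sampled) to have exactly the requested pairwise correlations via the
symmetric square root of the correlation matrix applied to a random
orthonormal basis. Orthogonality to the uniform vector means patterns do
not move the ROI mean: the univariate stage sees exactly `amplitude_c`,
the decoding stage sees the patterns.

Defaults and why:

* **Amplitudes** IP 3.39, CP 3.08, NM 3.04 (percent signal on a baseline of
  100) — the group-average V5 percent-change values of the study being
  emulated, so univariate output is directly comparable.
* **Pattern geometry**: CP–NM correlation 0.95, IP correlation 0.2 with
  each. This encodes the opponency hypothesis — CP and NM nearly share a
  representation — while leaving CP/NM marginally separable, the profile
  reported for accompanying motion-sensitive areas.
* **Pattern strength 2 and voxel noise SD 3** (AR(1) 0.3, drift ±1,
  60 voxels): chosen together, once, so that the default group decoding
  operating point lands mid-band at ≈75% for IP-vs-CP with CP-vs-NM near
  chance — the regime in which the cross-decoding bias analysis is
  meaningful. A literal per-voxel SD of 1 on this signal geometry yields
  near-ceiling decoding and would make every qualitative comparison
  trivially saturated.
* **Between-participant jitter** (10%): a common response gain and a
  rescaling of each condition's deviation from the mean amplitude, plus a
  small random rotation of each pattern. Jittering the raw amplitudes
  themselves would scramble the ~0.3% condition ordering across
  participants, which is not how stable within-subject designs behave.
* **Motion**: six smoothed random-walk series are produced per run, appear
  in the GLM as z-scored nuisance regressors, and leak weakly
  (SD 0.1 loadings) into the voxel signals.

What the simulator does *not* emulate: spatial voxel correlations,
physiological (cardiac/respiratory) noise structure, nonlinear HRF
saturation, scanner drift nonlinearity, and real ROI geometry. Passing
tests on synthetic data therefore demonstrate the correctness and
statistical calibration of the machinery, not that any real dataset will
show the effect.

## Beta-series GLM

Each block gets its own regressor: a boxcar over the block convolved with a
double-gamma HRF and peak-normalised, so a plateau response of amplitude
`a` maps to a coefficient of `a` (with `standardize = FALSE`). Following
the modelled analysis, block and nuisance columns are z-scored by default;
z-scoring rescales coefficients but cannot change decoding, which is
invariant to per-voxel linear maps shared by all blocks. The HRF is
parameterised by lobe modes (peak 6 s, undershoot 16 s, dispersions 1,
ratio 6, 32 s support), the common default double-gamma family; the source
analysis names only its toolbox's default kernel, so the exact parameters
are exposed in `hrf_params()`. Estimation is ordinary least squares per
voxel with a hard error on rank deficiency (naming the collinear columns).
Optional discrete-cosine columns (cutoff 128 s) stand in for highpass
filtering inside the model rather than as a signal-domain filter.

Percent-change time courses divide each block's window by that block and
voxel's intensity at the onset TR (×100, −100). The published sentence
admits a per-voxel or ROI-mean baseline; per-voxel is used. The summary
window averages 10 TRs (one 12 s block at TR 1.2 s) beginning at the
*fourth TR after onset* interpreted as 0-based index 4 — forced by the
accompanying "4.8 s after stimulus onset".

## Decoding and cross-decoding

Pairwise decoding trains a soft-margin linear SVM (cost 1, no feature
scaling, `e1071`/libsvm) on 7 of 8 runs and tests on the held-out run;
performance is the average of the eight folds. The fitted machine is
reduced to an explicit `(w, b)` oriented so a positive decision value means
the canonically first label, and a decision value of exactly zero also goes
to that label — a deterministic tie rule. No voxel selection and no feature
normalisation are applied by default (a `scale` flag exists).

Cross-decoding trains on two conditions and labels the held-out run's
blocks of the *untrained* condition, accumulating over folds; the reported
quantity is the fraction of untrained blocks absorbed by each trained
class. Only ROIs whose group-mean accuracy strictly exceeds 70% in at
least two of the three pairwise decoders enter this analysis
(`roi_gate()`), since bias is uninterpretable where discrimination fails.

## Permutation inference

Condition labels are permuted *within runs*, preserving each run's label
counts exactly; the same slot-level scheme is applied to every participant,
and each permutation's statistics are averaged across participants to form
one group null (15,200 permutations at full scale; the add-one rank rule
`p = (#{null ≥ observed} + 1) / (n + 1)` makes `1/15201 ≈ 6.6e-5` the
smallest attainable p). Ties count toward the tail, which is conservative
for discrete statistics such as accuracy. The two-tailed rule doubles the
smaller tail and caps at 1; the unpermuted labelling is not re-included as
a null sample, since the `+1` already plays that role. Bonferroni
correction divides alpha by the number of comparisons (3 pairs × 6 ROIs →
2.8e-3 for discrimination; 3 × 2 → 8.3e-3 for bias).

The permutation null can be built with the analysis SVM or with a fast
nearest-centroid rule (`stat_pairwise_accuracy(..., method = "centroid")`);
observed statistic and null always use the same rule. The centroid rule is
what the package's own large calibration studies use, purely for speed.

## Univariate statistics

Averaged percent change per participant and condition feeds a classical
one-way repeated-measures ANOVA (condition over the subject×condition
residual; df (k−1), (k−1)(n−1) — (2, 8) for five participants), fitted via
`stats::aov()` with a subject error stratum. Pairwise contrasts test
condition-mean differences against the same residual error term with its
df. No sphericity correction is applied by default (none was reported);
Greenhouse–Geisser is available behind a flag. Error bars use the
Cousineau within-subject normalisation (participant means removed, grand
mean restored) without the Morey factor, which is likewise available
behind a flag. A reported `t(2,8)` for one contrast is treated as a typo
for `t(8)`.

## Scaled problem sizes

The package's own test and calibration studies run at desk scale, chosen
as follows and fixed: type-I calibration uses 200 null groups of 3
participants (4 runs × 18 blocks, 8 voxels) at 500 permutations with the
centroid statistic; ANOVA null uniformity uses 2,000 replicates of 5×3
tables; signature recovery uses 50 groups of 5 participants at the full
8-run design with the default ROI. The full 15,200-permutation scheme is
exercised where only the scheme itself (not a refit per permutation) is
needed. Note that the tie-conservative rank rule together with a discrete
accuracy statistic makes the realised type-I rate sit slightly *below* the
nominal 5% (typically 3.5–4.5% in the calibration above); finer accuracy
grids (more blocks, folds, participants) move it toward nominal.

## Known limitations

* Real-data mode expects ROI-masked NIfTI volumes with volume-aligned
  block onsets; slice-timing and motion correction are assumed done.
* No residual autocorrelation correction (no pre-whitening): betas are OLS,
  as in the modelled analysis; permutation inference does not rely on
  parametric residual assumptions.
* The SVM is libsvm's hinge-loss C-SVC; squared-hinge solvers are not used.
* Group inference assumes all participants share the run/block label
  structure (true by design here).
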