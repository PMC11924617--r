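---
title: "Methods: weak-foot COP features, the DDI, and the two-stage fall-risk model"
author: "gaitDDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weak-foot COP features, the DDI, and the two-stage fall-risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitDDI)
```

## The problem

Instrumented insoles record per-sensor plantar pressure for both feet while
an older adult walks for a couple of minutes. The goal is to screen for high
fall risk (HR vs LR, a label conventionally anchored to a Berg Balance Scale
cut-off) from that single walk. Two obstacles shape the design:

1. **Short recordings.** A two-minute walk yields one subject-level
   observation. Step-level sliding windows turn a walk of $S$ steps into
   $N = \lfloor (S - L)/s \rfloor + 1$ overlapping samples of $L$ steps at
   stride $s$, at the price of heavy inter-window correlation.
2. **Inconsistent expression.** Some individuals express their high-risk
   gait only episodically on their weaker side. Their short-window feature
   vectors scatter; pooled across subjects they blur the decision boundary
   and degrade a classifier trained on everyone.

The package implements the full pipeline: step segmentation, windowing,
center-of-pressure (COP) feature extraction on the *weak foot*, the
Distribution Difference Index (DDI) with a trainable threshold that flags
"recessive weak foot" (RWF) individuals, and a two-stage classification
model evaluated leave-one-subject-out (LOSO).

## Steps, windows and the weak foot

A *step* is one foot-contact event of either foot: a contact opens when the
per-foot total force rises above `eps` (default 2% of the recording's
95th-percentile total force — real sensors never rest at exactly zero) and
closes when it stays at or below `eps` for 50 ms (shorter dropouts are
bridged). The first two contacts are discarded as gait start-up. Windows of
`L` consecutive steps advance by a stride of `s = 10` steps; a window keeps
both feet's signals over its frame span so symmetry features remain
computable. With `S = 180`, `L = 130`, `s = 10` every subject contributes
`r plan_windows(180, 130, 10)$N` windows.

Per stance frame the COP is the force-weighted mean of the sensor
coordinates. For each window the *weak foot* is the side with the smaller
anterior-posterior COP standard deviation (`Std_y`) — reduced forward
roll-over travel marks a foot that has partially lost gait integrity. Ties
go to the right foot (the left branch of the selection rule is strict).

Fourteen features are computed per window (`feature_registry()`), in three
families:

* **Foot-level** statistics of the weak foot's COP trajectory (mm):
  `Std_x`, `Mean_x`, `Std_y`, `Mean_y`, the mean and SD of the resultant
  distance from the trajectory centroid (`MRD`, `SRD`), the total excursion
  `TOTEX`, and the 95% confidence-circle area
  `CCA` $= \pi\,(MRD + 1.645\,SRD)^2$ — the standard posturography
  confidence-circle formula, adopted here because only the feature's name
  is conventionally fixed.
* **Symmetry** between the feet: `GA` $= 100\,|\ln(m_L/m_R)|$ of mean
  stance durations, cosine similarity `SIM` and Jensen-Shannon divergence
  `JSD` (natural log, so bounded by $\ln 2$) of the two feet's per-sensor
  mean stance-pressure distributions, aligned by sensor index.
* **Temporal consistency**: the same three comparators applied to
  consecutive weak-foot steps and averaged (`GIC`, `SSIM`, `SJSD`). `GIC`
  carries the same $\times 100$ log-ratio scale as `GA` for symmetry
  between the two families; every downstream use z-scores the features, so
  the scale is inert.

The exact comparator formulas for the symmetry and consistency families are
package choices (the family names are conventional, their formulas are
not); they are deliberately simple, documented, and swappable. Population
(not sample) standard deviations are used throughout: windows are short and
the population form is stable. A degenerate input (an all-zero pressure
distribution) yields `NA` for the affected feature with a warning — never a
silent zero. The left foot's `x` is mirrored into the right-foot frame
wherever the two sides enter a common statistic.

## The DDI and the adaptive threshold

For one subject, let $v_1,\dots,v_N$ be the z-scored weak-foot feature
vectors (default 5-D: `Std_y`, `Std_x`, `MRD`, `TOTEX`, `CCA` — a
configurable default, since the originally selected five are not published)
of their windows at one length. The *full-connection distance* is the mean
Euclidean distance over all ordered pairs,
$d_L = \frac{1}{N(N-1)} \sum_{i \ne j} \lVert v_i - v_j \rVert$ (the
normalizer is read as $\sum_{i=1}^{N}(N-1)$ — the only reading under which
the statistic is the average of all pairwise distances). The DDI is the
ratio $d_l / d_h$ of the dispersion at a short window length (default
$d_{20}$) to that at a long length (default $d_{130}$, set to the longest
length the recordings support). The long-window dispersion is the
subject's own baseline, so the ratio cancels overall gait variability and
any common rescaling of the feature space.

Standardization is z-scoring with training-cohort statistics, fitted *per
window length* — features such as `TOTEX` scale with the window length, and
a pooled scaler would let the between-length offset swallow the
within-length variation that the DDI measures.

Episodically expressed high-risk gait scatters short windows (a 20-step
window sits mostly inside or mostly outside an episode) but averages out at
130 steps, elevating the DDI. The trainable threshold interpolates the
training cohort's DDI range, $T = DDI_{\min} + (DDI_{\max} - DDI_{\min})
\alpha$ with $\alpha \in [0, 1]$; a subject with $DDI > T$ (strictly) is
flagged RWF. In robust mode the extremes are replaced by $\mu \pm 3\sigma$
clipped to the observed range, which matters exactly when an extreme RWF
outlier would otherwise stretch the $\alpha$ scale; the raw form is the
default, the robust form a configuration flag.

At test time a held-out subject's DDI is computed from their own unlabeled
windows with the training-fitted scalers; a recording too short for the
configured long length falls back to the longest usable length with a
warning, so deployment does not fail on short walks.

## The two-stage model

Step 1 scans $\alpha$ over 0.14-0.40 in steps of 0.02 (14 candidates; the
narrow range guards both branches against starvation). Each $\alpha$
partitions the training subjects into RWF/DWF; each branch runs three-phase
feature selection:

1. *Pre-selection*: two-sample t-test, keep $p < 0.05$ (if nothing
   survives, the top features by $p$ are kept with a warning).
2. *Multi-method selection*: eleven selectors each nominate a fixed-size
   subset — five filters (ANOVA-F, mutual information on quantile-binned
   features, point-biserial correlation, variance rank, a Relief-style
   nearest-hit/nearest-miss margin), four wrappers (forward and backward
   greedy search around logistic regression and a decision stump, scored by
   subject-grouped CV), and two embedded methods (L1-penalized logistic
   regression, random-forest impurity importance). The wrapper base
   learners are deliberately lightweight; the eleven-selector *structure*
   (5 filter + 4 wrapper + 2 embedded) is fixed, while the selector
   identities are documented package choices.
3. *Final selection*: features ranked by nomination frequency; the
   cardinality maximizes subject-grouped cross-validated accuracy of the
   fixed default-setting surrogate classifier (an RBF-SVM — configurable).

The partition is scored by subject-level (majority-vote), subject-weighted
CV accuracy of the surrogate on the selected features — the quantity the
model is ultimately judged on; the best $(\alpha,$ feature sets$)$ wins,
ties resolved toward the *largest* $\alpha$. On easy training sets many
partitions tie at perfect training accuracy, and preferring the smallest
$\alpha$ then flags the maximal set of subjects, fragmenting the training
data for no measured gain; the conservative tie-break flags nobody without
evidence. Step 2 then picks each branch's
classifier from seven candidates (logistic regression, SVM, k-NN, decision
tree, random forest, gradient boosting, AdaBoost), tuning exactly two
hyperparameters each by subject-grouped label-stratified CV. AdaBoost
(SAMME over depth-1 stumps) is implemented in-package; every other
candidate wraps an established implementation.

All cross-validation is grouped by subject — windows at stride 10 overlap
by up to $L - 10$ steps, so splitting a subject across folds would leak —
and a branch trains its own model only with at least `branch_min = 3`
subjects *and* at least two subjects per class (grouped stratified CV is
undefined below that); otherwise it falls back to the pooled one-stage
model. Subject-level calls aggregate window predictions by majority vote
with ties going to HR: a screening tool prefers a false alarm to a missed
high-risk walker.

LOSO evaluation refits everything — scalers, threshold, feature selections,
tuned classifiers — without the held-out subject, and records a per-fold
fingerprint of the training ids so the absence of leakage is assertable.

## The synthetic cohort generator

No raw recordings from the source cohorts are available, so the package
ships a simulator rich enough to exercise every stage with known ground
truth. Each foot contact emits per-sensor half-sine bursts whose onsets
progress heel-to-toe, plus a small sustained whole-stance load on every
sensor (5% of amplitude). The sustained posterior load keeps the COP a
blend of all sensors, so attenuating the anterior sensors' amplitude and
burst duration shrinks the anterior-posterior COP excursion monotonically —
this *rollover attenuation* is the simulated high-risk effect, and it is
what the weak-foot selection rule keys on. An earlier design that
compressed anterior onsets instead was discarded: at mild attenuation it
lengthened anterior dwell and moved `Std_y` the wrong way.

The defaults are the package's simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| walk length | 222 steps (~2.2 min at 100 steps/min) | the collection protocol's "at least two minutes" |
| sampling rate | 100 Hz | typical instrumented insole; 50 Hz measurably destabilizes window features |
| stance / cadence | 0.8 s, 100 steps/min | ordinary elderly gait |
| timing jitter CV | 0.05 | ordinary step-time variability |
| max attenuation `atten` | 0.55 | a strong but physiological anterior-load reduction |
| severity ranges | HR $U(0.4, 1)$, LR $U(0.18, 0.49)$, RWF $U(0.6, 1)$ | inter-individual heterogeneity; the HR/LR ranges overlap slightly so the hardest subjects are genuinely ambiguous; every subject has an identifiable weak side; the episodic phenotype is defined by episodes of frank high-risk gait |
| RWF low-state expression `lr_frac` | 0.12 | recessive = near-normal background between episodes |
| switching probability | 0.15/step | temporally clustered episodes of a few steps (seconds), per the episodic interpretation |
| multiplicative sensor noise | 4% | a quiet modern pressure insole |
| fatigue trend | 12-20% rollover-depth change per walk, random direction | progressive loading changes over a continuous walk |

The fatigue trend deserves a note, because it is load-bearing. The window
geometry is asymmetric: 20-step windows spread across the whole walk while
130-step windows can only start within the first ~90 steps. Under that
geometry, *any* stationary fluctuation — white sensor noise included —
produces a ratio $d_{20}/d_{130}$ well above 1, and temporally structured
processes produce a *smaller* ratio than white noise, with wide
realization-to-realization spread when the long-window dispersion estimate
rests on few windows. A monotone within-walk trend behaves differently: its
contribution to each $d_L$ is essentially deterministic given the trend
magnitude, giving every subject a stable, nonzero long-window baseline.
With it, consistent (DWF) subjects concentrate at a low ratio while
episodic (RWF) subjects are pushed up by their short-window scatter; without
it, the DDI of consistent subjects is dominated by the realization noise of
a six-to-ten-window dispersion estimate. This is also a statement about the
real world: the DDI's denominator presumes that long windows differ for
*systematic* reasons (fatigue, attention drift), and walks short enough to
yield only a handful of long windows make the index fragile.

What the simulator does **not** emulate: real sensor nonlinearities and
hysteresis, spatially correlated pressure migration, turning at corridor
ends, double-support load transfer, or any biomechanically validated
forward dynamics. Passing tests therefore show that the pipeline recovers
the phenomena the generator encodes — not that the published accuracies
transfer to real cohorts.

## Numerical and design choices

* When $(S-L)/s$ is not an integer the window count floors and the
  trailing remainder of steps is dropped — the only loss-free completion.
* Weak-side ties select the right foot (the strict branch is the left).
* `DDI` is undefined when $d_h = 0$ (all long windows identical): that is a
  degenerate-gait error, not a value.
* A degenerate training cohort (all DDIs equal) yields $T = DDI_{\min}$
  with a warning.
* The $\alpha$ scan caches feature selections by branch membership: many
  $\alpha$ values induce the same partition, and recomputing would only
  burn time (results are identical).
* Phase-3 ties prefer fewer features; unanimous nominations are returned
  unchanged without a phase-3 vote.
* All randomness (fold assignment, selector subsampling, classifier seeds)
  flows from one run seed; classifier wrappers pin `nthread`/`num.threads`
  to 1 for reproducibility.
* `fast_config()` is the scaled-down configuration used by the package's
  own simulation studies: a three-candidate roster (`lr`, `svm`, `dt`),
  reduced two-point grids, 3-fold inner CV, 3-feature nominations and a
  capped phase-1 pool. It shrinks search breadth, never the method's
  structure. The shipped studies use cohorts of 12 subjects (25% RWF) for
  LOSO comparisons, 40 subjects (16/16/8) for threshold recovery, and a
  6-subject pilot sweep over three window lengths; these sizes are the
  package's chosen demonstration scale.
* The LOSO comparison study uses a *strong-effect* cohort (severity ranges
  `sev_hr = c(0.55, 1)`, `sev_lr = c(0.1, 0.4)`): with sixteen subjects a
  borderline-severity cohort turns the two-stage-vs-pooled comparison into
  a coin flip over one or two ambiguous subjects, which measures cohort
  luck rather than the architecture.

## Known limitations

* The "44 features" of the original weak-foot feature set are not
  reconstructible from public sources; the registry ships 14 named
  features, and the five-feature DDI vector is a documented default, not a
  verified reproduction.
* Symmetry/consistency comparators are package definitions of
  conventionally named quantities.
* At cohort sizes around sixteen subjects, branch-specific training sets
  are small; the pooled fallback triggers often and the two-stage model's
  advantage over the pooled baseline is modest and seed-dependent — the
  architecture's value grows with cohort size.
* The DDI requires at least two windows at both lengths; subjects whose
  walks are shorter than the long window length plus one stride fall back
  to a shorter baseline length with a warning.
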