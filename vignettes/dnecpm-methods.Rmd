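---
title: "Predicting motor outcomes from dynamic nodal-efficiency networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting motor outcomes from dynamic nodal-efficiency networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`dnecpm` implements a connectome-based predictive-modeling pipeline for
continuous clinical outcomes — in its motivating application, the
post-levodopa UPDRS-III motor score of Parkinson's patients — from
pre-treatment resting-state fMRI. The pipeline's premise is that the
*dynamics* of functional connectivity carry predictive information that
static connectivity misses. Its feature of choice is the **dynamic nodal
efficiency (dnE) network**:

1. A subject's regional BOLD time series (246 nodes in the packaged
   parcellation) are temporally conditioned: leading volumes discarded,
   nuisance signals regressed out, band-pass filtered to 0.01–0.10 Hz.
2. A sliding window (50 time points, stepped by 1 TR = 2 s) yields a
   sequence of windowed Pearson correlation graphs.
3. In each window, each node's **global efficiency**
   $E_i = \frac{1}{N-1}\sum_{j \ne i} 1/d(i,j)$ (with $d$ the shortest-path
   length) summarizes how easily that node exchanges information with the
   rest of the network; collecting windows gives each node an efficiency
   *curve*.
4. The **dnE matrix** is the node-by-node Pearson correlation of these
   curves: entry $(i,j)$ measures how synchronously the two nodes'
   efficiencies fluctuate. Its entries lie in $[-1, 1]$ by construction.
5. The vectorized upper triangle (30,135 features at 246 nodes) enters an
   L1-penalized regression of the clinical score,

   $$\min_\beta \; \lVert y - x\beta \rVert_2^2 + \tfrac{1}{2}\lambda
   \lVert \beta \rVert_1, \qquad \lambda = 0.08,$$

   evaluated by leave-one-out cross-validation (LOOCV), with significance
   from a label-permutation test and error summarized as MAE.
6. Fold-averaged regression weights are aggregated into a 24-macro-region
   contribution matrix and a per-node prediction-efficacy score in
   $[0, 1]$.

## Signal conditioning

Spatial preprocessing (realignment, normalization, smoothing) is out of
scope: the pipeline consumes ROI-by-time matrices plus, optionally, the
6-column rigid-body motion parameters produced by realignment.

* **Volume discarding.** Default 4 volumes, the usual allowance for
  magnetization equilibration.
* **Motion screening.** Framewise displacement uses the Power
  backward-difference convention, converting rotations to arc length on a
  50 mm sphere (configurable). Subjects are excluded when *mean* FD
  exceeds 1 mm. The choice of the mean (rather than maximum) statistic is
  a design decision: a mean above 1 mm indicates pervasive motion rather
  than isolated spikes, and matches the magnitude of exclusions reported
  in comparable cohorts; both the statistic's threshold and the summary it
  is compared against can be changed.
* **Nuisance regression.** The Friston-24 expansion of the motion
  parameters ($P, P^2, P_{t-1}, P_{t-1}^2$) plus any pre-extracted global,
  CSF and white-matter signals are removed by OLS per node. Residuals are
  orthogonal to the design by construction, which the tests assert.
* **Band-pass.** A 4th-order Butterworth applied forward-backward
  (zero phase) retains 0.01–0.10 Hz. No filter family was mandated by the
  design; this is the standard resting-state choice and avoids phase
  distortion that would shift windowed correlations.
* **Order.** The default order is regress-then-filter, so that filtered
  series are not re-contaminated by unfiltered nuisance variance; the
  reverse order is available as an option and recorded in the run report.

## Graph construction and efficiency

How a windowed correlation matrix becomes a graph is genuinely open
(weighted vs. binarized, thresholded or not), so it is explicit
configuration. The default is **weighted** graphs with **negative
correlations discarded** and **no sparsity threshold**, edge length
$1/r$. Rationale: densely binarized graphs are complete in almost every
window, which makes every nodal efficiency identically 1 and the dnE
correlation undefined; weighted graphs keep the metric informative
without committing to an arbitrary sparsity. An optional sparsity
threshold keeps the strongest $\lceil s\,N(N-1)/2 \rceil$ edges by
absolute weight, with ties broken by lexicographic node-pair order for
reproducibility.

Shortest paths are computed by a compiled Floyd–Warshall kernel (the
dense, small-N regime of brain graphs suits the $O(N^3)$ algorithm; at
246 nodes a window costs ~13 ms). The test suite checks the kernel
against igraph's Dijkstra distances — an independent algorithm and code
base — on 200 random weighted and binary graphs to $10^{-10}$.

Zero-variance efficiency curves (possible in degenerate graphs) are
flagged per node and their dnE entries set to 0 rather than NaN: the
feature matrix stays finite and the degeneracy is auditable in the run
report.

### Window arithmetic

The window count is always computed from the series actually windowed:
$\lfloor (T - L)/s \rfloor + 1$. A 240-point scan at $L = 50, s = 1$
gives 191 windows; after the default 4-volume discard a 236-point series
gives 187. Published window counts that assume the full scan length are
reproduced by windowing the undiscarded series; the pipeline reports
whatever the conditioned length implies.

## The penalized regression

The objective above carries a $\tfrac{1}{2}\lambda$ penalty factor and no
sample-size scaling; the implementation treats it as canonical so that
$\lambda = 0.08$ is meaningful and portable. Features are standardized
(zero mean, unit sample variance) and the response centered *within each
training fold* — a single penalty can only act comparably across features
on a common scale, and re-estimating the standardization per fold keeps
the held-out subject out of its own fold's model (a corruption test
asserts this).

The solver follows the piecewise-linear LARS-lasso homotopy of the
objective from the null model down to the target penalty. This matters
numerically: at $\lambda = 0.08$ with thousands of features and tens of
subjects the fit is near the interpolation regime, where coordinate
descent (and generic solvers at default tolerances) converge slowly and
inexactly; the homotopy reaches the solution in roughly as many steps as
there are active features. An exact least-squares polish on the selected
active set then sharpens the stationarity conditions

$$|2 x_k^\top (y - x\beta)| \le \tfrac{\lambda}{2} \;\; (\beta_k = 0),
\qquad 2 x_k^\top (y - x\beta) = \tfrac{\lambda}{2}\,\mathrm{sign}
(\beta_k) \;\; (\beta_k \ne 0)$$

to near machine precision; the tests verify them to $10^{-6}$ on random
instances, together with the derived all-zero threshold
$\lambda_{\max} = 4\max_k |x_k^\top y|$, the $\lambda \to 0$ least-squares
limit, agreement with glmnet (under the mapping
$\lambda_{\text{glmnet}} = \lambda/(4n)$), and a brute-force perturbation
oracle. Coordinate descent remains as a fallback for numerically
degenerate paths.

$\lambda$ is fixed at 0.08 by default with no inner tuning loop; LOOCV
fold order follows subject order; the per-fold coefficient table is kept
in the standardized frame, where weights are comparable across features.

### Inference

The Pearson correlation between LOOCV predictions and observed scores is
tested two-tailed via the t transform and Bonferroni-corrected across the
number of prediction targets (two medication states in the reference
design). The permutation test reruns the *complete* LOOCV — including
per-fold standardization and fitting — on uniformly permuted scores, and
uses the one-sided add-one estimator
$p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\})/(1 + n_{\text{perm}})$,
which is never exactly 0 and matches the directional claim that real
labels predict better than permuted ones. Within the permutation loop the
per-fold standardized design matrices are cached (the design does not
change across permutations) and the active-set polish is skipped — it
moves coefficients at the $10^{-5}$ level, far below permutation
resolution — so null replicates cost bare solver calls.

## Weight aggregation

Fold-averaged weights count a feature as 0 in folds where it was not
selected, so the average carries selection frequency as well as
magnitude. The macro-region matrix is the **signed** mean of these
weights over all node pairs connecting two regions: positively and
negatively predictive connection classes stay distinguishable by sign
(an absolute-value mean would fold them together; the sign convention is
declared, not inferred). Node efficacy sums *absolute* incident weights
and min–max normalizes to $[0, 1]$; note that with min–max scaling the
weakest involved node maps to 0 unless some node carries no weight at
all.

The packaged lookup groups the 246 nodes into 24 macro regions (20
gyral/cortical groups covering 210 nodes, plus amygdala, hippocampus,
basal ganglia and thalamus covering 36), odd indices left hemisphere.
Any lookup with the same four-column schema may be substituted.

## The synthetic cohort generator

Because the motivating study's patient data are not deposited, every
stage is verified against synthetic cohorts with planted, recoverable
ground truth. The generator has two modes so that prediction-stage tests
do not depend on graph-stage design choices:

* **Direct dnE mode** plants the relation in Fisher-z space: entry
  $(p,q)$ is $\tanh(\mu + b\,\tilde s_i + \varepsilon)$ for planted pairs
  ($\mu + \varepsilon$ otherwise), $\varepsilon \sim N(0, \sigma^2)$,
  with $\tilde s_i$ the subject's standardized score. Entries respect
  $(-1, 1)$ by construction — no clipping that would distort the planted
  linearity — and the slope is recoverable by regressing
  $\mathrm{atanh}$-transformed entries on $\tilde s$; the closed-form
  attenuation $\mathrm{corr} = b/\sqrt{b^2 + \sigma^2}$ is a frozen test
  value.
* **Time-series mode** builds node-by-time matrices: every node mixes a
  shared band-limited (0.01–0.10 Hz) community signal with unique
  Gaussian noise; for a planted pair, the two nodes' couplings to the
  community signal are slowly modulated by latent low-pass processes
  whose mutual correlation $\alpha_i = (\tanh(b\,\tilde s_i)+1)/2$
  increases with the score. The efficiency curves of the pair then
  co-fluctuate in proportion to $\alpha_i$, so the dnE entry tracks the
  score through the full graph stage.

Scores are drawn uniformly over a bounded range and standardized for the
plant, keeping the effect size scale-free on a clinically bounded scale.
The defaults mirror the targeted study conditions: 62 subjects, 246
nodes, 240 time points at TR = 2 s, and a score range of (20, 70), whose
uniform draw has mean 45 and SD 14.4 — comparable to medication-off
UPDRS-III in a moderate-to-severe Parkinson's cohort (44.1 ± 12.0). The
mechanism constants of the time-series mode (community coupling 0.6 with
modulation amplitude 0.5; node-unique noise SD of 2.5 × `noise_sd`
against the unit-variance community signal; modulator cutoff 0.01 Hz)
were chosen once so that a large planted effect is recoverable but not
trivial — per-pair feature–score correlations around 0.5–0.7, well below
the deterministic plant of the direct mode.

All cohort randomness derives from one seed, expanded into per-subject
substreams as `seed + 99991 * i (mod 2^31 - 1)`, so any subject is
reproducible without generating its predecessors.

**What the generator does not emulate:** hemodynamic response shape,
scanner drift and physiological noise spectra, spatial (voxel-level)
structure, motion artifacts coupled to the signal, or heavy-tailed
score distributions. Passing recovery tests therefore demonstrates that
the pipeline's stages compose correctly and recover a planted
dynamic-connectivity signal at realistic dimensions — not that real
acquisitions carry such a signal.

## Problem sizes used in the checks

The shipped checks run, among others: a full-parcellation structural run
(62 subjects × 246 nodes × 240 time points, 5 permutations); a recovery
run at 60 subjects × 40 nodes × 236 time points with 3 planted pairs and
200 permutations; a null-calibration study of 50 effect-size-zero
cohorts (20 subjects × 10 nodes, 49 permutations each) whose permutation
p-values are tested for uniformity; and 200 random-graph comparisons of
the efficiency kernel against igraph. These sizes are chosen so the full
suite completes on a single CPU in well under half an hour while still
exercising every stage at the target dimensionality.

## Known limitations

* The pipeline starts at extracted ROI time series; no image-space
  processing, slice-timing correction, or frame censoring.
* Tapered windows, other dynamic graph metrics (local efficiency,
  modularity), and state clustering are not implemented.
* No inner $\lambda$ selection by default; the fixed-penalty design
  mirrors the motivating analysis, and a grid search would change the
  inferential properties of the permutation test.
* Figure rendering (circle/matrix plots) is out of scope; the underlying
  tables are produced.
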