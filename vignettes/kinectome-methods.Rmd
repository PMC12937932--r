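---
title: "Similarity gait networks: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity gait networks: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

`kinectome` treats whole-body gait as a network. Each of 23 tracked body
segments contributes a 3D position trace; after zero-phase low-pass
filtering, the Euclidean magnitude of each trace is reduced to an amplitude
distribution, and every pair of segments is compared through the
Jensen–Shannon divergence of their kernel density estimates. The
similarity matrix $A_{ij} = 1 - \mathrm{JS}(p_i, p_j)$ is a
subject-specific "kinectome" whose topology — summarized by graph metrics
averaged over a sweep of edge-retention thresholds — feeds, together with
per-segment dispersion features, a voting-feature-selection plus
gradient-boosted-tree classifier evaluated under nested cross-validation.
Shapley attributions aggregated across outer folds, filtered by cumulative
importance and cross-fold selection stability, name the features that
carry the decision.

# Signal model and preprocessing

Input recordings are tidy CSVs (`subject, time, segment, x, y, z`) at a
nominal 100 Hz. Preprocessing is deliberately minimal:

* **Filtering.** A 4th-order Butterworth low-pass at 10 Hz, applied
  forward and backward so the phase response is identically zero and the
  magnitude response is the squared Butterworth response. Human gait
  fundamentals sit near 1 Hz with meaningful harmonics well below 10 Hz,
  so the passband is generous. Edges are handled by odd (point-reflected)
  extension of length $3 \times \text{order}$ plus steady-state
  initialization of the filter state; this is the standard two-pass
  construction and leaves a short edge transient when a signal ends
  mid-swing, which is why summary statistics (IQRs, densities) are robust
  quantities rather than pointwise ones.
* **Magnitude.** $m_i(t) = \sqrt{x_i^2 + y_i^2 + z_i^2}$ collapses each
  segment to a scalar displacement, removing frame orientation effects.
* **Speed.** Per-axis central differences then the Euclidean norm.
  Differentiating before taking the norm keeps the quantity rotation- and
  translation-invariant; the alternative (differentiating the magnitude)
  is available via `speed_of_magnitude = TRUE` but is not the default
  because it conflates radial and tangential motion.
* **Dispersion.** The interquartile range, with quartiles by the
  linear-interpolation convention (type 7), one value per segment for
  position and speed. Mean and SD are computed alongside for univariate
  statistics but excluded from the classifier's feature table, which uses
  the robust descriptor only.

# Networks from amplitude distributions

For each unordered segment pair, both magnitude signals are turned into
Gaussian-kernel densities with Silverman bandwidths on a **shared** grid of
512 points spanning the pooled range extended by three bandwidths. The
Jensen–Shannon divergence uses base-2 logarithms so it is bounded in
$[0, 1]$, making $A = 1 - \mathrm{JS}$ a similarity in $[0, 1]$ without
rescaling; Kullback–Leibler terms are integrated by the trapezoid rule
with $0 \log 0 = 0$ and a $10^{-12}$ floor inside logarithms. Degenerate
(zero-variance) segments yield flagged missing rows rather than errors, so
a single dead channel does not abort a subject.

Edge-retention thresholds sweep 0.20–0.60 in steps of 0.05 (nine values)
and every graph metric is averaged over the thresholds at which it is
defined. Three choices deserve comment:

* **Weighted default.** Surviving edges keep their similarity weights
  (`network.mode = "weighted"`); strict binarization is available.
  Weight-dependent metrics (strength, eigenvector centrality, PageRank)
  are uninformative on dense binary graphs, and the threshold sweep
  already supplies the topology-varying component.
* **Distances.** Path-based metrics (betweenness, closeness) read the
  edge weight itself as a length, with `one_minus` and `inverse`
  transforms selectable. Reading similarity as distance is unusual but is
  retained as the default literal interpretation; the choice is recorded
  in every run's configuration, and the alternatives are one flag away.
* **Averaging over defined thresholds only.** Characteristic path length
  on an edgeless graph, assortativity on a regular graph, and similar
  undefined values are excluded from the average rather than coerced to 0,
  so a metric's average is never biased by degenerate thresholds.

Local metrics per node: degree, strength, weighted clustering
(geometric-mean triangle weights), normalized betweenness and closeness
(reachability-scaled, isolated nodes 0), eigenvector centrality (power
iteration, tolerance $10^{-6}$, at most 1000 iterations, flagged missing on
non-convergence), PageRank (damping 0.85). Global metrics: density,
average clustering, global efficiency, characteristic path length (largest
component when disconnected), greedy-community modularity, degree
assortativity, transitivity, average strength, component count.

# Feature table, confounds, cleaning

With 23 segments the table has $46 + 253 + 161 + 9 = 469$ named columns:
kinematic IQRs, the raw (unthresholded) upper triangle of $A$, the
threshold-averaged local metrics, and the global metrics. Age and sex are
regressed out of every feature by ordinary least squares once on the full
sample before modelling — the confound structure is demographic, not
fold-specific — while a fold-wise variant can be selected when strict
according-to-split residualization is preferred.

Cleaning follows fixed rules: drop columns more than 80% missing, impute
the rest with the median, drop zero-variance columns, z-score. All
statistics are *fit* on a designated row subset and *applied* everywhere;
inside cross-validation that subset is always the training side, so
held-out rows cannot leak into medians, means, or SDs (this is asserted by
a mutation test that perturbs a held-out row and checks the fitted
statistics bit-for-bit).

# Voting feature selection

Four heterogeneous rankers each vote for their top-$k$ features: one-way
ANOVA F; absolute coefficients of an L1-penalized logistic regression at
inverse regularization `vfs_lr_c` (glmnet parameterization
$\lambda = 1 / (C\,n)$); gain importance of a fixed gradient-boosted
ensemble (300 trees, depth 3, learning rate 0.1 — the ranker's own
settings are fixed, only the final classifier's are searched); and
MultiSURF relevance. Features are ordered by votes, then by the sum of
min–max-normalized scores across methods (the "tie-sum"), then by name, so
the selection is a deterministic function of the data. Both `vfs_k`
$\in [25, 100]$ and `vfs_lr_c` $\in [10^{-3}, 10^3]$ (log-uniform) are
tuned in the inner loop.

The MultiSURF variant is documented precisely because Relief-family
algorithms differ in small conventions: distances are Manhattan on
range-normalized features; neighbours of instance $i$ are those closer
than $\mu_i - \sigma_i/2$; hits subtract and misses add range-normalized
feature differences, misses weighted by the miss-class prior over one
minus the target-class prior; hit and miss contributions are averaged over
their own neighbour counts before summing. The last point is the classic
Relief normalization — without it, the one-instance imbalance between
same-class and other-class candidates (the target excludes itself from its
class) gives pure-noise features a small positive bias, which the
package's null-simulation test would catch. A brute-force double-loop
oracle of the same definition backs the vectorized implementation in the
test suite.

# Nested cross-validation

The evaluation design is 10-fold stratified outer cross-validation
repeated 3 times; within each outer training split a randomized search (20
draws by default) scores configurations by 4-fold inner stratified
cross-validation with multi-metric scoring (AUC, accuracy, sensitivity,
specificity), the best inner-AUC configuration is refit on the full outer
training split, and evaluated once on the untouched outer test split.
Choices the design leaves open were fixed as follows and are logged with
every run:

* classifier search space: trees 100–500, depth 2–6, learning rate
  log-uniform 0.01–0.3, row/column subsampling 0.6–1.0, L1/L2 penalties
  log-uniform $10^{-3}$–10;
* sensitivity/specificity operating point: predicted probability 0.5;
* AUC as the Mann–Whitney rank statistic with 0.5 credit for ties;
* per-fold seeds derived deterministically from (global seed, repeat,
  fold), so folds are independent yet the whole run replays exactly;
* fold summary reported as mean ± SD over the outer folds.

# Shapley aggregation and stability

Per outer fold, TreeSHAP attributions of the refit pipeline are computed
on the held-out subjects over the fold's selected features; unselected
features contribute exactly 0, which keeps the cross-fold mean
well-defined on the full feature space. The global importance
$\bar{s}_j$ is the cross-fold mean of mean absolute attributions, sorted
descending with a name tie-break; $C(k)$ is its normalized cumulative
curve and the top-95% set the smallest prefix with $C(k) \ge 0.95$.
Stability $\mathrm{stab}_j = 100 f_j / N$ counts membership in the folds'
*selected* lists (not per-fold SHAP rankings — stability is about the
selector, importance about the model), and the stable set intersects
$\{\mathrm{stab}_j \ge 95\}$ with the top-95% set. Direction of effect is
the sign of the case-conditional mean signed attribution: positive means
the values the feature takes in affected subjects push predictions toward
the affected class.

# Statistics

Group comparisons use Welch's t per feature with Benjamini–Hochberg
adjustment; demographics use Fisher's exact test (sex) and Kruskal–Wallis
(age). Spearman screening between stable features and clinical scores
flags $|\rho| \ge 0.30$ with $p < 0.05$. Sensitivity power uses Cohen's
$w = \sqrt{\chi^2 / N}$ with noncentral-$\chi^2$ power at $Nw^2$ (df 1),
and pooled-SD Cohen's $d$ with noncentral-$t$ power at
$d\sqrt{n_1 n_2/(n_1+n_2)}$. Recomputing $d$ from the reference cohort
moments (69.6 ± 8.67 vs 51.3 ± 17.03 years at 51/53) gives 1.3465 with
$(n-1)$-weighted pooling, slightly below the reported ≈1.36, and the
standard $w$ from the reference counts is ≈0.37 rather than 0.45; the
power bounds hold under either value, and the package asserts them at the
reported effect sizes.

# The synthetic cohort generator

The study's recordings are not deposited, so the generator is a
first-class module that emulates the *statistical signatures* the pipeline
is meant to detect, not gait biomechanics. Each segment's position is

> anatomical offset + gait oscillator (subject fundamental ~N(1.0, 0.08)
> Hz, two harmonics at relative amplitudes 0.4 and 0.15, left/right limbs
> anti-phase, arms anti-phase with ipsilateral legs) + shared latent
> oscillators + white noise (SD 1 cm) [+ random-walk drift].

Vertical offsets are compressed (trunk 1.00–1.58 m, limbs down to 0.10 m)
and oscillation amplitudes (trunk 0.11 m, arms 0.18 m, legs 0.22 m, distal
0.30 m) chosen comparable to inter-segment spacing, so neighbouring
amplitude distributions overlap partially and the similarity matrix spans
the full $[0, 1]$ range — the regime where the 0.20–0.60 threshold sweep
is informative.

Disease-like effects apply to group A ("case"), scaled per subject by a
latent severity that also generates the clinical scores (affine in
severity, noise proportional to each score's nominal SD, clipped to
plausible ranges):

* `distal_speed_scale` multiplies foot/toe/hand amplitudes
  (bradykinesia-like; default 0.6 attenuation);
* `positional_drift_sd` adds a shared whole-body random walk (postural
  variability; default 0.008 m per sample — large enough that positional
  dispersion rises reliably at the default 15 s duration);
* `proximal_coupling_gain` strengthens a shared trunk/head oscillator on
  a 0.03 baseline (centralized coupling; default 0.5);
* `interlimb_decoupling` shrinks a shared arm–leg component from its 0.12
  baseline (default 0.5).

With all effects at their null values the groups are exchangeable in
distribution (ages and sexes still differ by design, but never enter the
signals), which underwrites the permutation and null-calibration tests.
Because the JS network sees only *marginal* amplitude distributions,
coupling effects are detectable through the amplitude they add, not
through phase alignment as such; this is the simplest mechanism the
similarity stage can provably recover, and is the main sense in which
passing tests on synthetic data do not certify performance on real
recordings (real inter-segment dependence is temporal as well as
distributional, turns and stops are absent, and sensor artefacts are
reduced to white noise).

# Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline at desk scale:
parameter recovery uses 25 + 25 subjects at the generator defaults with a
reduced search (5 outer folds, 10 configurations, 3 inner folds); null
calibration uses 20 + 20 subjects across 10 seeds (tests) or 5 seeds
(acceptance script) with 4 outer folds and 3 configurations. The
full-scale defaults (10 × 3 outer, 20 draws) remain the package defaults
for real analyses.

Numerical details fixed for reproducibility: KDE grids of 512 points;
$10^{-12}$ floors inside logarithms; eigenvector centrality by power
iteration from the uniform vector with unit-norm output; greedy
modularity via agglomerative merging; name-based tie-breaks wherever
scores can tie exactly; all randomness derived from a single integer seed
(cohort generation, fold assignment, search draws, tree fitting with one
thread).

# Known limitations

* The generator does not model turning, ground contact, joint limits, or
  realistic axis coupling; effect sizes are calibrated for detectability,
  not clinical realism.
* Similarity networks from marginal distributions cannot distinguish
  amplitude coupling from phase coupling; a time-resolved extension would.
* Residualization is linear; nonlinear age effects on gait are not
  removed.
* The stable-feature set on small cohorts is sensitive to the fold
  layout; with 5 outer folds the 95% stability cutoff means "selected in
  every fold", which is conservative but coarse.
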