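# kinectome

Subject-specific kinematic similarity networks for gait classification.

Parkinsonian motor impairment changes how the *whole body* moves:
distal limb speed drops (bradykinesia), postural sway rises, and
movement becomes more centralized around the trunk. Metrics computed on
single sensors miss the coordination structure, so this package models a
gait recording as a network over the 23 tracked body segments and asks a
classifier — with full explainability bookkeeping — which network and
dispersion features separate patients from controls. It is aimed at
movement-science and digital-biomarker researchers working with
multi-segment motion-capture or IMU-suit exports.

## The model

For each subject, every segment's filtered 3D position trace is reduced
to its Euclidean magnitude $m_i(t)$, and each pair of segments is
compared through the Jensen–Shannon divergence of the kernel density
estimates of their amplitude distributions:

$$
A_{ij} \;=\; 1 - \mathrm{JS}(p_i, p_j), \qquad
\mathrm{JS}(p,q) = \tfrac12 \mathrm{KL}(p \,\|\, M) +
                   \tfrac12 \mathrm{KL}(q \,\|\, M),\quad
M = \tfrac12 (p + q),
$$

with base-2 logarithms so $A_{ij} \in [0,1]$. Binary/weighted graphs are
derived by sweeping edge-retention thresholds 0.20–0.60 (step 0.05) and
every graph metric (degree, strength, clustering, betweenness,
closeness, eigenvector centrality, PageRank; density, efficiency,
characteristic path length, modularity, assortativity, transitivity,
components) is averaged over the sweep. The feature table — per-segment
position/speed interquartile ranges, the raw upper triangle of $A$, and
the threshold-averaged metrics (469 columns) — is residualized on age
and sex, then classified with a voting feature selection (ANOVA-F,
L1-logistic, gradient-boosted-tree gain, MultiSURF; votes + normalized
score tie-sums) feeding an XGBoost model, all inside nested stratified
cross-validation with randomized hyperparameter search refit on AUC.
Per-fold TreeSHAP attributions on held-out subjects are aggregated into
a global importance vector, its 95% cumulative-importance set, and a
cross-fold stability percentage $\mathrm{stab}_j = 100 f_j / N$; the
stable feature set is screened against clinical severity scores with
Spearman correlations. A synthetic cohort generator with controllable
Parkinsonian-like effects (distal amplitude scaling, postural drift,
trunk coupling, arm–leg decoupling, severity-linked clinical scores)
makes every stage testable without access data.

## Worked example

```r
library(kinectome)

spec <- cohort_spec(n_group_a = 12, n_group_b = 12, duration = 8, seed = 7)
cohort <- generate_cohort(spec)

kin  <- lapply(cohort$recordings, kinematic_features)
nets <- lapply(kin, function(k) build_network(k$magnitudes))
gms  <- lapply(nets, metrics_across_thresholds)
tab  <- assemble_features(kin, nets, gms)
tab  <- residualize(tab, cohort$metadata$age, cohort$metadata$sex)

cfg  <- cv_config(outer_folds = 4, outer_repeats = 1, inner_folds = 3,
                  search_iterations = 6, seed = 7)
res  <- nested_cv(tab, cohort$metadata$group, cfg)
print(res$summary, digits = 3)
#>        metric  mean    sd
#> 1         auc 0.819 0.123
#> 2    accuracy 0.708 0.250
#> 3 sensitivity 0.583 0.419
#> 4 specificity 0.833 0.333
```

The outer-fold AUC of 0.82 ± 0.12 says the classifier separates the
simulated patient-like group from controls well above chance on
24 subjects it never saw during tuning; accuracy, sensitivity and
specificity are read at the 0.5 probability operating point. The
explainability summary then names what carried the decision:

```r
summ <- shap_summary(res)
head(names(summ$importance), 5)
#> [1] "closeness_Left Foot"       "A_L5_Right Upper Arm"
#> [3] "A_Left Hand_Right Foot"    "A_Left Forearm_Right Foot"
#> [5] "eigenvector_Left Forearm"  
length(summ$top_set)      # features carrying 95% of SHAP mass -> 19
length(summ$stable_set)   # selected in >= 95% of folds as well -> 5
```

Adjacency and centrality features involving the trunk and limbs dominate
— the injected effect raises trunk-coupled similarity and lowers distal
speed, and `export_body_network(summ)` projects these importances onto a
stickman layout (nodes sized by importance, signed toward the affected
class). The demographic power computation used for cohort sensitivity
analyses is one call:

```r
sensitivity_power(d = 1.36, ns = c(51, 53))$power_d
#> [1] 0.9999995
```

An end-to-end run with artifacts (tidy CSVs, feature table, fold
metrics, SHAP summary, body-network JSON, statistics) is
`run_pipeline("all", config = default_config(), outdir = "out")`;
`inst/scripts/kinectome-run.R` wraps the same entry point for shell use
with a YAML configuration.

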