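---
title: "Longitudinal connectomics with longconn: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal connectomics with longconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
```

## The problem

Progressive brain disease alters the *organization* of brain networks
before it is obvious in any single connection. A longitudinal two-group
imaging study — for instance a transgenic rodent model of Alzheimer's
disease followed against wild-type littermates over five imaging
sessions from young adulthood to old age — asks three questions:

1. Do whole-network summaries of the structural and functional
   connectome differ between groups, and do their *trajectories with
   age* differ (a group-by-age interaction)?
2. Are there specific subnetworks of connections that differ?
3. Does connectivity relate to cognitive performance, and differently
   so in each group?

`longconn` implements this analysis end to end, starting from
region-labeled tractography streamlines and regional resting-state
time series. Everything upstream (registration, segmentation,
tractography itself, voxel-level fMRI preprocessing) is out of scope.

## Connectome definitions

A connectome here is a symmetric, non-negative, zero-diagonal weighted
adjacency matrix over named regions with a weight-kind tag.

**Structural.** An edge joins regions i and j iff at least one
streamline has one endpoint in each. Three weightings share that
support: mean fractional anisotropy of the connecting streamlines
(`fa_w`, values in (0, 1]); fiber density (`fd_w`); and binary. The
fiber-density convention used is

$$fd(i,j) = \frac{\sum_{s} 1/\mathrm{length}_s}{vol_i + vol_j},$$

i.e. streamline count normalized by streamline length and by the two
region volumes. Only the *fact* of normalizing by region volumes and
streamline length is canonical; the constant (sum versus mean of the
volumes) differs between toolchains, so `build_structural()` exposes it
as `volume_normalization` with `"sum"` as the default. Streamlines with
both endpoints in one region are self-loops and ignored.

**Functional.** Only gray-matter regions carry resting-state signal,
so only they are functional nodes (54 of 76 regions at the default
parcellation). After preprocessing, the edge weight is the pairwise
partial correlation — obtained from the inverse sample covariance
$r_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$ — passed through Fisher's
variance-stabilizing z-transform. Negative partial correlations are
excluded (set to zero) because the graph measures used are not defined
for signed edges; the binary functional connectome marks `z > 0`.
Direct precision inversion is the default because the intended regime
has many more volumes (600) than regions (54); optional diagonal
shrinkage (`shrinkage` = λ) handles short series.

**Preprocessing.** Per region: linear detrend, z-score, zero-phase
band-pass to 0.01–0.1 Hz (4th-order Butterworth run forward and
backward), then least-squares residualization against the nuisance
regressors (six motion parameters plus white-matter and CSF means),
following that stated order. One consequence worth knowing: a recursive
band-pass filter is not a projection, so re-running the preprocessing
on its own output reproduces the signal's *shape* (per-region
correlation ≈ 0.98 in our property test) but not its exact values —
the z-scoring rescales, and the filter keeps attenuating the band
edges. An exactly idempotent pipeline would need a brick-wall spectral
projection, which we deliberately did not use because zero-phase
recursive filtering is the field convention.

## Graph measures

Five measures, in the conventions of the standard brain-connectivity
toolbox:

* **degree / strength** — count / weighted sum of a node's
  connections; network values are node averages.
* **clustering coefficient** — binary: triangle fraction
  $2t_i/(k_i(k_i-1))$; weighted: Onnela's geometric-mean-of-triangles
  formula with weights rescaled by the global maximum (hence invariant
  to uniform rescaling of weights). Nodes with fewer than two
  neighbors score 0.
* **global efficiency** — mean over ordered pairs of inverse
  shortest-path distance; weighted paths use edge lengths $1/w$
  (stronger = shorter); unreachable pairs contribute zero rather than
  being dropped.
* **local efficiency** — the global efficiency of the subgraph induced
  by each node's neighbors (same rule, on the weights, for weighted
  kinds), averaged over all nodes — including disconnected ones, which
  score 0.

All-pairs distances are computed by a vectorized Floyd–Warshall sweep;
at 76 nodes this is faster in R than per-source Dijkstra and returns
identical distances. The test suite checks all five measures against
naive scalar brute-force oracles (triple-loop shortest paths, direct
triangle enumeration) on hundreds of random graphs to 1e-10, and
weighted distances against igraph as an independent implementation.

## Network-based statistic

Edgewise two-sample pooled-variance t statistics are thresholded
(default `t > 3.1`); the surviving edges' connected components are
measured by extent (edge count); and the null distribution of the
*maximal* extent is built by permuting whole subjects across groups
(default 5000 permutations), preserving within-subject edge
dependence. P-values use the add-one estimator
$p = (1 + \#\{null \ge extent\})/(1 + n_{perm})$, so $p \ge
1/(1+n_{perm})$. Increased and decreased subnetworks are tested in
separate one-sided passes on the signed t (direction `"both"`), since
the two directions answer different scientific questions; intensity
(sum of suprathreshold t) is not offered as the component statistic —
extent is the toolbox default and the only statistic consistent with
the analysis this package reproduces. Edges with zero variance in both
groups are assigned t = 0 rather than NaN.

Calibration note: with a discrete max-extent statistic and the add-one
estimator, the test is slightly conservative — our 500-replicate null
calibration at the default 76-region scale observes a rejection rate a
little under the nominal 0.05, inside the binomial sampling band. At
much smaller networks (a dozen nodes) the discreteness is severe and
the realized level drops well below nominal; calibration checks should
therefore be run at the intended network scale.

## Cross-sectional tests

Per timepoint, kind and metric, groups are compared with the
Kruskal–Wallis rank test (tie-corrected, chi-square reference), with
the effect size $\eta^2 = (H - k + 1)/(N - k)$. This estimator can go
slightly negative for small H; that is expected. Multiple comparisons
are corrected by Benjamini–Hochberg FDR. The family is configurable
(`per_timepoint` default, `per_kind`, `global`) because family
composition is an analysis choice, not a property of the data; all
kind-by-metric tests within one timepoint form the default family.

## The mixed-effects cascade

Each network metric y is regressed on group (control = 0, tg = 1), age
in months (uncentered) and their interaction, with a subject random
intercept:

$$y_s = \beta_0 + \beta_1\,group + \beta_2\,age + \beta_3\,group \times age + \beta_{4,s} + \xi.$$

Estimation is REML (`lme4`); inference is Wald t-tests with
Satterthwaite degrees of freedom (`lmerTest`) — the estimator and
degrees-of-freedom method are implementation choices, made because they
are the de-facto standard for small-sample longitudinal designs.
P-values are FDR-adjusted per *term family*: all kind-by-metric
responses for a given term (group, age, interaction) form one family.
Wherever the interaction survives FDR, each group is refitted with an
age-only model (same random-intercept structure) to report
group-specific age effects. The connectivity–cognition model has the
same form with a network metric in place of age and a cognitive outcome
(trials completed, percent correct — modeled as continuous responses,
matching the linear form above, despite their count/percentage nature)
in place of the metric; its gated per-group refits report the
group-specific metric effect.

Effect sizes: marginal $R^2$ is the fixed-effects variance fraction
$var(X\hat\beta) / (var(X\hat\beta) + \hat\tau^2 + \hat\sigma^2)$, and
$f^2 = (R^2_{full} - R^2_{reduced})/(1 - R^2_{full})$ with the reduced
model dropping a single term's column. Unbalanced panels (dropout) are
handled by the likelihood; no imputation. Degenerate inputs are
errors: a rank-deficient design, or a panel in which fewer than two
subjects have repeated observations (the random intercept is then
unidentifiable). If the mixed fit fails the fitter falls back to
ordinary least squares and flags the result; with the random-intercept
variance at zero the fixed-effect estimates coincide with the
closed-form OLS solution, a property the tests assert.

## The synthetic cohort generator

The generator produces data with the statistical structure the
analysis assumes, at the design scale of a two-group, five-timepoint
rodent study (9 subjects per group, nominal ages 6–18 months, uniform
age jitter of ±0.3 months, missing-at-random dropout after the first
session).

**Streamlines.** Per region pair, a streamline count is drawn from a
negative binomial around a gravity-style mean (product of region
volumes with exponential distance decay between centroids), which
produces realistic heterogeneity of density and strength. The count
scale is calibrated numerically — by solving for the scale at which
the expected fraction of pairs with at least one streamline equals the
target — so the expected binary density is 62%, the regime of
whole-brain structural connectomes at this parcellation; the total
streamline count is then an emergent quantity, deliberately far below
the ~6×10⁵ of a real tractogram so that full cohorts simulate in
seconds. Per-streamline mean FA carries additive group, age,
interaction and subject effects (FA units, uncentered age); count
means carry log-scale effects with age centered at 12 months so the
multipliers stay moderate. A planted component (a listed set of region
pairs) receives extra FA and/or log-count shifts in the transgenic
group — the target the network-based statistic should recover. All
randomness flows from one seed through fixed substreams per subject
(random effects, constant across timepoints) and per
subject-timepoint (observation noise); identical inputs give
byte-identical tables.

**Time series.** Gray-matter series are sampled from a multivariate
normal with a specified precision structure: planted positive partial
correlations on chosen pairs over a weakly negative background partial
correlation. The background default (−0.06) was calibrated once, by
simulation at 600 volumes with the default preprocessing, so the
positive-edge functional density lands near 28% — the regime observed
for partial-correlation connectomes with the z > 0 rule; note that
with a zero background the expected density would be ~50% (the sign of
noise). The sampled signal is band-limited to 0.01–0.1 Hz before six
random-walk motion regressors and two autoregressive tissue-mean
series contaminate it additively.

**Behavior.** Working-memory outcomes follow the cognition model's
generative form: trials = b0 + b1·metric + b2·group +
b3·metric·group + subject + noise, truncated to [0, 90] (a session
ends at 90 trials) and rounded; percent correct analogously in
[0, 100].

The `"ad_like"` preset encodes a progressive-pathology pattern: an FA
deficit in the transgenic group with a mild positive age slope, and a
transgenic-only positive age slope on streamline counts over a lower
transgenic baseline — which propagates to fiber-density and binary
network measures as a group-by-age interaction, while functional
metrics stay null.

What the generator does *not* emulate: spatial autocorrelation of FA
along tracts, hemodynamic response shape, non-stationary motion,
informative dropout, and nonlinear age trajectories (real cohorts show
a change of trend at advanced age that a linear mixed model cannot
capture). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative assumptions, not
robustness to every property of real imaging data.

## Numerical choices and problem sizes

* Edge thresholds are strict inequalities everywhere (`z > 0`,
  `t > 3.1`, display filters like `FA > 0.3`).
* Within-subject random-effect draws use fixed substreams keyed on the
  subject id so dropout patterns do not shift other subjects' data.
* Within-subject correlation of network metrics across timepoints is a
  free parameter (`*_subject_sd`); nothing in the emulated design pins
  it, and defaults are chosen to be moderate.
* The test suite sizes its simulations to run on a single CPU in
  minutes as a deliberate design point: 200 random graphs for the
  metric oracles; 500 null replicates at 1000 permutations for NBS
  calibration (full 76-region scale) and 100 planted-recovery
  replicates; 300 replicates for mixed-model coefficient recovery and
  interval coverage at the 18-subject × 5-timepoint design; three
  seeded end-to-end cohort replicates for the qualitative
  pathology-pattern check.

## Limitations

Group comparison is two-sample only; no covariates beyond group and
age; no negative-edge network analysis; no modularity/rich-club/hub
statistics; NBS offers extent (not intensity) as the component
statistic; and the linear age model will misfit cohorts with strongly
nonlinear trajectories.
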