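# longconn

Longitudinal structural and functional brain connectome analysis in R.

`longconn` is aimed at researchers following brain networks of two
groups (e.g. a transgenic Alzheimer's-model cohort versus wild-type
littermates) across repeated imaging sessions. It starts where
voxel-level image processing ends — region-labeled tractography
streamlines and regional resting-state time series — and carries the
analysis through connectome construction, graph measures, localized
edge-level inference, and longitudinal mixed-effects modeling. A fully
seeded synthetic-cohort generator emulates the statistical structure of
such a study (group, age and group-by-age effects on connectivity, a
planted altered subnetwork, working-memory outcomes, dropout), so every
stage is testable without imaging data.

## What it computes

**Connectomes.** From a streamline table (endpoint regions, length,
mean fractional anisotropy), three structural connectomes over one
support set: FA-weighted (mean FA per connection), fiber-density
weighted (streamline count normalized by region volumes and streamline
length, `fd(i,j) = sum_s 1/len_s / (vol_i + vol_j)`), and binary. From
regional time series (detrended, z-scored, band-passed to 0.01–0.1 Hz,
nuisance-regressed), functional connectomes weighted by Fisher-z
partial correlations with negative edges excluded (`z > 0` rule), plus
their binary form.

**Graph measures.** Degree, strength, clustering coefficient (Onnela
geometric-mean variant for weighted graphs), and global and local
efficiency, with inverse-weight path lengths — the standard
brain-connectivity-toolbox conventions.

**Network-based statistic.** Edgewise pooled-variance t statistics,
thresholded (default `t > 3.1`); connected suprathreshold components
measured by extent; max-component null from whole-subject label
permutations (default 5000); add-one p-values per direction.

**Statistics.** Per-timepoint Kruskal–Wallis tests with eta-squared
and Benjamini–Hochberg FDR; and the longitudinal mixed-effects cascade

    y_s    = b0 + b1*group + b2*age + b3*group*age + u_s + e     (per metric)
    y_s^g  = b0 + b1*age + u_s + e                               (per group, gated on b3's FDR significance)
    DNMS_s = b0 + b1*conn + b2*group + b3*conn*group + u_s + e   (connectivity -> cognition)

with subject random intercepts `u_s`, REML estimation, Satterthwaite
Wald tests, term-family FDR, marginal R² and Cohen's f².

## Worked example

```r
library(longconn)

atlas  <- generate_atlas(76, 54, seed = 1)          # 76 regions, 54 gray matter
cohort <- generate_cohort(9, c(6, 9, 12, 15, 18),   # 2 x 9 subjects, 5 ages
                          dropout_prob = 0.1, seed = 1)

st <- generate_streamline_table(atlas, cohort[1, ],
                                effect_spec("ad_like"), seed = 1)
cs <- build_structural(st, atlas)
cs$fa_w
#> <connectome> kind=fa_w  76 nodes  density=64.1%  subject=ctrl01 tp=1

network_summary(cs$fa_w)
#>   subject_id timepoint_index kind            metric  value
#> 1     ctrl01               1 fa_w          strength 21.532
#> 2     ctrl01               1 fa_w global_efficiency  0.382
#> 3     ctrl01               1 fa_w  local_efficiency  0.392
#> 4     ctrl01               1 fa_w        clustering  0.474
```

Strength is the node-averaged sum of FA edge weights; the efficiencies
and clustering summarize integration and segregation of the weighted
graph. A density near 62% is the expected regime for whole-brain
structural connectomes at this parcellation.

```r
kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
#> $H            3.857
#> $p_value      0.0495
#> $eta_squared  0.714
```

`run_pipeline(run_config(profile = "fast", seed = 1), "out/")` executes
the whole cascade — generation, construction, metrics, per-timepoint
tests, NBS, longitudinal models — and writes every intermediate table,
a results bundle, and a manifest that reproduces the run exactly.

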