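# nestbarcode

Quantitative analysis of two-marker plant DNA metabarcoding for
mixed-origin woody samples — artificial bark mock communities and the
nests that *Polistes* paper wasps build from macerated plant fiber.

Wasp nests, like any composite plant material, can be profiled by
amplifying and sequencing short chloroplast barcodes (*rbcL* ~500 bp, the
*trnL* (UAA) intron P6 fragment 10–143 bp) from total nest DNA. Getting
from OTU hit tables to defensible statements about *which plants, in what
proportions* requires a chain of decisions — taxonomy assignment from tied
BLAST bit scores, contamination thresholds anchored on negative controls,
cross-marker consensus, and a calibration against mixtures of known
composition. `nestbarcode` implements that chain as tested, reusable R
functions, for metabarcoding practitioners who want the statistics
reproducible and auditable.

## What it implements

- **Taxonomy**: top-bit-score consensus assignment (`assign_taxon`) —
  species when the top ties name one species, genus when they span
  congeners, family when they span genera, discarded beyond; checklist
  demotion (`demote_by_checklist`); two-marker label consensus
  (`consensus_label`); read aggregation with an audit log of unassigned
  OTUs (`aggregate_counts`).
- **Filtering**: per-taxon negative-control thresholds
  (`apply_negative_control`), proportion conversion, threshold-and-
  renormalize at 0.01 per marker, and the two-marker median consensus
  `(A + B) / 2` with its 0.0025 threshold (`median_consensus`).
- **Mock-community evaluation**: false-positive/false-negative accounting
  (`classify_detections`) and the linear mixed-effects calibration
  `obs = b0 + b1 * true + u_taxon + e` fitted by REML
  (`fit_calibration`), with marker ranking by |slope − 1|
  (`compare_markers`).
- **Community statistics**: Shannon–Wiener in log base 2, Chao1 with the
  bias-corrected b = 0 form, exact-enumeration and normal-approximation
  Mann–Whitney tests, Spearman matrices, correspondence analysis (SVD of
  standardized residuals; inertia = chi-squared/N), Euclidean-distance
  dendrograms with Newick export, analytic sample-based rarefaction,
  bipartite wasp-plant summaries, and landscape regressions.
- **Simulation**: a seeded generator of the full study design — mock
  mixtures with per-(taxon, marker) log-normal amplification bias, an
  airborne contamination pool shared with the negative controls, and a
  two-species, two-locality 13-nest study with a built-in diversity–area
  relationship (`generate_mock_experiment`, `generate_nest_study`).
- **Orchestration**: `run_mock_eval()` and `run_nest_analysis()` drive the
  stages end to end and write TSV/Newick reports.

The package also ships its reference dataset: a seven-mixture bark mock
community of nine woody species with per-marker and median proportions as
printed (`load_table1_fixture()`).

## Worked example

```r
library(nestbarcode)

fx <- load_table1_fixture()          # seven known bark mixtures, nine taxa
filtered <- threshold_and_renormalize(fx$rbcl, 0.01)
classify_detections(filtered, fx$design)
#> <detection_report> marker=rbcL
#>  sample n_design n_detected n_false_negative n_false_positive
#>     PC1        2          2                0                0
#>     PC2        2          2                0                0
#>     PC3        3          3                0                0
#>     PC4        3          3                0                0
#>     PC5        5          4                1                0
#>     PC6        7          4                3                0
#>     PC7        9          2                7                0
```

Mixtures dominated by a few taxa (PC1–PC4) are recovered perfectly; the
trace-laden PC7 loses its sub-1% components to the threshold. Calibrating
observed read proportions against the known mass proportions:

```r
fit <- fit_calibration(fx$rbcl, fx$design)
fit
#> <calibration_fit> REML, n=31 pairs (9 taxa)
#>   observed = -0.002932 + 0.9968 * true
#>   sigma_u2=0.01283 sigma_e2=0.02781 | R2(adj OLS)=0.5464 R2(marginal)=0.5062

compare_markers(list(rbcL = fit,
                     trnL = fit_calibration(fx$trnl, fx$design),
                     median = fit_calibration(fx$median, fx$design)))
#>   marker     slope    intercept abs_slope_error r2_adjusted_ols r2_marginal rank
#> 1   rbcL 0.9967803 -0.002932251     0.003219695       0.5464337   0.5061980    1
#> 2 median 0.7953199  0.042811448     0.204680074       0.5208174   0.4527622    2
#> 3   trnL 0.6159876  0.084361329     0.384012412       0.3942985   0.3204968    3
```

A slope of 1 with intercept 0 would be perfect quantification; *rbcL*
tracks the true proportions essentially one-to-one here, while *trnL*'s
slope of 0.62 reflects stronger taxon-specific amplification bias, and the
median consensus sits between them — the same reliability ordering the
mixtures were designed to reveal. Comparing diversity between groups of
nests:

```r
mann_whitney(c(1.32, 1.60, 1.95), c(0.43, 0.55, 0.70, 0.81, 0.94))
#> Mann-Whitney U: W = 15 (n1=3, n2=5), p = 0.03571 [exact]
#>   normal-approximation p = 0.03689
```

Complete separation of 3 versus 5 diversity values gives W = 15; the exact
two-sided p is 2/56, with the commonly quoted normal approximation
alongside. A full simulated study runs with:

```r
sim <- generate_nest_study(sim_params(seed = 1))
res <- run_nest_analysis(sim$counts, sim$metadata, flora = sim$flora,
                         out_dir = "nest-report")
```

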