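---
title: "Methods: two-marker plant metabarcoding of composite woody samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-marker plant metabarcoding of composite woody samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestbarcode)
```

# The problem

Paper wasps (*Polistes*) build their nests from macerated plant fiber, so a
nest is a composite sample of whatever woody material the colony foraged.
DNA metabarcoding of two chloroplast loci — the ~500 bp *rbcL* fragment and
the short (10–143 bp) *trnL* (UAA) intron P6 fragment — can list the plant
taxa in such a sample and, with care, estimate their proportions.
`nestbarcode` implements the downstream, statistical half of that workflow.
It starts where the sequence-level pipeline ends: at BLAST-style hit tables
for clustered OTUs, or at per-taxon read-count tables. Read trimming,
merging, chimera removal and OTU clustering are deliberately out of scope.

Two kinds of studies are supported end to end:

* **mock communities** — mixtures assembled from known species in known mass
  proportions, used to measure detection (false positives/negatives) and
  quantification (the calibration of read proportions against true
  proportions), and
* **nest surveys** — genus-level composition tables for a set of nests with
  wasp species, locality and landscape covariates, analysed with standard
  community statistics.

# Taxonomy assignment

Each OTU is assigned by the *top-bit-score consensus* rule
(`assign_taxon()`): only hits tied for the maximum bit score are considered;
a single species gives a species-rank call, several species of one genus a
genus-rank call, several genera of one family a family-rank call, and ties
spanning families leave the OTU unassigned. Ties are judged after rounding
scores to one decimal — the precision BLAST itself reports — so
floating-point noise cannot promote a rank. Species-rank calls absent from a
regional checklist are demoted to genus (`demote_by_checklist()`); demotion
is applied per marker *before* the two markers are merged, an order the
protocol leaves open — demoting first keeps each marker's evidence
self-contained and cannot create a species call that neither marker
supports. The two markers' labels for the same taxon are merged by
`consensus_label()`: compatible labels (one lineage a prefix of the other)
keep the more specific name, incompatible labels within a family fall back
to the family, and cross-family conflicts yield no consensus.

# Filtering

The removal procedure has three stages, mirroring standard contamination
control for amplicon data:

1. **Negative control** (`apply_negative_control()`): the no-template
   control's read count for each taxon is a per-taxon removal threshold;
   sample cells at or below it are zeroed. The rule is a threshold, not a
   subtraction — a cell above the control's count keeps its full value.
2. **Per-marker proportion threshold** (`threshold_and_renormalize()`,
   default `theta_marker = 0.01`): cells below the threshold are flagged
   removed and zeroed, and retained cells are renormalized to sum to one per
   sample. The operation is idempotent at a fixed threshold and monotone in
   the threshold.
3. **Median consensus** (`median_consensus()`, default
   `theta_median = 0.0025`): for taxa detected by *both* markers (nonzero
   raw proportion in each, judged before the per-marker thresholds), the
   consensus value is the arithmetic mean of the two marker proportions.
   Consensus values below the median threshold are flagged removed.

Two conventions deserve a note. First, the consensus table is *not*
renormalized by default: the bundled reference table's printed medians are
exact means of the per-marker proportions, so renormalization is opt-in.
Second, a removed consensus cell keeps its computed value next to its flag
(the `value(0)` convention of printed tables) so removals stay auditable.
In transcribed tables a detected cell can print as `0.000(0)`; the
detection test therefore counts a flagged cell as detected even when its
rounded value is zero. For mock analyses, reads of taxa not in the design
are dropped before thresholding (`run_mock_eval(restrict_to_design =
TRUE)`), treating them as airborne-pollen contamination.

One cell of the bundled table is documented as irreproducible: sample PC7's
consensus value for *Rhus chinensis* (0.022) is printed with a removal flag
although it exceeds the 0.0025 threshold, while the same sample's
*Paulownia* (0.004, likewise below the per-marker thresholds in both
markers) is retained. No single rule reproduces both; the package follows
the threshold rule and reproduces the *value* of every printed cell to
within print rounding.

# Mock-community evaluation

`classify_detections()` partitions each sample's retained taxa against the
known design. A design species counts as detected when a retained label is
compatible at genus level or above: a family-rank call (Fabaceae for
*Robinia pseudoacacia*) or a congeneric species call (*Prunus mume* for
*Prunus salicina*) both count — this matches how such tables are scored in
practice, where the marker's limited resolution is not held against the
detection.

`fit_calibration()` fits the linear mixed-effects calibration

$$\mathrm{obs}_{ij} = \beta_0 + \beta_1\,\mathrm{true}_{ij} + u_j +
\varepsilon_{ij}, \qquad u_j \sim N(0, \sigma_u^2),$$

by REML (via lme4), with a random intercept per plant taxon $j$ pooled
across mixtures — taxon-specific amplification bias is exactly a
taxon-level shift, which is why the taxon, not the mixture, carries the
random effect. The observed side is renormalized over retained cells per
mixture; the true proportions are used as designed. Removed cells enter the
fit as zero observations by default (`removed = "zero"`); excluding them
(`removed = "exclude"`) is available and documented because both
conventions appear in published analyses of this design. Reported
quantities are the fixed intercept and slope, both variance components, the
adjusted R² of the OLS fit on the same pairs, and the marginal/conditional
R² of the mixed model — published "adjusted R²" values for such fits are
ambiguous about which is meant, so all are emitted and none is asserted as
canonical. A perfectly quantitative marker has slope 1 and intercept 0;
`compare_markers()` ranks markers by |slope − 1| (ties broken by OLS
adjusted R²).

## What the bundled reference table does and does not reproduce

The packaged seven-mixture bark table (`load_table1_fixture()`) supports
three reproductions exactly: the median-consensus values (to print
rounding), the false-negative accounting (three samples with false
negatives for *rbcL*, two for *trnL*, four false negatives in PC7 for
*trnL*), and the marker reliability ordering (*rbcL* best, then median,
then *trnL*).

The absolute calibration coefficients reported alongside the original
table, however, are not desk-reproducible from its printed values. Fitting
the model above on the reconstructed pairs gives slopes 0.997 (*rbcL*),
0.616 (*trnL*) and 0.795 (median); the originally reported slopes (0.67,
0.41, 0.53) are these values times an almost exactly uniform factor of 2/3
(0.672, 0.665, 0.666), with intercepts consistent with an affine map of the
observed values. A systematic sweep of reconstruction choices — dropping
versus zero-filling flagged cells, renormalization on or off, either
regression direction, random effects by taxon or mixture, random slopes,
plain OLS, and standard variance-stabilizing transforms — brings no
combination within 0.05 of all three reported slopes, while the *relative*
slopes are matched to about 1% by the straightforward reconstruction. The
package therefore reports what the stated model computes from the table and
documents the discrepancy rather than tuning toward the printed
coefficients; the corresponding acceptance test is expected to fail and is
left failing by design.

# Community statistics

All nest-survey statistics follow the printed formulas exactly:

* **Shannon–Wiener** uses log base 2, $H = -\sum_i \pi_i \log_2 \pi_i$.
  Many ecology packages default to natural logarithms; the factor
  $\ln 2 \approx 0.693$ matters when comparing to published values.
* **Chao1** is $S_\mathrm{obs} + a^2/(2b)$ with singletons $a$ and
  doubletons $b$; when $b = 0$ the bias-corrected form
  $S_\mathrm{obs} + a(a-1)/(2(b+1))$ is used because the classical form is
  undefined there.
* **Mann–Whitney** (`mann_whitney()`) uses the rank-sum-minus-offset
  statistic, so complete separation of $n_1 = 3$ over $n_2 = 5$ gives
  $W = 15$. The exact two-sided p-value enumerates all label assignments
  ($2/56 \approx 0.0357$ for that case); the tie-corrected,
  continuity-corrected normal approximation (0.037 for the same case) is
  always reported alongside, since small published datasets are routinely
  quoted with the approximate value.
* **Spearman matrices** compute $\rho$ from midranks (equivalently the
  classical $1 - 6\sum d^2 / (n(n^2-1))$ for tie-free data) with p-values
  delegated to `stats::cor.test()`.
* **Correspondence analysis** is the classical SVD of standardized
  residuals $D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$; its total inertia equals
  $\chi^2/N$, which the tests verify to 1e-10 against an independent
  chi-squared computation and against vegan's implementation.
* **Rarefaction** is the analytic sample-based form
  $E[S(k)] = \sum_t \left(1 - \binom{N-n_t}{k}/\binom{N}{k}\right)$,
  computed with log-binomials for stability and verified against brute
  resampling.
* **Dendrograms** use Euclidean distances between composition vectors with
  complete linkage by default — the linkage is not dictated by the method,
  so it is a documented, configurable choice — and export Newick via ape.
* **Landscape regressions** are ordinary least squares of per-nest richness
  or diversity on vegetation area within the 100 m foraging radius (or on
  the surrounding flora's genus-level diversity), reporting slope, R² and
  the two-sided slope test.

# The synthetic study generator

`generate_mock_experiment()` and `generate_nest_study()` emulate the study
design so that every stage is testable without any sequence download. The
defaults are fixed study conditions, not tuning knobs:

* seven mixtures of the nine woody species of the reference design, every
  species in at least three mixtures, Dirichlet(1) proportions (or the
  reference design itself on request);
* 1e5 reads per sample and marker — a typical post-QC MiSeq allocation for
  multiplexed amplicon runs;
* multiplicative log-normal amplification bias per (taxon, marker) with
  sigma 0.5, constant across samples — the simplest mechanism that produces
  the marker-dependent slope attenuation the calibration is meant to
  detect;
* a shared airborne-contamination pool of 10 background taxa contributing
  an expected 0.2% of reads (observed false-positive proportions in such
  experiments sit below 0.0025), sampled by both the real samples and the
  negative controls; negative-control depths default to 0 reads for *rbcL*
  and 3098 for *trnL*, the yields of the reference study's controls;
* hit tables built so the taxonomy module reproduces the intended labels,
  with genus-rank and family-rank top-score ties at configurable rates
  (0.4 and 0.1 by default, roughly the rank mix of the reference
  identifications);
* a 13-nest study (5 + 3 *P. rothneyi* at two localities, 5 *P. mandarinus*),
  where each nest's composition mixes its species' plant preference with a
  nest-specific draw from its locality's flora pool (8 genera at the
  semi-urban site, 20 at the forested site), and the number of genera
  available to a nest scales with its vegetation area — so the
  diversity–area relationship the regressions test for is built in and
  recoverable.

All randomness flows from the single mandatory seed; the generators restore
the caller's RNG state, and identical seeds give identical outputs.

What the simulator does *not* emulate: sequence errors, chimeras, index
hopping, PCR stochasticity beyond multinomial sampling, and DNA degradation
differences between markers. Passing tests on synthetic data therefore
demonstrate the correctness of the statistical pipeline under its own
model, not the fidelity of that model to wet-lab reality.

# Numerical choices and degenerate inputs

* Proportion comparisons against the bundled table use a 5e-4 tolerance
  (print rounding of three-decimal values); renormalized rows must sum to 1
  within 1e-9.
* The mixed model falls back to OLS (with a warning, and
  $\sigma_u^2 = 0$) when fewer than two taxa are available or lme4 fails;
  singular fits are accepted silently since an unbiased marker genuinely
  has $\sigma_u^2 \approx 0$.
* CA axes with singular values below 1e-10 are dropped; an exactly
  independent table yields zero inertia and no axes.
* Exact Mann–Whitney enumeration is used up to $n_1 + n_2 = 12$ without
  ties; ties always fall back to the corrected normal approximation (an
  enumeration over midranks is available on request).
* Empty samples (no retained taxa) are flagged, warned about, and excluded
  from downstream comparisons rather than silently renormalized.
* Problem sizes in the test suite are chosen to keep the full run around a
  minute on one core: 200 replicate mock experiments at depth 1e5 for the
  slope-recovery check, 1e4–2e4 resampling replicates for Monte-Carlo
  oracles, exhaustive enumeration only for $n_1, n_2 \le 5$.

# Known limitations

* Taxon matching across tables keys on the most specific name plus family;
  true homonyms across families would collide and are rejected rather than
  disambiguated.
* The calibration treats true proportions as fixed covariates; mass
  proportions measured with error would attenuate the slope beyond what
  the model accounts for.
* `spearman_matrix()` p-values are not corrected for multiple comparisons;
  apply `p.adjust` as appropriate to the survey design.
* The bipartite summary averages nest proportion vectors per species
  without weighting by read depth, matching the averaging convention of
  per-group composition summaries of this kind.
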