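---
title: "Methods: spatial immunophenotyping of primary melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immunophenotyping of primary melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tilspatial` quantifies the immune microenvironment of primary melanoma from
multiplex-immunohistochemistry (mIHC) cell tables and asks which immune
features predict recurrence-free survival (RFS). This vignette documents the
models and procedures the package implements, the choices made where the
underlying methodology was open, and what the synthetic-data generator does
and does not establish about behaviour on real tissue.

## The analysis model

The pipeline starts downstream of imaging: its inputs are per-cell tables
(coordinates in micrometres, per-marker fluorescence intensities, a tissue
compartment label), tissue-region polygons with the tumor/stroma margin, and
per-patient outcome records. Five analysis layers are applied in order.

### Marker positivity and phenotypes

A cell is positive for a marker when its intensity is at or above a
per-(sample, marker) threshold. The `>=` convention is fixed so a cell at
exactly the threshold is positive — thresholds in quantitative pathology are
reviewed per sample and placed in the empty valley between negative and
positive populations, so the boundary case is rare, but it must resolve
deterministically. `suggest_threshold()` proposes the antimode of a smoothed
log-intensity density between the two largest modes; suggestions are flagged
`review_required` because per-sample review is the accepted practice the
package emulates.

Lineage assignment is hierarchical, with melanoma (SOX10) taking precedence
over every immune marker: on tissue sections, segmentation bleed-through can
put immune signal into melanoma nuclei and the conflict must resolve one way.
Then CD3+CD8+ cells are CD8 T cells, CD3+CD8− non-CD8 T cells, CD20+ B
cells, CD56+CD3− NK cells (requiring CD3− excludes NKT-like cells, since
CD56 alone is ambiguous), CD1a+ or Langerin+ Langerhans cells, and the rest
`other`. Requiring CD3 as well as CD8 for a CD8 T cell is an assumption: a
CD8 stain alone can also mark some NK subsets. Melanoma cells additionally
carry Class I MHC status from HLA-ABC.

CD8+ T cells are partitioned into eight phenotype classes by CD39, CD103 and
PD-1 positivity: P1 (+,+,+), P2 (+,+,−), P3 (+,−,+), P4 (+,−,−), P5 (−,+,+),
P6 (−,+,−), P7 (−,−,+), P8 (−,−,−). The partition property — every CD8 cell
gets exactly one class and the class counts sum to the CD8 count — is
enforced by construction and asserted by tests. Compositions are expressed
per compartment as percentages of the CD8 compartment; the T-cell fraction
is T cells over all nucleated cells of a panel.

In flow cytometry, CD8 events are classified by residency: DN (CD69−CD103−,
circulating), SP (CD69+CD103−, intermediate), DP (CD69+CD103+,
tumor-resident). CD69−CD103+ events fit none of the three conventional
classes; pooling them into any class would distort its fraction, so they are
counted and excluded. Every gate fraction is reported against its parent
gate, and an empty parent yields a missing value, never a zero — a 0% and an
unobservable fraction are different findings.

### Registration

Serial sections stained with different panels are misaligned by a small
rotation, translation and a slight scale change from sectioning. The package
registers panels with a landmark-based least-squares fit; the default model
is a similarity transform (closed-form orthogonal Procrustes), which
preserves distances up to one scale factor and therefore protects the
20 µm proximity rule; a full affine fit (shear allowed) is available behind
`type = "affine"`, with the caveat that distances are then no longer
preserved and proximity statistics computed across panels inherit the shear.
Registration quality is summarised as the root-mean-square landmark residual
in micrometres.

### Spatial statistics

Densities are counts over compartment polygon areas, always reported per
mm² (coordinates are µm; areas divide by 10^6). Proximity uses Euclidean
nearest-neighbor distances from each melanoma cell to the nearest cell of a
phenotype, plus the fraction of cells with a neighbor within a radius
(default 20 µm, closed ball: exactly 20 µm counts). Because melanoma is
stained on both panels but immune phenotypes are split across them, each
phenotype is compared against the melanoma cells of its own panel, in the
registered frame. Both directions (% of melanoma near the phenotype and % of
the phenotype near melanoma) are reported, since either can be the quantity
of interest and they are not symmetric.

The margin analysis takes the tumor/stroma interface polyline, assigns every
tumor or stroma cell a signed distance (negative into the tumor), and counts
cells in eight half-open 50 µm bands spanning [−200, 200) µm. A cell exactly
on the margin has distance 0 and falls in the first stromal band [0, 50) —
the half-open convention needs a home for 0. Epidermis cells are excluded:
the analysis concerns the tumor/stromal interface. Band densities divide by
the true area of each band clipped to tumor+stroma tissue. Those areas are
computed by deterministic grid integration of the signed-distance field
(default pitch 2 µm): the signed distance is evaluated on a square grid
covering the margin neighbourhood and each node contributes its grid-cell
area to its band. On a circular margin of radius 1 mm this reproduces the
analytic annulus areas to better than 0.5%, and unlike a rectangle
approximation it remains correct on curved margins; the pitch is a pure
accuracy/time dial documented per call.

### Cohort statistics

Two-group comparisons use the two-sided Mann-Whitney U test, exact by full
enumeration when both groups have at most 8 observations (enumeration
permutes the observed values, so ties are handled without approximation) and
the tie-corrected normal approximation with continuity correction otherwise.
No multiple-testing adjustment is applied by default — raw p-values mirror
the source analyses this package supports — and `p.adjust` can always be
applied downstream.

Feature correlation uses Spearman's rho: immune densities are heavy-tailed
and rank correlation is robust to the long upper tails. Features are
clustered with average linkage on 1 − rho after sorting columns
alphabetically, which makes the result invariant to input column order.

Margin profiles are compared between outcome groups with a two-way ANOVA of
log1p density on band, group and their interaction — the log1p stabilises
the variance of near-zero band densities — with per-band non-parametric
tests (Mann-Whitney for two groups, Kruskal-Wallis otherwise). The split —
parametric overall test, non-parametric per band — is a fixed rule standing
in for the common "ANOVA or Kruskal-Wallis as required" practice, which
never states its rule.

### Survival modelling

Univariable screening fits Cox proportional-hazards models per feature
(partial likelihood via the `survival` package), reporting hazard ratios
with Wald intervals. Features showing monotone-likelihood separation are
refitted with a ridge penalty and flagged.

Model selection is exhaustive: all feature subsets up to `k_max = 6` are
enumerated (for 10 candidate features that is 847 subsets) and each is
scored by a random survival forest under event-stratified k-fold
cross-validation. The forest (via `ranger`) uses log-rank splitting; the
prognostic index (PI) of a patient is the ensemble mortality — the row sum
of the predicted cumulative hazard function. Because the mortality scale
depends on the training split, raw out-of-fold PIs are not comparable
across folds; for scoring, each fold's held-out PIs are rank-normalised to
(0, 1) before pooling, which removes between-fold scale noise from the
cross-validated AUC. Subsets are ranked by the cumulative/dynamic AUC of
that pooled score at the evaluation horizon — year 3 by default, or, with
`eval_year = NULL`, the mean AUC over years 1–5, which is noticeably more
stable when no single horizon is privileged. Forest hyperparameters are
fixed and recorded in the configuration — 200 trees, `ceiling(sqrt(p))`
split candidates and a minimum terminal node of 10 by default; the
node-size floor regularises against spurious splits on noise features,
which otherwise inflate the cross-validated AUC of noise-bearing subsets.
For the selected subset, the reported per-patient PI comes from one
full-cohort forest using out-of-bag predictions (a single honest scale for
cutoffs and risk groups), and importance is out-of-fold permutation
importance, reported as mean ± s.d. across folds.

The time-dependent AUC is the cumulative/dynamic form with inverse
probability of censoring weights (a Uno-type estimator): at horizon t, cases
are patients with an event by t, controls are patients event-free beyond t,
case weights are 1/G(T−) from the Kaplan-Meier estimate of the censoring
distribution, and ties in the PI count one half. Confidence intervals come
from a seeded patient-level bootstrap (percentile, 200 replicates by
default). PI cutoffs maximize Youden's J over all observed PI values
against the binary outcome at the horizon (patients censored before the
horizon are excluded from cutoff estimation since their status is
unknowable); ties resolve to the smallest cutoff, and patients at or above
the cutoff are high risk. Risk groups are then compared by Kaplan-Meier
estimates and the log-rank test.

The endpoint convention is RFS: time to recurrence or melanoma death, with
censoring at last follow-up; 5-year outcome groups are `poor` (event within
5 years), `good` (event-free beyond 5 years), `unknown` otherwise.

## The synthetic-data generator

All statistical behaviour is validated on synthetic data with known ground
truth, because the pipeline's target data — patient tissue — ships no truth
labels.

The tissue generator builds a tumor disc (default radius 1000 µm) with a
stromal collar (600 µm) and an epidermal rim (120 µm); the margin is the
tumor/stroma circle. Melanoma cells are uniform in the tumor; each immune
phenotype is an inhomogeneous Poisson process whose log-density is linear in
signed margin distance, clipped at ±200 µm — the simplest mechanism that
produces band-profile gradients of the kind the margin analysis measures.
Marker intensities are two-mode lognormal (negative meanlog 1, positive
meanlog 4, sdlog 0.3); with thresholds at the antimode (e^2.5), the Bayes
error of a single call is ~3×10⁻⁷, so phenotype recovery failures indicate
pipeline defects, not simulation noise. Default densities (CD8 150/mm² with
P2 at 10% of CD8, background 1200/mm², giving a T-cell fraction near 15%)
are in the range quantitative-pathology studies of primary melanoma report.
The two panels are serial sections: each panel gets its own melanoma and
background realisations, the immune panel's coordinates are perturbed by a
similarity transform (3° rotation, ~50 µm shift, 1% scale) and landmarks
carry 2 µm annotation noise — a plausible serial-section regime that
exercises registration end to end.

The cohort generator draws clinicopathologic features (Breslow thickness
lognormal around 3.2 mm, ulceration ~48%, nodal involvement ~40%, age ~64)
and survival times from a Weibull proportional-hazards model; default
log-hazard coefficients are −0.05 per percentage point of %P2-of-CD8 and
+0.35 per mm Breslow, with smaller ulceration/nodal/mitotic effects.
Censoring is exponential with its rate solved numerically against the
realised event times so the expected censored fraction equals the designed
rate. The flow generator draws residency/CD39/PD-1 classes at designed
fractions — DN/SP/DP at 29/50/20%, CD39 rising with residency, PD-1 at
93.5% within CD39+ DP cells — and emits intensities the gating tree then
recovers.

What passing these tests shows: the pipeline's estimators recover known
truth under the assumed data model (clean bimodal intensities, Poisson
point patterns, proportional hazards). What they do not show: robustness to
segmentation errors, intensity drift between samples, non-elliptical tumor
geometries with invaginations (signed distance remains well-defined but
bands can self-overlap in deep folds), informative censoring, or
non-proportional hazards. Real-tissue thresholds still need per-sample
review.

## Numerical choices and problem sizes

Randomness flows from one master seed through named substreams per stage
(`substream_seed`), so adding a stage never perturbs another stage's
stream, and every pipeline output is a pure function of (inputs, config,
seed). Geometry predicates: polygon areas are shoelace sums; point-in-
polygon is even-odd ray casting vectorised per edge (boundary points count
inside, verified explicitly for small point sets); point-to-polyline
distances are exact segment projections. Degenerate inputs fail loudly:
empty target sets in proximity give missing values (not zeros), zero-area
compartments give missing densities with warnings, parents with zero events
give missing gate fractions, and constant features are refused by the Cox
screen and dropped with a warning by the correlation clustering.

Test-suite simulations use deliberately modest problem sizes chosen to make
Monte-Carlo bounds tight enough to detect real defects while keeping the
suite fast: tissues of a few thousand cells, cohorts of 300–500 for
parameter recovery, 20 seeds for selection stability, 10⁵ events for gating
recovery, and cross-validation at 5 folds with 50–100 trees where the full
10×200 configuration would add nothing but runtime. The acceptance script
re-runs the same computations from scratch at those sizes.

## Known limitations

- Compartment polygons are simple rings with containment-by-precedence
  (tumor over stroma over epidermis); polygons with holes are not
  supported.
- The margin band geometry assumes the interface polyline is consistent
  with the tumor polygon boundary; a margin drawn far from the actual
  polygon boundary will produce bands whose signed distances and
  compartment labels disagree.
- The PI is a forest ensemble mortality and has no absolute scale; cutoffs
  are only meaningful relative to the cohort that produced them.
- Exhaustive selection with cross-validated scoring is a stability
  screen, not a guarantee: with weak incremental signals, noise subsets can
  win folds, which is why selection stability is itself reported across
  seeds in the tests.
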