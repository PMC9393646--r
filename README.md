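# tilspatial

Spatial immunophenotyping of tumor-infiltrating lymphocytes (TILs) in
primary melanoma tissue.

Quantitative pathology of multiplexed immunohistochemistry (mIHC) produces,
per tissue section, a table of segmented cells with coordinates and marker
intensities. `tilspatial` turns those tables — together with tissue-region
polygons and patient outcome records — into prognostic immune features:

- **Phenotyping.** Per-sample marker positivity thresholds (`intensity >=
  threshold`), hierarchical lineage calls (SOX10 melanoma; CD3/CD8 T cells;
  CD20 B; CD56 NK; CD1a/Langerin Langerhans cells; HLA-ABC Class I MHC
  status of melanoma), and the eight CD8+ T-cell phenotype classes P1–P8
  defined by every CD39 × CD103 × PD-1 combination (P2 =
  CD39+CD103+PD-1−). A flow-cytometry gating tree classifies CD8 residency
  (DN/SP/DP by CD69/CD103) with CD39 and PD-1 subset fractions.
- **Registration.** Serial sections stained with different panels are
  aligned by a landmark least-squares similarity transform (affine behind a
  flag) so both panels analyze in one frame.
- **Spatial statistics.** Compartment densities in cells/mm², melanoma
  nearest-neighbor proximity with a 20 µm radius rule (both directions),
  and tumor-margin infiltration profiles: eight half-open 50 µm bands
  spanning ±200 µm of the tumor/stroma interface, each with true clipped
  band areas.
- **Cohort statistics.** Exact/approximate Mann-Whitney comparisons,
  Spearman correlation clustering of immune features, two-way ANOVA margin
  profile tests, and clinicopathologic summary tables.
- **Survival modelling.** Univariable Cox screening; exhaustive feature
  subset enumeration (all C(p,1..6) subsets) scored by random survival
  forests under event-stratified cross-validation; cumulative/dynamic
  time-dependent AUC (IPCW) at years 1–5 with bootstrap CIs; Youden-optimal
  prognostic-index cutoffs; Kaplan-Meier/log-rank risk stratification.
- **Synthetic data.** Tissue, cohort and flow generators with known ground
  truth (designed phenotype shares, margin attraction gradients, Weibull
  proportional-hazards effects), so the whole pipeline is testable without
  patient data.

## Worked example

```r
library(tilspatial)

# a synthetic sample: two serial-section panels, regions, landmarks, truth
ts    <- generate_tissue(tissue_design(seed = 5), "S1")
calls <- phenotype_cells(ts$cells, ts$thresholds)

table(calls$lineage[calls$panel_id == "tcell"])
#> melanoma    other    T_CD8 T_nonCD8
#>     2000     9551     1274      776

t_cell_fraction(calls[calls$panel_id == "tcell", ])
#> [1] 15.07242

# register the immune panel onto the T-cell panel frame
tf <- estimate_transform(ts$landmarks[, c("x_moving", "y_moving")],
                         ts$landmarks[, c("x_fixed", "y_fixed")])
tf$rmse_um
#> [1] 2.682269
```

The lineage table says the T-cell panel of this simulated 3.1 mm² tumor
carries 1,274 CD8+ and 776 non-CD8 T cells among ~13.6k nucleated cells — a
T-cell fraction of 15.1%, matching the generator's designed 15%. The
registration residual (2.7 µm) reflects the 2 µm landmark annotation noise
the generator plants on top of a 3° rotation + 1% scale misalignment.

Margin band profile and survival selection:

```r
bp <- band_profile(calls[calls$panel_id == "tcell", ], ts$regions)
co  <- generate_cohort(cohort_design(n = 400, seed = 11))
sel <- select_model(co$patients, c("pct_p2_tumor", "breslow_mm"),
                    k_max = 2, folds = 5, seed = 3, num_trees = 100)
sel
#> exhaustive RSF selection: 3 subsets, 5-fold CV
#> best subset (AUC 0.626 at year(s) 3): breslow_mm + pct_p2_tumor
```

`run_pipeline(analysis_config(seed = 1), out_dir = "out")` executes every
stage in order (simulate → phenotype → register → spatial → margins →
stats → survival) and writes per-stage CSV/JSON outputs; the result is a
pure function of (inputs, config, seed). A thin command-line wrapper with
per-stage subcommands lives at `inst/cli/tilspatial.R`.

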