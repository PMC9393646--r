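# End-to-end orchestration: simulate (or ingest) -> phenotype -> register ->
# spatial -> margins -> stats -> survival, writing per-stage outputs.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_tilspatial(sprintf("stage '%s' failed: %s", stage,
                            conditionMessage(e)),
                    "tilspatial_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes per-stage CSV/JSON outputs to
#' `out_dir`. With `inputs = NULL` a synthetic study is generated from the
#' config seed: `n_samples` tissue samples and an `n_patients` cohort.
#' Alternatively `inputs` supplies `samples` (a list of lists with `cells`,
#' `regions`, `landmarks`, `thresholds`) and `patients`. All outputs are a
#' pure function of (inputs, config, seed).
#'
#' @param config an [analysis_config()]
#' @param inputs optional input bundle (see Details)
#' @param out_dir output directory (created if missing); NULL = don't write
#' @param n_samples,n_patients synthetic study size when `inputs` is NULL
#' @param tissue_template [tissue_design()] reused for every synthetic
#'   sample (each sample gets its own seed substream)
#' @return invisible list of all stage results
#' @export
run_pipeline <- function(config = analysis_config(), inputs = NULL,
                         out_dir = NULL, n_samples = 4, n_patients = 66,
                         tissue_template = tissue_design()) {
  assert_that(inherits(config, "analysis_config"),
              "config must be an analysis_config")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_csv <- function(df, name) {
    if (!is.null(out_dir)) {
      out <- df
      num <- vapply(out, is.numeric, logical(1))
      for (cl in names(out)[num]) {
        out[[cl]] <- trimws(formatC(out[[cl]], format = "g", digits = 15))
      }
      write.csv(out, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
    }
    df
  }
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = 12, force = TRUE)
    }
    x
  }

  sim <- run_stage("simulate", {
    if (is.null(inputs)) {
      samples <- lapply(seq_len(n_samples), function(i) {
        d <- tissue_template
        d$seed <- substream_seed(config$seed, paste0("s", i))
        generate_tissue(d, sample_id = sprintf("S%02d", i))
      })
      cohort <- generate_cohort(cohort_design(n = n_patients,
                                              seed = substream_seed(config$seed,
                                                                    "cohort")))
      list(samples = samples, patients = cohort$patients)
    } else {
      inputs
    }
  })
  samples <- sim$samples
  patients <- sim$patients

  calls <- run_stage("phenotype", {
    out <- lapply(samples, function(s) phenotype_cells(s$cells, s$thresholds))
    emit_csv(do.call(rbind, out), "phenotypes.csv")
    out
  })

  registered <- run_stage("register", {
    tfs <- list()
    out <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      cc <- calls[[i]]
      if (!is.null(s$landmarks)) {
        tf <- estimate_transform(s$landmarks[, c("x_moving", "y_moving")],
                                 s$landmarks[, c("x_fixed", "y_fixed")])
        mov <- cc$panel_id == "immune"
        cc[mov, c("x_um", "y_um")] <-
          apply_transform(cc[mov, ], tf)[, c("x_um", "y_um")]
        tfs[[s$cells$sample_id[1]]] <- list(matrix = tf$A, rmse_um = tf$rmse_um,
                                            n_landmarks = tf$n_landmarks,
                                            type = tf$type)
      }
      out[[i]] <- cc
    }
    emit_json(tfs, "transforms.json")
    out
  })

  spatial <- run_stage("spatial", {
    dens <- do.call(rbind, lapply(seq_along(samples), function(i) {
      rbind(compute_density(registered[[i]], samples[[i]]$regions, "lineage"),
            compute_density(registered[[i]][registered[[i]]$lineage == "T_CD8", ],
                            samples[[i]]$regions, "cd8_class"))
    }))
    prox <- do.call(rbind, lapply(seq_along(samples), function(i) {
      cc <- registered[[i]]
      data.frame(sample_id = cc$sample_id[1],
                 proximity_summary(cc, radius_um = config$radius_um))
    }))
    emit_csv(dens, "densities.csv")
    emit_csv(prox, "proximity.csv")
    list(densities = dens, proximity = prox)
  })

  bands <- run_stage("margins", {
    b <- do.call(rbind, lapply(seq_along(samples), function(i) {
      band_profile(registered[[i]], samples[[i]]$regions,
                   band_width_um = config$band_width_um,
                   extent_um = config$margin_extent_um, grid_um = 4)
    }))
    emit_csv(b, "band_profiles.csv")
    b
  })

  stats_out <- run_stage("stats", {
    summ <- cohort_summary(patients)
    grouped <- patients[patients$outcome_group %in% c("good", "poor"), ]
    cmp <- NULL
    if (all(table(grouped$outcome_group) >= 3)) {
      cmp <- do.call(rbind, lapply(
        intersect(c("pct_p2_tumor", "breslow_mm", "mitotic_rate", "age_years"),
                  names(patients)),
        function(f) {
          data.frame(feature = f,
                     compare_groups(grouped[[f]][grouped$outcome_group == "good"],
                                    grouped[[f]][grouped$outcome_group == "poor"]))
        }))
      emit_csv(cmp, "comparisons.csv")
    }
    emit_csv(summ, "cohort_summary.csv")
    list(summary = summ, comparisons = cmp)
  })

  surv <- run_stage("survival", {
    feats <- intersect(c("pct_p2_tumor", "breslow_mm", "ulceration",
                         "nodal_status", "mitotic_rate"), names(patients))
    cox <- do.call(rbind, lapply(feats, function(f) {
      cox_univariable(patients, f)
    }))
    sel <- select_model(patients, feats, k_max = min(config$k_max, 2),
                        folds = min(config$cv_folds, 5),
                        seed = substream_seed(config$seed, "survival"),
                        eval_year = config$eval_year,
                        num_trees = config$num_trees)
    km <- km_logrank(patients$rfs_years, patients$event,
                     sel$best$risk_group)
    emit_csv(cox, "cox_univariable.csv")
    emit_csv(data.frame(patient_id = patients$patient_id,
                        pi = sel$best$pi, risk_group = sel$best$risk_group),
             "prognostic_index.csv")
    emit_csv(km$curves, "km_curves.csv")
    emit_json(list(best_subset = sel$best$features,
                   auc_eval_year = sel$best$auc,
                   auc_by_year = sel$best$auc_by_year,
                   importance = sel$best$importance,
                   cutoff = sel$best$cutoff,
                   logrank_p = km$p_value), "survival_model.json")
    list(cox = cox, selection = sel, km = km)
  })

  invisible(list(samples = samples, patients = patients, calls = calls,
                 registered = registered, spatial = spatial, bands = bands,
                 stats = stats_out, survival = surv))
}
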