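# Analysis configuration shared by all pipeline stages.

#' Build an analysis configuration
#'
#' Defaults follow the study design the pipeline implements: melanoma
#' proximity uses a 20 um radius; the margin band extends 200 um into tumor
#' and stroma in 50 um bands; survival model selection uses 10-fold
#' cross-validation over feature subsets of size at most 6, with the
#' selection AUC evaluated at 3 years.
#'
#' @param radius_um proximity radius in micrometres (> 0)
#' @param margin_extent_um margin half-width each side of the interface
#' @param band_width_um width of each margin band; must divide the extent
#' @param cv_folds cross-validation folds for model selection
#' @param k_max maximum feature-subset size in exhaustive selection
#' @param eval_year year at which the selection AUC is read
#' @param num_trees trees per random survival forest
#' @param seed master seed feeding all stage substreams
#' @return a list of class `analysis_config`
#' @export
analysis_config <- function(radius_um = 20, margin_extent_um = 200,
                            band_width_um = 50, cv_folds = 10, k_max = 6,
                            eval_year = 3, num_trees = 200, seed = 1L) {
  assert_that(radius_um > 0, "radius_um must be > 0")
  assert_that(band_width_um > 0, "band_width_um must be > 0")
  assert_that(margin_extent_um %% band_width_um == 0,
              "margin_extent_um must be an integer multiple of band_width_um")
  assert_that(cv_folds >= 2, "cv_folds must be >= 2")
  assert_that(k_max >= 1, "k_max must be >= 1")
  structure(list(radius_um = radius_um, margin_extent_um = margin_extent_um,
                 band_width_um = band_width_um, cv_folds = cv_folds,
                 k_max = k_max, eval_year = eval_year, num_trees = num_trees,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unspecified fields take the `analysis_config()` defaults.
#'
#' @param path YAML file
#' @return an `analysis_config`
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), allowed)
  assert_that(length(unknown) == 0,
              sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  do.call(analysis_config, vals)
}

#' Read a per-(sample, marker) positivity-threshold table
#'
#' @param path CSV with columns `sample_id`, `marker`, `threshold`
#' @return data.frame of thresholds
#' @export
read_thresholds <- function(path) {
  th <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("sample_id", "marker", "threshold"), names(th))
  if (length(missing_cols) > 0) {
    stop_tilspatial(
      sprintf("threshold table missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "tilspatial_schema_error")
  }
  th
}
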