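# Per-patient clinicopathologic and outcome records.

#' Derive the 5-year outcome group
#'
#' Patients who die of melanoma (event) within 5 years of primary diagnosis
#' are `poor`; patients recurrence-free for more than 5 years are `good`;
#' everyone else (short follow-up, late events) is `unknown`.
#'
#' @param rfs_years recurrence-free survival time in years
#' @param event 1 = recurrence/melanoma death, 0 = censored
#' @param horizon_years classification horizon (default 5)
#' @return character vector: `good`, `poor` or `unknown`
#' @export
derive_outcome_group <- function(rfs_years, event, horizon_years = 5) {
  ifelse(event == 1 & rfs_years <= horizon_years, "poor",
         ifelse(event == 0 & rfs_years > horizon_years, "good", "unknown"))
}

#' Read a patient table from CSV
#'
#' Requires `patient_id`, `rfs_years`, `event`; clinicopathologic columns
#' (breslow_mm, ulceration, nodal_status, mitotic_rate, age_years, gender,
#' site, stage) and immune features are carried through. `outcome_group` is
#' derived from the 5-year rule when absent, and checked against it when
#' present.
#'
#' @param path CSV file
#' @return validated data.frame of patient records
#' @export
read_patients <- function(path) {
  pts <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("patient_id", "rfs_years", "event"), names(pts))
  if (length(missing_cols) > 0) {
    stop_tilspatial(
      sprintf("patient table missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "tilspatial_schema_error")
  }
  assert_that(!anyDuplicated(pts$patient_id), "duplicate patient_id")
  assert_that(all(pts$rfs_years >= 0), "rfs_years must be nonnegative")
  assert_that(all(pts$event %in% c(0, 1)), "event must be 0/1")
  assert_that(all(pts$rfs_years[pts$event == 1] > 0),
              "event = 1 requires rfs_years > 0")
  derived <- derive_outcome_group(pts$rfs_years, pts$event)
  if (!"outcome_group" %in% names(pts)) {
    pts$outcome_group <- derived
  } else if (any(pts$outcome_group != derived)) {
    warning(sprintf("%d outcome_group value(s) inconsistent with the 5-year rule",
                    sum(pts$outcome_group != derived)))
  }
  pts
}
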