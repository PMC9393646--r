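# Cell tables: one row per segmented cell, with sample/panel ids, coordinates
# in micrometres and per-marker fluorescence intensities.

CELL_REQUIRED_COLS <- c("sample_id", "panel_id", "cell_id", "x_um", "y_um",
                        "compartment")
COMPARTMENTS <- c("tumor", "stroma", "epidermis", "unclassified")

#' Marker columns of a cell table
#'
#' Any column that is not part of the fixed schema is treated as a marker
#' intensity column.
#'
#' @param cells a cell table
#' @return character vector of marker column names
#' @export
cell_markers <- function(cells) {
  setdiff(names(cells), CELL_REQUIRED_COLS)
}

#' Validate a per-cell table
#'
#' Checks the fixed schema: required columns present, `cell_id` unique within
#' `(sample_id, panel_id)`, finite coordinates, nonnegative marker
#' intensities, and a recognised compartment label.
#'
#' @param cells data.frame to validate
#' @return the validated table, invisibly classed as `cell_table`
#' @export
validate_cell_table <- function(cells) {
  missing_cols <- setdiff(CELL_REQUIRED_COLS, names(cells))
  if (length(missing_cols) > 0) {
    stop_tilspatial(
      sprintf("cell table is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "tilspatial_schema_error")
  }
  for (col in c("x_um", "y_um")) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop_tilspatial(
        sprintf("non-numeric %s at row(s): %s", col,
                paste(head(bad, 5), collapse = ", ")),
        "tilspatial_parse_error")
    }
    if (any(!is.finite(v))) {
      stop_tilspatial(
        sprintf("non-finite %s at row(s): %s", col,
                paste(head(which(!is.finite(v)), 5), collapse = ", ")),
        "tilspatial_parse_error")
    }
  }
  key <- paste(cells$sample_id, cells$panel_id, cells$cell_id)
  assert_that(!anyDuplicated(key),
              "cell_id must be unique within (sample_id, panel_id)")
  assert_that(all(cells$compartment %in% COMPARTMENTS),
              sprintf("compartment must be one of: %s",
                      paste(COMPARTMENTS, collapse = ", ")))
  # NA intensity means "marker not stained on this cell's panel"
  for (m in cell_markers(cells)) {
    v <- cells[[m]]
    assert_that(is.numeric(v) && all(is.na(v) | (is.finite(v) & v >= 0)),
                sprintf("marker '%s' intensities must be finite and nonnegative", m))
  }
  class(cells) <- unique(c("cell_table", class(cells)))
  invisible(cells)
}

#' Read a per-cell table from CSV
#'
#' Expects the columns `sample_id,panel_id,cell_id,x_um,y_um,compartment`
#' followed by one column per marker; unknown marker columns are kept.
#'
#' @param path CSV file path
#' @return a validated `cell_table` data.frame
#' @export
read_cell_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  cells <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cell_table(cells)
  cells <- as.data.frame(cells)
  class(cells) <- c("cell_table", "data.frame")
  cells
}

#' Write a per-cell table to CSV
#'
#' Full-precision round trip: coordinates and intensities are written with
#' enough digits that `read_cell_table()` restores them exactly.
#'
#' @param cells validated cell table
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  out <- cells
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("cell_id"))
  for (col in names(out)[num]) {
    out[[col]] <- trimws(formatC(out[[col]], format = "g", digits = 17))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
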