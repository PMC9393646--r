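# Marker positivity and hierarchical lineage / CD8 phenotype assignment.
#
# CD8+ T cells are partitioned by CD39/CD103/PD-1 positivity into the eight
# phenotype classes P1..P8; melanoma is identified by SOX10, B cells by CD20,
# NK cells by CD56 (CD3-), Langerhans cells by CD1a or Langerin, and Class I
# MHC status of melanoma cells by HLA-ABC.

CD8_CLASSES <- paste0("P", 1:8)
LINEAGES <- c("melanoma", "T_CD8", "T_nonCD8", "B", "NK", "langerhans", "other")

#' Call marker positivity against per-(sample, marker) thresholds
#'
#' A cell is positive for a marker when its intensity is greater than or
#' equal to the sample's threshold for that marker.
#'
#' @param cells a cell table
#' @param thresholds data.frame with `sample_id`, `marker`, `threshold`
#' @param markers markers to call; default all marker columns in `cells`
#' @return data.frame of logicals, one column per marker, one row per cell
#' @export
call_positivity <- function(cells, thresholds, markers = cell_markers(cells)) {
  out <- matrix(NA, nrow(cells), length(markers),
                dimnames = list(NULL, markers))
  for (s in unique(cells$sample_id)) {
    rows <- cells$sample_id == s
    ths <- thresholds[thresholds$sample_id == s, ]
    for (m in markers) {
      t_m <- ths$threshold[ths$marker == m]
      if (length(t_m) != 1) {
        stop_tilspatial(
          sprintf("no positivity threshold for sample '%s', marker '%s'", s, m),
          "tilspatial_config_error")
      }
      out[rows, m] <- cells[[m]][rows] >= t_m
    }
  }
  as.data.frame(out)
}

#' Suggest a positivity threshold from an intensity distribution
#'
#' Intensities from a marker typically form a low (negative) and a high
#' (positive) mode on the log scale. The suggestion is the antimode: the
#' minimum of a smoothed log-intensity density between the two largest modes.
#' When no second mode is detectable the distribution is treated as all
#' negative and the 99th percentile of the lower half is returned with a
#' warning. Suggestions are starting points for per-sample review, not
#' final calls.
#'
#' @param intensities nonnegative intensity values, length >= 50
#' @return threshold on the intensity scale, with attribute
#'   `review_required = TRUE`
#' @export
suggest_threshold <- function(intensities) {
  assert_that(length(intensities) >= 50, "need >= 50 intensity values")
  assert_that(all(is.finite(intensities)) && all(intensities >= 0),
              "intensities must be finite and nonnegative")
  lx <- log1p(intensities)
  fallback <- function() {
    warning("intensity distribution looks unimodal; using 99th percentile of lower half")
    lower <- intensities[intensities <= median(intensities)]
    thr <- unname(quantile(lower, 0.99, type = 7))
    structure(thr, review_required = TRUE)
  }
  if (sd(lx) < 1e-12) return(fallback())
  d <- density(lx, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) return(fallback())
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley_rel <- which.min(y[top2[1]:top2[2]])
  thr <- expm1(d$x[top2[1] + valley_rel - 1])
  structure(thr, review_required = TRUE)
}

#' Assign an immune/tumor lineage from marker positivity
#'
#' Precedence: SOX10+ cells are melanoma regardless of immune-marker status
#' (guards against segmentation bleed-through); then CD3+CD8+ = CD8 T cell,
#' CD3+CD8- = non-CD8 T cell, CD20+ = B cell, CD56+CD3- = NK cell,
#' CD1a+ or Langerin+ = Langerhans cell; everything else is `other`.
#' Markers absent from `positivity` are treated as negative, so each panel
#' resolves only the lineages its markers support.
#'
#' @param positivity data.frame of logical marker calls (columns may include
#'   SOX10, CD3, CD8, CD20, CD56, CD1a, Langerin, HLA_ABC)
#' @return data.frame with `lineage` and, for melanoma cells, `mhc1_positive`
#' @export
assign_lineage <- function(positivity) {
  n <- nrow(positivity)
  get <- function(m) {
    if (!m %in% names(positivity)) return(rep(FALSE, n))
    v <- positivity[[m]]
    v[is.na(v)] <- FALSE  # marker absent from this cell's panel
    v
  }
  sox10 <- get("SOX10"); cd3 <- get("CD3"); cd8 <- get("CD8")
  cd20 <- get("CD20"); cd56 <- get("CD56")
  cd1a <- get("CD1a"); lang <- get("Langerin")
  lineage <- rep("other", n)
  lineage[cd1a | lang] <- "langerhans"
  lineage[cd56 & !cd3] <- "NK"
  lineage[cd20] <- "B"
  lineage[cd3 & !cd8] <- "T_nonCD8"
  lineage[cd3 & cd8] <- "T_CD8"
  lineage[sox10] <- "melanoma"
  mhc1 <- ifelse(lineage == "melanoma", get("HLA_ABC"), NA)
  data.frame(lineage = lineage, mhc1_positive = mhc1)
}

#' Assign CD8+ T-cell phenotype classes P1..P8
#'
#' The eight classes enumerate CD39/CD103/PD-1 positivity:
#' P1 (+,+,+), P2 (+,+,-), P3 (+,-,+), P4 (+,-,-),
#' P5 (-,+,+), P6 (-,+,-), P7 (-,-,+), P8 (-,-,-).
#'
#' @param cd39,cd103,pd1 logical vectors of equal length
#' @return character vector of classes
#' @export
assign_cd8_class <- function(cd39, cd103, pd1) {
  assert_that(length(cd39) == length(cd103) && length(cd39) == length(pd1),
              "marker vectors must have equal length")
  idx <- 1L + (!cd39) * 4L + (!cd103) * 2L + (!pd1) * 1L
  CD8_CLASSES[idx]
}

#' Phenotype every cell in a table
#'
#' Runs positivity calling, lineage assignment and CD8 classification in one
#' pass, returning one phenotype call per cell.
#'
#' @param cells a cell table
#' @param thresholds per-(sample, marker) threshold table
#' @return data.frame: cell identity columns, per-marker positivity,
#'   `lineage`, `cd8_class` (`"none"` for non-CD8 cells), `mhc1_positive`
#' @export
phenotype_cells <- function(cells, thresholds) {
  pos <- call_positivity(cells, thresholds)
  lin <- assign_lineage(pos)
  cd8_class <- rep("none", nrow(cells))
  is_cd8 <- lin$lineage == "T_CD8"
  if (any(is_cd8)) {
    get <- function(m) if (m %in% names(pos)) pos[[m]][is_cd8] else
      rep(FALSE, sum(is_cd8))
    cd8_class[is_cd8] <- assign_cd8_class(get("CD39"), get("CD103"), get("PD1"))
  }
  cbind(cells[, c("sample_id", "panel_id", "cell_id", "x_um", "y_um",
                  "compartment")],
        pos, lineage = lin$lineage, cd8_class = cd8_class,
        mhc1_positive = lin$mhc1_positive)
}

#' CD8 phenotype composition of a compartment
#'
#' Expresses each class P1..P8 as a percentage of the CD8+ T cells in the
#' requested compartment of each sample. Samples with no CD8 cells in the
#' compartment get `NA` for all classes.
#'
#' @param calls phenotype calls from [phenotype_cells()]
#' @param compartment compartment to summarise (default `"tumor"`)
#' @return data.frame: sample_id, cd8_class, n, pct
#' @export
cd8_composition <- function(calls, compartment = "tumor") {
  samples <- unique(calls$sample_id)
  out <- expand.grid(sample_id = samples, cd8_class = CD8_CLASSES,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$pct <- NA_real_
  for (s in samples) {
    sub <- calls[calls$sample_id == s & calls$compartment == compartment &
                   calls$lineage == "T_CD8", ]
    rows <- out$sample_id == s
    if (nrow(sub) == 0) next
    counts <- table(factor(sub$cd8_class, levels = CD8_CLASSES))
    out$n[rows] <- as.integer(counts[out$cd8_class[rows]])
    out$pct[rows] <- 100 * out$n[rows] / nrow(sub)
  }
  out
}

#' T-cell fraction of a sample
#'
#' The number of T cells (CD8+ and non-CD8) as a percentage of all nucleated
#' cells in the sample, within one staining panel.
#'
#' @param calls phenotype calls for a single sample and panel
#' @return percentage in `[0, 100]`
#' @export
t_cell_fraction <- function(calls) {
  assert_that(nrow(calls) > 0, "empty sample")
  100 * sum(calls$lineage %in% c("T_CD8", "T_nonCD8")) / nrow(calls)
}
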