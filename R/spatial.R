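# Compartment densities and melanoma-proximity statistics.

#' Cell densities per compartment
#'
#' Counts each phenotype per (sample, compartment) and divides by the
#' compartment area, reporting cells per mm^2. Tumor and stroma are reported
#' by default; zero counts yield density 0, a zero-area compartment yields a
#' missing density with a warning.
#'
#' @param calls phenotype calls (must carry `sample_id`, `compartment` and
#'   the column named by `phenotype_col`)
#' @param regions a `region_set` for the sample, or a named list of
#'   `region_set`s keyed by sample id
#' @param phenotype_col column holding the phenotype label (`"lineage"` or
#'   `"cd8_class"`)
#' @param compartments compartments to report
#' @return data.frame: sample_id, phenotype, compartment, n, area_mm2,
#'   density_mm2 (with `density_mm2 * area_mm2 == n`)
#' @export
compute_density <- function(calls, regions, phenotype_col = "lineage",
                            compartments = c("tumor", "stroma")) {
  if (inherits(regions, "region_set")) {
    regions <- setNames(list(regions), regions$sample_id)
  }
  phenos <- sort(unique(calls[[phenotype_col]]))
  samples <- unique(calls$sample_id)
  out <- expand.grid(sample_id = samples, phenotype = phenos,
                     compartment = compartments, stringsAsFactors = FALSE)
  out$n <- 0L; out$area_mm2 <- NA_real_; out$density_mm2 <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- out$sample_id[i]; comp <- out$compartment[i]
    reg <- regions[[s]]
    assert_that(!is.null(reg), sprintf("no region set for sample '%s'", s))
    a <- reg$area_mm2[[comp]] %||% NA_real_
    sub <- calls$sample_id == s & calls$compartment == comp &
      calls[[phenotype_col]] == out$phenotype[i]
    out$n[i] <- sum(sub)
    out$area_mm2[i] <- a
    if (is.na(a) || a <= 0) {
      warning(sprintf("zero or missing area for %s/%s; density set to NA", s, comp))
    } else {
      out$density_mm2[i] <- out$n[i] / a
    }
  }
  out
}

#' Nearest-neighbor distances between two point sets
#'
#' Euclidean distance from each source cell to its nearest target cell,
#' in micrometres. Computed in blocks so memory stays bounded.
#'
#' @param source,target data.frames with `x_um`, `y_um`
#' @return numeric vector, one distance per source row
#' @export
nearest_neighbor_distances <- function(source, target) {
  assert_that(nrow(target) > 0, "target set is empty")
  sx <- source$x_um; sy <- source$y_um
  tx <- target$x_um; ty <- target$y_um
  n <- length(sx)
  out <- numeric(n)
  block <- max(1L, floor(4e6 / max(length(tx), 1L)))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sx[idx], tx, "-")^2 + outer(sy[idx], ty, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Percentage of source cells within a radius of any target cell
#'
#' Closed-ball convention: a source cell exactly at the radius counts as
#' within. An empty target set yields 0% with a warning (no target can be
#' near anything); an empty source set is an error.
#'
#' @param source,target data.frames with `x_um`, `y_um`
#' @param radius_um radius in micrometres
#' @return percentage in `[0, 100]`
#' @export
percent_within_radius <- function(source, target, radius_um = 20) {
  assert_that(nrow(source) > 0, "source set is empty")
  assert_that(radius_um >= 0, "radius must be >= 0")
  if (nrow(target) == 0) {
    warning("target set is empty; 0% within radius")
    return(0)
  }
  d <- nearest_neighbor_distances(source, target)
  100 * sum(d <= radius_um) / length(d)
}

#' Melanoma-proximity summary for every phenotype
#'
#' For each immune phenotype in a sample: the mean distance from each
#' melanoma cell to the nearest cell of the phenotype, the percentage of
#' melanoma cells with such a cell within the radius, and the reverse
#' percentage (phenotype cells near melanoma). Melanoma cells are stained
#' on both panels, so the comparison is restricted to cells of the same
#' panel as the melanoma reference.
#'
#' @param calls phenotype calls for one sample (both panels, registered into
#'   one frame)
#' @param radius_um proximity radius (default 20)
#' @param phenotype_col column holding phenotype labels
#' @param phenotypes labels to summarise; default every label except
#'   melanoma
#' @return data.frame: phenotype, panel, mean_nn_um, pct_melanoma_within,
#'   pct_phenotype_within, radius_um
#' @export
proximity_summary <- function(calls, radius_um = 20, phenotype_col = "lineage",
                              phenotypes = NULL) {
  phenotypes <- phenotypes %||%
    setdiff(sort(unique(calls[[phenotype_col]])), "melanoma")
  rows <- list()
  for (ph in phenotypes) {
    ph_cells <- calls[calls[[phenotype_col]] == ph, ]
    panels <- unique(ph_cells$panel_id)
    for (pn in panels) {
      mel <- calls[calls$lineage == "melanoma" & calls$panel_id == pn, ]
      tgt <- ph_cells[ph_cells$panel_id == pn, ]
      if (nrow(mel) == 0) next
      if (nrow(tgt) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          phenotype = ph, panel = pn, mean_nn_um = NA_real_,
          pct_melanoma_within = NA_real_, pct_phenotype_within = NA_real_,
          radius_um = radius_um)
        next
      }
      d <- nearest_neighbor_distances(mel, tgt)
      rows[[length(rows) + 1]] <- data.frame(
        phenotype = ph, panel = pn, mean_nn_um = mean(d),
        pct_melanoma_within = 100 * sum(d <= radius_um) / length(d),
        pct_phenotype_within = percent_within_radius(tgt, mel, radius_um),
        radius_um = radius_um)
    }
  }
  do.call(rbind, rows) %||% data.frame()
}
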