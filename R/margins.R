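# Tumor-margin infiltration analysis.
#
# The margin is the polyline at the tumor/stroma interface. Cells within a
# band of fixed extent either side of the margin are assigned a signed
# distance (negative into the tumor, positive into the stroma) and counted
# in half-open 50 um bands; band densities divide by the true area of each
# band clipped to tumor + stroma tissue.

#' Signed distance from points to the tumor margin
#'
#' Magnitude is the minimum Euclidean distance to the margin polyline(s);
#' the sign is negative for points inside the tumor and positive otherwise.
#' Points on the margin get 0 (stromal side by the half-open band
#' convention). Points in the epidermis or outside classified tissue are
#' excluded (`NA`), with the excluded count attached as an attribute.
#'
#' @param x,y coordinates in micrometres
#' @param regions a `region_set` with a margin
#' @return numeric vector of signed distances; attribute `n_excluded`
#' @export
signed_margin_distance <- function(x, y, regions) {
  assert_that(!is.null(regions$margin) && length(regions$margin) > 0,
              "region set has no margin polyline")
  pts <- cbind(x, y)
  d <- rep(Inf, length(x))
  for (m in regions$margin) d <- pmin(d, dist_to_polyline(pts, m))
  comp <- classify_points(x, y, regions)
  keep <- comp %in% c("tumor", "stroma")
  sgn <- ifelse(comp == "tumor", -1, 1)
  out <- ifelse(keep, sgn * d, NA_real_)
  out[keep & d == 0] <- 0
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Areas of margin bands
#'
#' Computes the area of each signed-distance band clipped to tumor + stroma
#' tissue by deterministic grid integration of the signed-distance field:
#' the window around the margin is covered by a square grid of pitch
#' `grid_um` and each node is classified into its band.
#'
#' @param regions a `region_set` with a margin
#' @param band_width_um band width (default 50)
#' @param extent_um extent each side of the margin (default 200; must be a
#'   multiple of the band width)
#' @param grid_um integration grid pitch in micrometres
#' @return data.frame: band_lo, band_hi, area_mm2
#' @export
band_areas <- function(regions, band_width_um = 50, extent_um = 200,
                       grid_um = 2) {
  assert_that(extent_um %% band_width_um == 0,
              "extent must be an integer multiple of band width")
  edges <- seq(-extent_um, extent_um, by = band_width_um)
  mall <- do.call(rbind, regions$margin)
  gx <- seq(min(mall[, 1]) - extent_um, max(mall[, 1]) + extent_um, by = grid_um)
  gy <- seq(min(mall[, 2]) - extent_um, max(mall[, 2]) + extent_um, by = grid_um)
  pts <- expand.grid(x = gx, y = gy)
  sd_g <- signed_margin_distance(pts$x, pts$y, regions)
  cell_area <- grid_um^2 / 1e6
  bins <- cut(sd_g, breaks = edges, right = FALSE)
  counts <- table(bins)
  data.frame(band_lo = edges[-length(edges)], band_hi = edges[-1],
             area_mm2 = as.numeric(counts) * cell_area)
}

#' Margin band infiltration profile
#'
#' Assigns every classified tumor/stroma cell a signed margin distance and
#' counts cells per phenotype in half-open bands `[lo, hi)` spanning
#' `[-extent, extent)`; densities divide by the geometric band areas.
#'
#' @param calls phenotype calls for one sample (registered frame)
#' @param regions a `region_set` with a margin
#' @param band_width_um band width in micrometres (default 50)
#' @param extent_um band extent each side (default 200)
#' @param phenotype_col column holding phenotype labels
#' @param grid_um grid pitch for band-area integration
#' @param areas optional precomputed [band_areas()] table for these regions
#'   (saves recomputing the area integral for repeated profiles)
#' @return data.frame: sample_id, phenotype, band_lo, band_hi, n, area_mm2,
#'   density_mm2; attributes `n_excluded` (cells outside classified tissue)
#'   and `n_outside` (classified cells beyond the extent)
#' @export
band_profile <- function(calls, regions, band_width_um = 50, extent_um = 200,
                         phenotype_col = "lineage", grid_um = 2,
                         areas = NULL) {
  sd_c <- signed_margin_distance(calls$x_um, calls$y_um, regions)
  edges <- seq(-extent_um, extent_um, by = band_width_um)
  areas <- areas %||% band_areas(regions, band_width_um, extent_um, grid_um)
  phenos <- sort(unique(calls[[phenotype_col]]))
  out <- expand.grid(phenotype = phenos,
                     band_lo = edges[-length(edges)],
                     stringsAsFactors = FALSE)
  out$band_hi <- out$band_lo + band_width_um
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    in_band <- !is.na(sd_c) & sd_c >= out$band_lo[i] & sd_c < out$band_hi[i] &
      calls[[phenotype_col]] == out$phenotype[i]
    out$n[i] <- sum(in_band)
  }
  out <- merge(out, areas, by = c("band_lo", "band_hi"), sort = FALSE)
  out$density_mm2 <- ifelse(out$area_mm2 > 0, out$n / out$area_mm2, NA_real_)
  out <- data.frame(sample_id = calls$sample_id[1] %||% NA_character_,
                    out[order(out$phenotype, out$band_lo),
                        c("phenotype", "band_lo", "band_hi", "n",
                          "area_mm2", "density_mm2")],
                    row.names = NULL)
  attr(out, "n_excluded") <- attr(sd_c, "n_excluded")
  attr(out, "n_outside") <- sum(!is.na(sd_c) &
                                  (sd_c < -extent_um | sd_c >= extent_um))
  out
}
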