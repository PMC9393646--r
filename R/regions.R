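# Tissue region geometry: compartment polygons plus the tumor/stroma margin.

#' Construct a region set
#'
#' A region set holds, per sample, the compartment polygons (tumor, stroma,
#' epidermis; each a list of simple polygons in micrometre coordinates), the
#' tumor/stroma margin polyline(s), and compartment areas in mm^2. Stroma and
#' epidermis rings that enclose the tumor are interpreted as outer boundaries;
#' point classification applies tumor-first precedence so the enclosed area
#' is not double counted, and the stored areas follow the same convention.
#'
#' @param sample_id sample identifier
#' @param polygons named list: compartment -> list of n x 2 polygon matrices
#' @param margin optional list of polyline matrices at the tumor/stroma border
#' @param validate check ring closure and self-intersection
#' @return an object of class `region_set`
#' @export
region_set <- function(sample_id, polygons, margin = NULL, validate = TRUE) {
  assert_that("tumor" %in% names(polygons) && length(polygons$tumor) > 0,
              "region set requires at least one tumor polygon")
  polygons <- lapply(polygons, function(ps) lapply(ps, function(p) {
    p <- as.matrix(p)
    if (validate) {
      if (polygon_self_intersects(p)) {
        stop_tilspatial("self-intersecting polygon", "tilspatial_geometry_error")
      }
    }
    close_ring(p)
  }))
  if (!is.null(margin)) {
    margin <- lapply(margin, as.matrix)
    for (m in margin) assert_that(nrow(m) >= 2, "margin polyline needs >=2 vertices")
  }
  gross <- vapply(polygons, function(ps) {
    sum(vapply(ps, polygon_area, numeric(1)))
  }, numeric(1)) / 1e6
  # tumor-first precedence: a stroma/epidermis ring that encloses the tumor
  # contributes its gross area minus the areas it encloses
  area <- gross
  if ("stroma" %in% names(polygons)) {
    enc <- encloses_area(polygons$stroma, polygons$tumor)
    area[["stroma"]] <- gross[["stroma"]] - enc / 1e6
  }
  if ("epidermis" %in% names(polygons)) {
    inner <- c(polygons$tumor, polygons$stroma %||% list())
    enc <- encloses_area(polygons$epidermis, inner)
    area[["epidermis"]] <- gross[["epidermis"]] - enc / 1e6
  }
  assert_that(all(area > 0), "compartment areas must be positive")
  structure(list(sample_id = sample_id, polygons = polygons,
                 margin = margin, area_mm2 = area),
            class = "region_set")
}

# total area (um^2) of inner polygons enclosed by any outer ring, counting
# only maximal inner rings (a ring nested inside a larger counted ring is
# already covered by it)
encloses_area <- function(outer, inner) {
  centroid <- function(p) c(mean(p[-nrow(p), 1]), mean(p[-nrow(p), 2]))
  in_any <- function(pt, polys) {
    any(vapply(polys, function(op) points_in_polygon(pt[1], pt[2], op),
               logical(1)))
  }
  inner <- inner[order(-vapply(inner, polygon_area, numeric(1)))]
  counted <- list(); tot <- 0
  for (ip in inner) {
    ct <- centroid(ip)
    if (!in_any(ct, outer)) next
    if (length(counted) > 0 && in_any(ct, counted)) next
    tot <- tot + polygon_area(ip)
    counted <- c(counted, list(ip))
  }
  tot
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", x$sample_id, "\n")
  for (k in names(x$polygons)) {
    cat(sprintf("  %-10s %d polygon(s), %.4f mm^2\n", k,
                length(x$polygons[[k]]), x$area_mm2[[k]]))
  }
  cat(sprintf("  margin: %s\n",
              if (is.null(x$margin)) "absent" else
                sprintf("%d polyline(s)", length(x$margin))))
  invisible(x)
}

#' Classify points into tissue compartments
#'
#' Tumor takes precedence over stroma, stroma over epidermis (nested rings).
#'
#' @param x,y coordinates in micrometres
#' @param regions a `region_set`
#' @return character vector of compartment labels (`"unclassified"` outside)
#' @export
classify_points <- function(x, y, regions) {
  out <- rep("unclassified", length(x))
  for (comp in c("epidermis", "stroma", "tumor")) {
    for (p in regions$polygons[[comp]] %||% list()) {
      inside <- points_in_polygon(x, y, p)
      out[inside] <- comp
    }
  }
  out
}

#' Read tissue regions from GeoJSON
#'
#' Expects an RFC 7946 FeatureCollection whose Polygon features carry a
#' `compartment` property (`tumor`, `stroma`, `epidermis`) and whose
#' LineString features with `compartment: "margin"` trace the tumor/stroma
#' interface. Coordinates are planar micrometres.
#'
#' @param path GeoJSON file
#' @param sample_id sample identifier; defaults to a top-level `sample_id`
#'   property if present
#' @return a `region_set`
#' @export
read_regions <- function(path, sample_id = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  assert_that(identical(gj$type, "FeatureCollection"),
              "regions file must be a GeoJSON FeatureCollection")
  sample_id <- sample_id %||% gj$sample_id %||% "sample"
  polygons <- list(); margin <- list()
  for (ft in gj$features) {
    comp <- ft$properties$compartment %||% "unclassified"
    geom <- ft$geometry
    if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(pt) {
        c(pt[[1]], pt[[2]])
      }))
      if (!is_closed_ring(ring)) {
        stop_tilspatial(sprintf("unclosed polygon ring for compartment '%s'", comp),
                        "tilspatial_geometry_error")
      }
      if (polygon_self_intersects(ring)) {
        stop_tilspatial(sprintf("self-intersecting polygon for compartment '%s'", comp),
                        "tilspatial_geometry_error")
      }
      polygons[[comp]] <- c(polygons[[comp]], list(ring))
    } else if (identical(geom$type, "LineString")) {
      line <- do.call(rbind, lapply(geom$coordinates, function(pt) {
        c(pt[[1]], pt[[2]])
      }))
      margin <- c(margin, list(line))
    }
  }
  if (is.null(polygons$tumor)) {
    stop_tilspatial("regions file has no tumor polygon", "tilspatial_geometry_error")
  }
  region_set(sample_id, polygons,
             margin = if (length(margin)) margin else NULL,
             validate = FALSE)
}

#' Write a region set to GeoJSON
#'
#' @param regions a `region_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regions <- function(regions, path) {
  feat <- list()
  for (comp in names(regions$polygons)) {
    for (p in regions$polygons[[comp]]) {
      coords <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
      feat <- c(feat, list(list(
        type = "Feature",
        properties = list(compartment = comp),
        geometry = list(type = "Polygon", coordinates = list(coords)))))
    }
  }
  for (m in regions$margin %||% list()) {
    coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    feat <- c(feat, list(list(
      type = "Feature",
      properties = list(compartment = "margin"),
      geometry = list(type = "LineString", coordinates = coords))))
  }
  gj <- list(type = "FeatureCollection", sample_id = regions$sample_id,
             features = feat)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
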