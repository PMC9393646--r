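# Planar geometry primitives. Coordinates are micrometres throughout.
# Polygons are n x 2 matrices (closed or open rings; closed internally).

#' Shoelace area of a simple polygon
#'
#' @param poly n x 2 matrix of vertices (closing vertex optional)
#' @return absolute area in the square of the coordinate unit
#' @export
polygon_area <- function(poly) {
  poly <- close_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

close_ring <- function(poly) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  assert_that(ncol(poly) == 2 && nrow(poly) >= 3, "polygon needs >=3 x,y vertices")
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

is_closed_ring <- function(poly) {
  poly <- as.matrix(poly)
  nrow(poly) >= 4 && all(poly[1, ] == poly[nrow(poly), ])
}

# Proper segment intersection test for self-intersection checks.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(poly) {
  poly <- close_ring(poly)
  n <- nrow(poly) - 1
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_cross(poly[i, ], poly[i + 1, ], poly[j, ], poly[j + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray casting, vectorised over points (one pass per polygon edge,
#' so large grids classify quickly). Boundary points count as inside; the
#' explicit boundary check is applied for point sets small enough that its
#' O(points x edges) cost is negligible.
#'
#' @param x,y point coordinates
#' @param poly n x 2 polygon matrix
#' @return logical vector
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- close_ring(poly)
  n <- nrow(poly)
  xv <- poly[-n, 1]; yv <- poly[-n, 2]
  m <- length(xv)
  inside <- rep(FALSE, length(x))
  j <- m
  for (i in seq_len(m)) {
    cross <- (yv[i] > y) != (yv[j] > y)
    if (any(cross)) {
      xint <- (xv[j] - xv[i]) * (y - yv[i]) / (yv[j] - yv[i]) + xv[i]
      hit <- cross & (x < xint)
      hit[is.na(hit)] <- FALSE
      inside <- xor(inside, hit)
    }
    j <- i
  }
  if (length(x) <= 20000) {
    d <- dist_to_polyline(cbind(x, y), poly)
    inside[d < 1e-9] <- TRUE
  }
  inside
}

# Minimum distance from each point to a polyline (set of segments).
# pts: m x 2; line: n x 2 (n >= 2). Vectorised over points per segment.
dist_to_polyline <- function(pts, line) {
  pts <- as.matrix(pts); line <- as.matrix(line)
  assert_that(nrow(line) >= 2, "polyline needs >=2 vertices")
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(line) - 1)) {
    a <- line[i, ]; b <- line[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Regular polygon approximating a circle; used by the tissue generator.
disc_polygon <- function(center = c(0, 0), radius, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Annulus cannot be a simple ring; tissue compartments that are annuli are
# represented by their outer ring, with containment resolved by precedence
# (tumor first, then stroma, then epidermis) when classifying points.
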