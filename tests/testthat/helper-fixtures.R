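# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# minimal well-formed cell table
tiny_cell_table <- function(n = 3, sample_id = "S1", panel_id = "tcell") {
  data.frame(sample_id = sample_id, panel_id = panel_id, cell_id = seq_len(n),
             x_um = seq_len(n) * 10, y_um = seq_len(n) * 5,
             compartment = "tumor",
             CD3 = rep(60, n), CD8 = rep(1, n), check.names = FALSE)
}

# square tumor [0,w]x[0,w] with stroma collar out to 2w on the +x side only
# is awkward; use nested squares: tumor [0,w]^2 inside stroma [-w, 2w]^2
square_regions <- function(w = 1000, sample_id = "SQ", with_margin = TRUE) {
  tum <- rbind(c(0, 0), c(w, 0), c(w, w), c(0, w))
  str <- rbind(c(-w, -w), c(2 * w, -w), c(2 * w, 2 * w), c(-w, 2 * w))
  # margin along the tumor's right edge x = w (a straight interface)
  margin <- if (with_margin) list(rbind(c(w, -w), c(w, 2 * w))) else NULL
  region_set(sample_id, polygons = list(tumor = list(tum), stroma = list(str)),
             margin = margin)
}

# straight-margin geometry for margin tests: tumor = x < 0 half of a big
# square, stroma = x > 0 half; margin = the y axis
halfplane_regions <- function(h = 1000, w = 1000, sample_id = "HP") {
  tum <- rbind(c(-w, 0), c(0, 0), c(0, h), c(-w, h))
  str <- rbind(c(-w - 1, -1), c(w, -1), c(w, h + 1), c(-w - 1, h + 1))
  region_set(sample_id, polygons = list(tumor = list(tum), stroma = list(str)),
             margin = list(rbind(c(0, 0), c(0, h))))
}

points_df <- function(x, y) data.frame(x_um = x, y_um = y)

# random simple (star-shaped) polygon around the origin
random_star_polygon <- function(n_vertices = 12, r_range = c(50, 400)) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_range[1], r_range[2])
  cbind(r * cos(th), r * sin(th))
}

# brute-force oracles ------------------------------------------------------

bf_nn_distances <- function(src, tgt) {
  vapply(seq_len(nrow(src)), function(i) {
    min(sqrt((src$x_um[i] - tgt$x_um)^2 + (src$y_um[i] - tgt$y_um)^2))
  }, numeric(1))
}

bf_pct_within <- function(src, tgt, r) {
  d <- bf_nn_distances(src, tgt)
  100 * sum(d <= r) / nrow(src)
}

bf_youden <- function(pi, outcome) {
  best_j <- -Inf; best_cut <- NA
  for (c0 in sort(unique(pi))) {
    sens <- mean(pi[outcome == 1] >= c0)
    spec <- mean(pi[outcome == 0] < c0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_cut <- c0 }
  }
  list(cutoff = best_cut, j = best_j)
}

# exact two-sided Mann-Whitney p by full enumeration (independent of the
# package implementation: works from ranks of the pooled sample)
bf_mw_exact_p <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(x, y) - mu)
  sel <- utils::combn(length(pooled), n1)
  mean(apply(sel, 2, function(s) {
    abs(u_of(pooled[s], pooled[-s]) - mu) >= obs - 1e-12
  }))
}
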