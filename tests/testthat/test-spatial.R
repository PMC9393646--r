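test_that("nearest-neighbor distances are Euclidean (3-4-5 triangle)", {
  expect_equal(nearest_neighbor_distances(points_df(0, 0), points_df(3, 4)), 5)
  expect_equal(nearest_neighbor_distances(points_df(1, 1), points_df(1, 1)), 0)
  expect_error(nearest_neighbor_distances(points_df(0, 0),
                                          points_df(numeric(0), numeric(0))),
               "empty")
})

test_that("nearest-neighbor and radius queries match the brute-force oracle", {
  set.seed(9)
  for (i in 1:5) {
    src <- points_df(runif(300, 0, 500), runif(300, 0, 500))
    tgt <- points_df(runif(300, 0, 500), runif(300, 0, 500))
    expect_equal(nearest_neighbor_distances(src, tgt),
                 bf_nn_distances(src, tgt))
    r <- runif(1, 5, 50)
    expect_equal(percent_within_radius(src, tgt, r),
                 bf_pct_within(src, tgt, r))
  }
})

test_that("percent within radius follows the closed-ball convention", {
  mel <- points_df(c(0, 100), c(0, 0))
  imm <- points_df(10, 0)
  expect_equal(percent_within_radius(mel, imm, 20), 50)
  expect_equal(percent_within_radius(mel, imm, 10), 50)  # boundary included
  expect_equal(percent_within_radius(mel, imm, 9.999), 0)
  expect_equal(percent_within_radius(mel, imm, 0), 0)
  expect_warning(
    z <- percent_within_radius(mel, points_df(numeric(0), numeric(0)), 20),
    "empty")
  expect_equal(z, 0)
})

test_that("percent within radius is non-decreasing in the radius", {
  set.seed(10)
  src <- points_df(runif(200, 0, 300), runif(200, 0, 300))
  tgt <- points_df(runif(50, 0, 300), runif(50, 0, 300))
  pcts <- vapply(seq(0, 100, by = 5), function(r) {
    percent_within_radius(src, tgt, r)
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("densities divide counts by compartment area", {
  reg <- square_regions(w = 1000, sample_id = "A")  # tumor area 1 mm^2
  calls <- data.frame(sample_id = "A",
                      compartment = rep(c("tumor", "stroma"), c(50, 20)),
                      lineage = "B",
                      x_um = 1, y_um = 1)
  dens <- compute_density(calls, reg)
  tum <- dens[dens$compartment == "tumor", ]
  expect_equal(tum$density_mm2, 50)
  expect_equal(tum$density_mm2 * tum$area_mm2, tum$n)
  # stroma: 3000x3000 minus enclosed 1 mm^2 tumor = 8 mm^2
  stro <- dens[dens$compartment == "stroma", ]
  expect_equal(stro$density_mm2, 20 / 8)
})

test_that("density estimates match the Poisson sampling oracle", {
  # homogeneous Poisson at 100 cells/mm^2 over ~10 mm^2
  set.seed(13)
  w <- sqrt(10) * 1000
  sq <- rbind(c(0, 0), c(w, 0), c(w, w), c(0, w))
  reg <- region_set("P", polygons = list(tumor = list(sq)))
  ok <- vapply(1:50, function(i) {
    n <- rpois(1, 100 * 10)
    calls <- data.frame(sample_id = "P", compartment = "tumor", lineage = "X",
                        x_um = runif(n, 0, w), y_um = runif(n, 0, w))
    d <- compute_density(calls, reg, compartments = "tumor")$density_mm2
    abs(d - 100) <= 3 * sqrt(100 / 10)
  }, logical(1))
  expect_gte(mean(ok), 0.98)
})

test_that("proximity metrics are invariant under a rigid transform", {
  ts <- generate_tissue(tissue_design(tumor_radius_um = 400,
                                      stroma_width_um = 200,
                                      melanoma_count = 300,
                                      cd8_density_mm2 = 120,
                                      other_density_mm2 = 100,
                                      seed = 31), "RI")
  calls <- phenotype_cells(ts$cells, ts$thresholds)
  calls <- calls[calls$panel_id == "tcell", ]
  p0 <- proximity_summary(calls, radius_um = 20)
  th <- 73 * pi / 180
  tf <- structure(list(A = cbind(matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                        2), c(1234, -987))),
                  class = "planar_transform")
  p1 <- proximity_summary(apply_transform(calls, tf), radius_um = 20)
  expect_equal(p1$mean_nn_um, p0$mean_nn_um, tolerance = 1e-6)
  expect_equal(p1$pct_melanoma_within, p0$pct_melanoma_within)
  expect_equal(p1$pct_phenotype_within, p0$pct_phenotype_within)
})
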