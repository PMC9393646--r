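test_that("signed margin distance is negative in tumor, zero on the margin", {
  reg <- halfplane_regions(h = 1000, w = 1000)
  d <- signed_margin_distance(c(-30, 30, 0, -999999), c(500, 500, 500, 500),
                              reg)
  expect_equal(d[1], -30)
  expect_equal(d[2], 30)
  expect_equal(d[3], 0)
  expect_true(is.na(d[4]))           # outside classified tissue
  expect_equal(attr(d, "n_excluded"), 1)
})

test_that("signed distances match a dense margin-sampling oracle", {
  # wavy margin; oracle resamples the polyline at 0.1 um spacing
  xs <- seq(0, 1000, by = 25)
  margin <- cbind(50 * sin(xs / 120), xs)
  w <- 2000
  tum <- rbind(cbind(50 * sin(xs / 120), xs), c(-w, 1000), c(-w, 0))
  str <- rbind(c(-w, -1), c(w, -1), c(w, 1001), c(-w, 1001))
  reg <- region_set("W", polygons = list(tumor = list(tum), stroma = list(str)),
                    margin = list(margin), validate = FALSE)
  dense <- do.call(rbind, lapply(seq_len(nrow(margin) - 1), function(i) {
    a <- margin[i, ]; b <- margin[i + 1, ]
    nseg <- max(2, ceiling(sqrt(sum((b - a)^2)) / 0.1))
    tt <- seq(0, 1, length.out = nseg)
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }))
  set.seed(17)
  px <- runif(500, -300, 300); py <- runif(500, 100, 900)
  d_pkg <- abs(signed_margin_distance(px, py, reg))
  d_oracle <- vapply(seq_along(px), function(i) {
    min(sqrt((px[i] - dense[, 1])^2 + (py[i] - dense[, 2])^2))
  }, numeric(1))
  expect_lt(max(abs(d_pkg - d_oracle), na.rm = TRUE), 0.2)
})

test_that("cells land in the documented half-open bands", {
  reg <- halfplane_regions()
  sd_x <- c(-25, 25, 180, -180, 250)
  calls <- data.frame(sample_id = "HP", x_um = sd_x, y_um = 500,
                      lineage = "B")
  bp <- band_profile(calls, reg, grid_um = 5)
  got <- setNames(bp$n, paste0("[", bp$band_lo, ",", bp$band_hi, ")"))
  expect_equal(unname(got[c("[-50,0)", "[0,50)", "[150,200)", "[-200,-150)")]),
               c(1, 1, 1, 1))
  expect_equal(sum(bp$n), 4)  # the 250 um cell is outside the extent
  expect_equal(attr(bp, "n_outside"), 1)
  expect_equal(nrow(bp[bp$phenotype == "B", ]), 8)
})

test_that("band counts plus exclusions conserve the cell total", {
  ts <- generate_tissue(tissue_design(tumor_radius_um = 400,
                                      stroma_width_um = 250,
                                      melanoma_count = 400,
                                      cd8_density_mm2 = 150,
                                      other_density_mm2 = 200,
                                      seed = 23), "CV")
  calls <- phenotype_cells(ts$cells, ts$thresholds)
  calls <- calls[calls$panel_id == "tcell", ]
  bp <- band_profile(calls, ts$regions, grid_um = 5)
  expect_equal(sum(bp$n) + attr(bp, "n_outside") + attr(bp, "n_excluded"),
               nrow(calls))
  # counts invariant under phenotype relabeling
  calls2 <- calls
  calls2$lineage <- factor(calls$lineage,
                           labels = paste0("ph_", seq_along(unique(calls$lineage))))
  bp2 <- band_profile(calls2, ts$regions, grid_um = 5)
  expect_equal(sort(tapply(bp2$n, bp2$band_lo, sum)),
               sort(tapply(bp$n, bp$band_lo, sum)))
})

test_that("homogeneous cells give flat band densities on a straight margin", {
  reg <- halfplane_regions(h = 2000, w = 500)
  set.seed(29)
  ba <- band_areas(reg, grid_um = 2)
  dens <- vapply(1:20, function(i) {
    n <- rpois(1, 200 * 1 * 2)  # 200/mm^2 over the 1x2 mm window
    calls <- data.frame(sample_id = "HP", x_um = runif(n, -500, 500),
                        y_um = runif(n, 0, 2000), lineage = "X")
    bp <- band_profile(calls, reg, areas = ba)
    bp$density_mm2
  }, numeric(8))
  pooled <- rowMeans(dens)  # per-band mean over the 20 realisations
  expect_lt(max(pooled) / min(pooled), 1.2)
})

test_that("band areas equal the analytic annulus areas on a disc margin", {
  reg <- region_set("D",
                    polygons = list(tumor = list(disc_polygon(radius = 1000,
                                                              n = 512)),
                                    stroma = list(disc_polygon(radius = 1600,
                                                               n = 512))),
                    margin = list(close_ring(disc_polygon(radius = 1000,
                                                          n = 512))),
                    validate = FALSE)
  ba <- band_areas(reg, grid_um = 2)
  analytic <- vapply(seq_len(8), function(i) {
    lo <- ba$band_lo[i]; hi <- ba$band_hi[i]
    pi * ((1 + hi / 1000)^2 - (1 + lo / 1000)^2)
  }, numeric(1))
  expect_equal(ba$area_mm2, analytic, tolerance = 0.01)
})
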