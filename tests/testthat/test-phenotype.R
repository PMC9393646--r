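test_that("positivity uses the >= convention and per-sample thresholds", {
  cells <- tiny_cell_table(3)
  cells$CD3 <- c(10, 5, 4.999)
  th <- data.frame(sample_id = "S1", marker = c("CD3", "CD8"),
                   threshold = c(5, 5))
  pos <- call_positivity(cells, th)
  expect_equal(pos$CD3, c(TRUE, TRUE, FALSE))
  th_missing <- th[th$marker == "CD3", ]
  expect_error(call_positivity(cells, th_missing), "CD8",
               class = "tilspatial_config_error")
})

test_that("raising a threshold never increases the positive count", {
  set.seed(11)
  for (i in 1:10) {
    x <- rlnorm(500, sample(c(1, 4), 1), 0.5)
    cells <- tiny_cell_table(500)
    cells$CD3 <- x
    counts <- vapply(seq(0, 60, by = 5), function(t) {
      th <- data.frame(sample_id = "S1", marker = c("CD3", "CD8"),
                       threshold = c(t, 5))
      sum(call_positivity(cells, th)$CD3)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("suggested thresholds separate bimodal intensities", {
  set.seed(3)
  x <- c(rlnorm(500, 0, 0.3), rlnorm(500, log(100), 0.3))
  thr <- suggest_threshold(x)
  expect_gt(thr, exp(0 + 2 * 0.3))
  expect_lt(thr, 100 * exp(-2 * 0.3))
  expect_true(attr(thr, "review_required"))
  expect_warning(suggest_threshold(rep(5, 100)), "unimodal")
})

test_that("suggested thresholds recover simulator ground truth calls", {
  set.seed(21)
  acc <- vapply(1:20, function(i) {
    state <- runif(400) < 0.4
    x <- rlnorm(400, ifelse(state, 4, 1), 0.3)
    thr <- as.numeric(suggest_threshold(x))
    mean((x >= thr) == state)
  }, numeric(1))
  expect_true(all(acc >= 0.98))
})

test_that("lineage assignment follows the marker hierarchy", {
  mk <- function(...) {
    v <- list(...)
    as.data.frame(lapply(v, identity))
  }
  pos <- data.frame(SOX10 = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
                    CD3 = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                    CD8 = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                    CD20 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    CD56 = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
                    CD1a = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
                    Langerin = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
                    HLA_ABC = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  lin <- assign_lineage(pos)
  # SOX10 wins over CD3; CD56+CD3+ is NOT NK; all-negative is other
  expect_equal(lin$lineage,
               c("melanoma", "T_CD8", "T_nonCD8", "B", "T_nonCD8", "NK",
                 "other"))
  expect_true(lin$mhc1_positive[1])
  expect_true(is.na(lin$mhc1_positive[2]))
})

test_that("the eight CD39/CD103/PD-1 combinations map bijectively to P1..P8", {
  grid <- expand.grid(cd39 = c(TRUE, FALSE), cd103 = c(TRUE, FALSE),
                      pd1 = c(TRUE, FALSE))
  cls <- assign_cd8_class(grid$cd39, grid$cd103, grid$pd1)
  expect_setequal(cls, paste0("P", 1:8))
  expect_equal(assign_cd8_class(TRUE, TRUE, FALSE), "P2")
  expect_equal(assign_cd8_class(FALSE, FALSE, FALSE), "P8")
  expect_equal(assign_cd8_class(TRUE, TRUE, TRUE), "P1")
})

test_that("CD8 composition sums to 100 and matches designed shares", {
  # arithmetic on a constructed sample: 10x7 + 30 cells
  calls <- data.frame(sample_id = "A", compartment = "tumor",
                      lineage = "T_CD8",
                      cd8_class = rep(paste0("P", 1:8), c(rep(10, 7), 30)))
  comp <- cd8_composition(calls)
  expect_equal(comp$pct[comp$cd8_class == "P8"], 30)
  expect_equal(sum(comp$pct), 100, tolerance = 1e-9)

  single <- data.frame(sample_id = "B", compartment = "tumor",
                       lineage = "T_CD8", cd8_class = "P2")
  expect_equal(cd8_composition(single)$pct[2], 100)

  # simulator: designed shares recovered within binomial bounds
  ts <- generate_tissue(tissue_design(cd8_density_mm2 = 260,
                                      melanoma_count = 200,
                                      other_density_mm2 = 50,
                                      t_noncd8_density_mm2 = 0,
                                      seed = 8), "C")
  calls <- phenotype_cells(ts$cells, ts$thresholds)
  cd8 <- calls[calls$lineage == "T_CD8", ]
  expect_gt(nrow(cd8), 1500)
  design_p <- tissue_design()$cd8_class_probs
  comp <- cd8_composition(calls, "tumor")
  n_tot <- sum(comp$n)
  for (k in paste0("P", 1:8)) {
    p_hat <- comp$pct[comp$cd8_class == k] / 100
    bound <- 1.96 * sqrt(design_p[[k]] * (1 - design_p[[k]]) / n_tot)
    expect_lt(abs(p_hat - design_p[[k]]), bound + 0.015)
  }
})

test_that("T-cell fraction is T cells over all nucleated cells", {
  calls <- data.frame(sample_id = "A",
                      lineage = rep(c("T_CD8", "T_nonCD8", "other"),
                                    c(5, 15, 180)))
  expect_equal(t_cell_fraction(calls), 10)
  expect_equal(t_cell_fraction(data.frame(sample_id = "A", lineage = "other")),
               0)
  expect_error(t_cell_fraction(data.frame(lineage = character(0))), "empty")
})
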