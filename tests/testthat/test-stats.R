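test_that("Mann-Whitney comparison: symmetry, separation, oracle equality", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_groups(x, x)$p_value, 1)
  sep <- compare_groups(c(1, 2, 3, 4, 5), c(10, 11, 12, 13, 14))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- round(rnorm(n1), 1); b <- round(rnorm(n2, 0.5), 1)  # ties likely
    expect_equal(compare_groups(a, b)$p_value, bf_mw_exact_p(a, b),
                 tolerance = 1e-12)
  }
  # independent cross-check against the standard implementation (no ties)
  set.seed(42)
  a <- rnorm(6); b <- rnorm(7)
  expect_equal(compare_groups(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_warning(p_tied <- compare_groups(rep(1, 5), rep(1, 5))$p_value,
                 "tied")
  expect_equal(p_tied, 1)
})

test_that("large-sample comparison holds its type-I error near 0.05", {
  set.seed(43)
  rej <- vapply(1:10000, function(i) {
    compare_groups(rnorm(12), rnorm(12))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("correlation clustering: identical, anti-correlated, block designs", {
  set.seed(44)
  f <- data.frame(a = rnorm(30))
  f$b <- f$a                       # duplicate
  f$c <- -f$a                      # perfect anti-correlation
  f$d <- rnorm(30)
  cl <- correlation_cluster(f, k = 2)
  expect_equal(cl$rho["a", "b"], 1)
  expect_equal(1 - cl$rho["a", "c"], 2)       # distance at the maximum
  expect_equal(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_true(isSymmetric(cl$rho))
  expect_equal(unname(diag(cl$rho)), rep(1, 4))
  # invariant to column order
  cl2 <- correlation_cluster(f[, c("d", "c", "b", "a")], k = 2)
  expect_equal(cl2$clusters[names(cl$clusters)], cl$clusters)
  expect_warning(correlation_cluster(cbind(f, const = 1)), "constant")
})

test_that("designed correlation blocks are recovered at k = 3", {
  set.seed(45)
  hits <- vapply(1:50, function(i) {
    n <- 200
    z <- matrix(rnorm(3 * n), n, 3)
    # within-block correlation ~0.8, between ~0
    f <- do.call(cbind, lapply(1:3, function(b) {
      sapply(1:3, function(j) 2 * z[, b] + rnorm(n))
    }))
    colnames(f) <- sprintf("blk%d_%d", rep(1:3, each = 3), rep(1:3, 3))
    cl <- correlation_cluster(as.data.frame(f), k = 3)
    truth <- rep(1:3, each = 3)[match(names(cl$clusters), colnames(f))]
    # cluster labels are arbitrary; compare the induced partitions
    all(outer(cl$clusters, cl$clusters, "==") == outer(truth, truth, "=="))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

null_profile <- function(n_per_group, shift_stroma = 1) {
  bands <- seq(-200, 150, by = 50)
  do.call(rbind, lapply(seq_len(2 * n_per_group), function(s) {
    g <- if (s <= n_per_group) "good" else "poor"
    mult <- if (g == "good") shift_stroma else 1
    data.frame(sample_id = paste0("S", s), band_lo = bands,
               density_mm2 = rlnorm(8, log(50), 0.5) *
                 ifelse(bands >= 0, mult, 1),
               group = g)
  }))
}

test_that("margin profile test is calibrated under the null", {
  set.seed(46)
  ps <- vapply(1:400, function(i) {
    margin_profile_test(null_profile(10))$anova$p_value[2]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("margin profile test detects a stroma-side group shift", {
  set.seed(47)
  hit <- vapply(1:100, function(i) {
    res <- margin_profile_test(null_profile(30, shift_stroma = 1.5))
    res$anova$p_value[2] < 0.05 && res$anova$p_value[3] < 0.05
  }, logical(1))
  expect_gte(mean(hit), 0.90)
})

test_that("margin profile test rejects single-band input", {
  prof <- null_profile(5)
  expect_error(margin_profile_test(prof[prof$band_lo == 0, ]), ">= 2 bands")
})

test_that("cohort summaries reproduce printed count percentages", {
  expect_equal(format_count_pct(16, 33), "16/33 (48.48%)")
  expect_equal(count_pct(16, 33), 48.48)
  expect_equal(count_pct(25, 80), 31.25)
  expect_equal(count_pct(33, 66), 50)
  expect_equal(format_count_pct(0, 10), "0/10 (0.00%)")

  pts <- data.frame(patient_id = sprintf("P%02d", 1:12),
                    rfs_years = c(rep(2, 6), rep(6.5, 6)),
                    event = rep(c(1, 0), each = 6),
                    breslow_mm = rep(c(2, 4), 6),
                    ulceration = rep(c(1, 0, 1), 4))
  pts$outcome_group <- derive_outcome_group(pts$rfs_years, pts$event)
  summ <- cohort_summary(pts)
  ulc_poor <- summ[summ$variable == "ulceration" & summ$level == "1" &
                     summ$group == "poor", ]
  expect_equal(ulc_poor$summary,
               format_count_pct(ulc_poor$n, ulc_poor$denominator))
  n_tot <- summ[summ$variable == "n" & summ$group == "total", ]
  expect_equal(n_tot$n, 12)
})
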