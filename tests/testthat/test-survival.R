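test_that("univariable Cox is unbiased under the null and recovers effects", {
  set.seed(51)
  covered <- vapply(1:100, function(i) {
    d <- data.frame(rfs_years = rexp(500), event = 1, x = rnorm(500))
    fit <- cox_univariable(d, "x")
    se <- (log(fit$ci_hi) - log(fit$hr)) / qnorm(0.975)
    abs(fit$coef) <= 2 * se
  }, logical(1))
  expect_gte(mean(covered), 0.93)

  errs <- vapply(1:20, function(i) {
    x <- rnorm(500)
    t <- rexp(500, exp(0.7 * x))
    d <- data.frame(rfs_years = t, event = 1, x = x)
    abs(cox_univariable(d, "x")$coef - 0.7)
  }, numeric(1))
  expect_lte(mean(errs), 0.15)

  d <- data.frame(rfs_years = rexp(50), event = 1, x = 1)
  expect_error(cox_univariable(d, "x"), "constant")
})

test_that("subset enumeration counts match the binomial sums", {
  expect_length(enumerate_subsets(paste0("f", 1:10), 6), 847)
  expect_length(enumerate_subsets("solo", 1), 1)
  expect_length(enumerate_subsets(paste0("f", 1:3), 6), 7)
  expect_error(enumerate_subsets(paste0("f", 1:3), 0), "k_max")
  subs <- enumerate_subsets(c("b", "a"), 2)
  expect_equal(subs, list("a", "b", c("a", "b")))  # deterministic order
})

test_that("Youden cutoffs equal the brute-force threshold scan", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    pi <- round(rnorm(n), sample(1:3, 1))  # ties at low precision
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    got <- roc_cutoff(pi, outcome)
    want <- bf_youden(pi, outcome)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
  }
})

test_that("Youden cutoff separates a perfectly discriminating index", {
  got <- roc_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(got$youden_j, 1)
  expect_gt(got$cutoff, 3); expect_lte(got$cutoff, 10)
  expect_error(roc_cutoff(1:5, rep(1, 5)), "classes")
  # null: random index achieves little
  set.seed(53)
  js <- vapply(1:50, function(i) {
    roc_cutoff(rnorm(200), rbinom(200, 1, 0.5))$youden_j
  }, numeric(1))
  expect_lte(mean(js), 0.25)
})

test_that("pROC agrees with the package cutoff scan", {
  skip_if_not_installed("pROC")
  set.seed(54)
  pi <- rnorm(150); outcome <- rbinom(150, 1, 0.4)
  got <- roc_cutoff(pi, outcome)
  r <- pROC::roc(outcome, pi, quiet = TRUE, direction = "<")
  co <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  expect_equal(got$youden_j, max(co$sensitivity + co$specificity - 1),
               tolerance = 1e-9)
})

test_that("KM without censoring equals the empirical survival fraction", {
  set.seed(55)
  t1 <- rexp(40); t2 <- rexp(40, 2)
  km <- km_logrank(c(t1, t2), rep(1, 80), rep(c("a", "b"), each = 40))
  ca <- km$curves[km$curves$group == "a", ]
  emp <- vapply(ca$time, function(tt) mean(t1 > tt), numeric(1))
  expect_equal(ca$surv, emp, tolerance = 1e-12)
  # identical groups: chi-square 0, p 1
  km0 <- km_logrank(rep(t1, 2), rep(1, 80), rep(c("a", "b"), each = 40))
  expect_equal(km0$chisq, 0, tolerance = 1e-9)
  expect_equal(km0$p_value, 1, tolerance = 1e-9)
  expect_error(km_logrank(t1, rep(1, 40), rep("a", 40)), "groups")
})

test_that("log-rank detects a hazard ratio of 2 at n = 100 per group", {
  set.seed(56)
  hit <- vapply(1:100, function(i) {
    t1 <- rexp(100, 1); t2 <- rexp(100, 2)
    km_logrank(c(t1, t2), rep(1, 200),
               rep(c("a", "b"), each = 100))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hit), 0.90)
})

test_that("time-dependent AUC: planted signal, null, and antisymmetry", {
  set.seed(57)
  n <- 300
  x <- rnorm(n)
  t <- rexp(n, exp(1.5 * x)) * 3
  cens <- rexp(n, 0.1)
  time <- pmin(t, cens); event <- as.integer(t <= cens)
  a <- time_dependent_auc(x, time, event, eval_years = 3)
  expect_gte(a$auc, 0.9)
  # reversing the index mirrors the AUC
  a_rev <- time_dependent_auc(-x, time, event, eval_years = 3)
  expect_equal(a_rev$auc, 1 - a$auc, tolerance = 1e-9)

  nulls <- vapply(1:50, function(i) {
    pi <- rnorm(n)
    time_dependent_auc(pi, time, event, eval_years = 3)$auc
  }, numeric(1))
  expect_gt(mean(nulls), 0.45); expect_lt(mean(nulls), 0.55)

  # uncensored closed-form oracle: cumulative/dynamic AUC at t equals the
  # plain binary AUC of (event by t) vs the index
  t_all <- rexp(200, exp(0.8 * rnorm(200)))
  pi2 <- rnorm(200) + t_all * -0.3
  lab <- as.integer(t_all <= 1)
  got <- time_dependent_auc(pi2, t_all, rep(1, 200), eval_years = 1)$auc
  r <- outer(pi2[lab == 1], pi2[lab == 0], ">") +
    0.5 * outer(pi2[lab == 1], pi2[lab == 0], "==")
  expect_equal(got, mean(r), tolerance = 1e-12)
})

test_that("model selection is deterministic given the seed", {
  co <- generate_cohort(cohort_design(n = 80, n_noise = 1, seed = 9))
  d <- co$patients
  s1 <- select_model(d, c("pct_p2_tumor", "breslow_mm"), k_max = 1,
                     folds = 3, seed = 7, num_trees = 25)
  s2 <- select_model(d, c("pct_p2_tumor", "breslow_mm"), k_max = 1,
                     folds = 3, seed = 7, num_trees = 25)
  expect_identical(s1$best$features, s2$best$features)
  expect_identical(s1$subsets$auc, s2$subsets$auc)
  expect_identical(s1$best$pi, s2$best$pi)
  expect_identical(s1$best$cutoff, s2$best$cutoff)
})
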