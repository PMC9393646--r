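# Survival modelling: univariable Cox screening, exhaustive-subset random
# survival forests with cross-validated time-dependent AUC, ROC-derived
# prognostic-index cutoffs and Kaplan-Meier / log-rank stratification.
#
# The prognostic index (PI) of a forest is its ensemble mortality: the sum
# over event times of the predicted cumulative hazard. Higher PI = higher
# predicted risk.

#' Univariable Cox proportional-hazards screen
#'
#' Partial-likelihood fit of a single feature; reports the hazard ratio,
#' 95% Wald confidence interval and Wald p-value. A feature showing signs of
#' monotone-likelihood separation (diverging coefficient) is refitted with a
#' ridge penalty and flagged with a warning.
#'
#' @param dataset data.frame with time, event and feature columns
#' @param feature name of the feature column
#' @param time_col,event_col survival columns (defaults `rfs_years`, `event`)
#' @return data.frame: feature, n, coef (log-HR), hr, ci_lo, ci_hi, p_value
#' @export
cox_univariable <- function(dataset, feature, time_col = "rfs_years",
                            event_col = "event") {
  x <- dataset[[feature]]
  assert_that(!is.null(x), sprintf("no column '%s'", feature))
  assert_that(length(unique(x[!is.na(x)])) > 1,
              sprintf("feature '%s' is constant", feature))
  d <- data.frame(time = dataset[[time_col]], event = dataset[[event_col]],
                  x = x)
  d <- d[complete.cases(d), ]
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, data = d))
  if (!is.finite(coef(fit)) || abs(coef(fit)) > 15) {
    warning(sprintf("feature '%s' shows separation; refitting with ridge penalty",
                    feature))
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ ridge(x, theta = 1),
                      data = d))
  }
  b <- coef(fit)[1]; se <- sqrt(diag(fit$var))[1]
  z <- b / se
  data.frame(feature = feature, n = nrow(d), coef = unname(b),
             hr = exp(unname(b)),
             ci_lo = exp(unname(b - qnorm(0.975) * se)),
             ci_hi = exp(unname(b + qnorm(0.975) * se)),
             p_value = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Enumerate candidate feature subsets
#'
#' All subsets of size 1..`k_max` in deterministic order: by size, then
#' lexicographically within size. `k_max` is capped at the number of
#' features.
#'
#' @param features character vector of feature names
#' @param k_max maximum subset size (default 6)
#' @return list of character vectors
#' @export
enumerate_subsets <- function(features, k_max = 6) {
  assert_that(k_max >= 1, "k_max must be >= 1")
  assert_that(length(features) >= 1, "need >= 1 feature")
  features <- sort(unique(features))
  k_max <- min(k_max, length(features))
  out <- list()
  for (k in seq_len(k_max)) {
    cmb <- combn(features, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Deterministic event-stratified fold assignment.
stratified_folds <- function(event, folds, seed) {
  fold <- integer(length(event))
  with_seed(seed, {
    for (lev in unique(event)) {
      idx <- which(event == lev)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

rsf_pi <- function(fit, newdata) {
  p <- predict(fit, data = newdata)
  rowSums(p$chf)
}

#' Exhaustive feature-subset selection with random survival forests
#'
#' For every candidate subset a random survival forest (log-rank splitting)
#' is trained under k-fold cross-validation stratified on event status; the
#' out-of-fold prognostic index is scored by cumulative/dynamic AUC at the
#' evaluation year and the subset with the highest AUC is selected. For the
#' selected subset the per-fold permutation importances (mean and s.d.
#' across folds), out-of-fold time-dependent AUC at years 1..5, the
#' Youden-optimal PI cutoff at the evaluation year, and per-patient risk
#' groups are reported.
#'
#' @param dataset data.frame with survival columns and candidate features
#' @param features candidate feature names
#' @param k_max maximum subset size (default 6)
#' @param folds cross-validation folds (default 10)
#' @param seed integer seed controlling folds and forests
#' @param eval_year selection horizon in years (default 3); `NULL` selects
#'   on the mean AUC across `eval_years`, which is more stable when no
#'   single horizon is privileged
#' @param num_trees trees per forest (default 200)
#' @param min_node_size minimum terminal-node size (default 10; regularises
#'   against spurious splits on noise features)
#' @param mtry split candidates per node; default `ceiling(sqrt(p))` for a
#'   subset of p features
#' @param eval_years horizons for the reported AUC curve
#' @param time_col,event_col survival columns
#' @return list of class `til_model_selection`: `subsets` (data.frame with
#'   subset, size, auc), `best` (list: features, auc, auc_by_year,
#'   importance, pi, cutoff, risk_group)
#' @export
select_model <- function(dataset, features, k_max = 6, folds = 10, seed = 1L,
                         eval_year = 3, num_trees = 200, min_node_size = 10,
                         mtry = NULL, eval_years = 1:5,
                         time_col = "rfs_years", event_col = "event") {
  d <- dataset[, c(time_col, event_col, features)]
  assert_that(all(complete.cases(d)), "dataset has missing values")
  time <- d[[time_col]]; event <- d[[event_col]]
  assert_that(sum(event) >= folds,
              "need at least one event per fold; reduce folds")
  fold <- stratified_folds(event, folds, substream_seed(seed, "folds"))

  subsets <- enumerate_subsets(features, k_max)
  rsf_formula <- function(feats) stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", feats), collapse = " + ")))
  fit_subset <- function(feats, importance = "none") {
    # the ensemble-mortality scale depends on the training split, so raw
    # out-of-fold PIs are not comparable across folds; scoring uses
    # within-fold ranks mapped to (0, 1)
    pi_oof <- numeric(nrow(d))
    imp <- matrix(NA_real_, folds, length(feats),
                  dimnames = list(NULL, feats))
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- ranger::ranger(rsf_formula(feats), data = d[tr, , drop = FALSE],
                            num.trees = num_trees, splitrule = "logrank",
                            min.node.size = min_node_size,
                            mtry = mtry %||% ceiling(sqrt(length(feats))),
                            importance = importance,
                            seed = substream_seed(seed, paste0("rsf", f)),
                            num.threads = 1)
      raw <- rsf_pi(fit, d[te, , drop = FALSE])
      pi_oof[te] <- rank(raw, ties.method = "average") / (length(raw) + 1)
      if (importance != "none") imp[f, ] <- fit$variable.importance[feats]
    }
    list(pi = pi_oof, imp = imp)
  }

  sel_years <- eval_year %||% eval_years
  aucs <- numeric(length(subsets))
  pis <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    res <- fit_subset(subsets[[i]])
    pis[[i]] <- res$pi
    a <- time_dependent_auc(res$pi, time, event, eval_years = sel_years)
    aucs[i] <- mean(a$auc, na.rm = TRUE)
  }
  best_i <- which.max(aucs)
  best_feats <- subsets[[best_i]]

  best_fit <- fit_subset(best_feats, importance = "permutation")
  # the reported PI comes from one full-cohort forest, using out-of-bag
  # predictions so every patient's PI is on a single honest scale
  final <- ranger::ranger(rsf_formula(best_feats), data = d,
                          num.trees = num_trees, splitrule = "logrank",
                          min.node.size = min_node_size,
                          mtry = mtry %||% ceiling(sqrt(length(best_feats))),
                          seed = substream_seed(seed, "rsf_final"),
                          num.threads = 1)
  pi_final <- rowSums(final$chf)
  auc_by_year <- time_dependent_auc(pi_final, time, event,
                                    eval_years = eval_years, n_boot = 200,
                                    seed = substream_seed(seed, "aucboot"))
  cutoff_year <- eval_year %||% stats::median(eval_years)
  outcome <- outcome_at_year(time, event, cutoff_year)
  usable <- !is.na(outcome)
  cut <- roc_cutoff(pi_final[usable], outcome[usable])
  risk_group <- ifelse(pi_final >= cut$cutoff, "high", "low")
  importance <- data.frame(
    feature = best_feats,
    weight_mean = colMeans(best_fit$imp),
    weight_sd = apply(best_fit$imp, 2, sd), row.names = NULL)
  importance <- importance[order(-importance$weight_mean), ]

  structure(list(
    subsets = data.frame(
      subset = vapply(subsets, paste, character(1), collapse = "+"),
      size = lengths(subsets), auc = aucs),
    best = list(features = best_feats, auc = aucs[best_i],
                auc_by_year = auc_by_year, importance = importance,
                pi = pi_final, pi_oof = best_fit$pi, cutoff = cut$cutoff,
                risk_group = risk_group),
    eval_year = eval_year, selection_years = sel_years, folds = folds,
    seed = seed, num_trees = num_trees), class = "til_model_selection")
}

#' @export
print.til_model_selection <- function(x, ...) {
  cat(sprintf("exhaustive RSF selection: %d subsets, %d-fold CV\n",
              nrow(x$subsets), x$folds))
  cat(sprintf("best subset (AUC %.3f at year(s) %s): %s\n",
              x$best$auc, paste(x$selection_years, collapse = ","),
              paste(x$best$features, collapse = " + ")))
  invisible(x)
}

#' Binary outcome status at a horizon
#'
#' 1 for patients with an event by `year`, 0 for patients followed beyond
#' `year`, `NA` for patients censored before `year` (status unknowable).
#'
#' @param time,event survival time and event indicator
#' @param year horizon
#' @return integer vector with NAs
#' @export
outcome_at_year <- function(time, event, year) {
  ifelse(event == 1 & time <= year, 1L,
         ifelse(time > year, 0L, NA_integer_))
}

#' Youden-optimal cutoff on a prognostic index
#'
#' Scans every observed PI value as a candidate cutoff (high risk = PI at or
#' above the cutoff) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1; ties resolve to the smallest cutoff.
#'
#' @param pi numeric prognostic indices
#' @param outcome binary outcome (1 = event by the horizon)
#' @return list: cutoff, sensitivity, specificity, youden_j
#' @export
roc_cutoff <- function(pi, outcome) {
  keep <- !is.na(pi) & !is.na(outcome)
  pi <- pi[keep]; outcome <- outcome[keep]
  assert_that(length(unique(outcome)) == 2, "need both outcome classes")
  n_pos <- sum(outcome == 1); n_neg <- sum(outcome == 0)
  cand <- sort(unique(pi))
  best <- list(cutoff = cand[1], sensitivity = NA, specificity = NA,
               youden_j = -Inf)
  for (c0 in cand) {
    high <- pi >= c0
    sens <- sum(high & outcome == 1) / n_pos
    spec <- sum(!high & outcome == 0) / n_neg
    j <- sens + spec - 1
    if (j > best$youden_j + 1e-12) {
      best <- list(cutoff = c0, sensitivity = sens, specificity = spec,
                   youden_j = j)
    }
  }
  best
}

# IPCW weights: KM estimate of the censoring survivor function G.
censoring_survfit <- function(time, event) {
  survival::survfit(survival::Surv(time, 1 - event) ~ 1)
}

eval_km <- function(fit, t, left = FALSE) {
  # step-function evaluation of a survfit curve at t (left limit optional)
  tt <- if (left) t - 1e-10 else t
  s <- summary(fit, times = tt, extend = TRUE)$surv
  pmax(s, 1e-10)
}

#' Cumulative/dynamic time-dependent AUC of a prognostic index
#'
#' At each horizon t, cases are patients with an event by t and controls are
#' patients still event-free beyond t; the AUC is the IPCW-weighted
#' probability that a case's PI exceeds a control's (ties count 1/2), with
#' case weights 1/G(T-) from the Kaplan-Meier censoring distribution
#' (Uno-type estimator). Horizons with no cases or no controls give `NA`.
#' Optional bootstrap (resampling patients) gives percentile CIs.
#'
#' @param pi prognostic index, higher = higher risk
#' @param time,event survival data
#' @param eval_years horizons (default 1..5 years)
#' @param n_boot bootstrap replicates for CIs (0 = none)
#' @param seed bootstrap seed
#' @return data.frame: year, auc, ci_lo, ci_hi, n_cases, n_controls
#' @export
time_dependent_auc <- function(pi, time, event, eval_years = 1:5,
                               n_boot = 0, seed = 1L) {
  assert_that(length(pi) == length(time) && length(time) == length(event),
              "pi, time, event must have equal length")
  point <- function(pi, time, event, t, G) {
    case <- event == 1 & time <= t
    ctrl <- time > t
    if (sum(case) == 0 || sum(ctrl) == 0) {
      return(c(auc = NA_real_, n_cases = sum(case), n_controls = sum(ctrl)))
    }
    w <- 1 / eval_km(G, time[case], left = TRUE)
    pc <- pi[case]; pq <- pi[ctrl]
    conc <- vapply(seq_along(pc), function(i) {
      sum(pc[i] > pq) + 0.5 * sum(pc[i] == pq)
    }, numeric(1))
    c(auc = sum(w * conc) / (sum(w) * length(pq)),
      n_cases = sum(case), n_controls = sum(ctrl))
  }
  G <- censoring_survfit(time, event)
  est <- t(vapply(eval_years, function(t) point(pi, time, event, t, G),
                  numeric(3)))
  out <- data.frame(year = eval_years, auc = est[, "auc"],
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    n_cases = est[, "n_cases"], n_controls = est[, "n_controls"])
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(length(pi), replace = TRUE)
        Gb <- censoring_survfit(time[idx], event[idx])
        vapply(eval_years, function(t) {
          point(pi[idx], time[idx], event[idx], t, Gb)[["auc"]]
        }, numeric(1))
      })
    })
    boots <- matrix(boots, nrow = length(eval_years))
    out$ci_lo <- apply(boots, 1, quantile, 0.025, na.rm = TRUE)
    out$ci_hi <- apply(boots, 1, quantile, 0.975, na.rm = TRUE)
  }
  out
}

#' Kaplan-Meier curves and log-rank comparison of risk groups
#'
#' @param time,event survival data
#' @param group group labels (>= 2 non-empty groups)
#' @return list: `fit` (survfit), `curves` (data.frame of step points per
#'   group), `chisq`, `p_value`
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  assert_that(nlevels(droplevels(group)) >= 2, "need >= 2 non-empty groups")
  assert_that(all(table(group) >= 1), "empty group")
  d <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  curves <- data.frame(group = sub("^group=", "", strata), time = fit$time,
                       surv = fit$surv, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor)
  list(fit = fit, curves = curves, chisq = unname(sd_$chisq), p_value = p)
}
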