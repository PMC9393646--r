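# Cohort statistics: two-group comparisons, correlation clustering of immune
# features, margin-profile tests and clinicopathologic summary tables.

mw_u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Two-group comparison by the Mann-Whitney U test
#'
#' Two-sided, unpaired. For groups of at most 8 each the p-value is exact,
#' by enumeration of all assignments of the pooled values to the two groups
#' (ties handled naturally by permuting the observed values); for larger
#' groups the normal approximation with tie correction and continuity
#' correction is used. Completely tied data yield p = 1 with a warning.
#'
#' @param values_good,values_poor numeric vectors, each with n >= 3
#' @param exact_max use exact enumeration when both groups are at most this
#'   size (default 8)
#' @return data.frame: n_good, n_poor, median_good, median_poor, U, p_value,
#'   method
#' @export
compare_groups <- function(values_good, values_poor, exact_max = 8) {
  x <- values_good[!is.na(values_good)]
  y <- values_poor[!is.na(values_poor)]
  assert_that(length(x) >= 3 && length(y) >= 3, "each group needs n >= 3")
  n1 <- length(x); n2 <- length(y)
  U <- mw_u_statistic(x, y)
  mu <- n1 * n2 / 2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("all values tied across both groups; p = 1")
    p <- 1; method <- "degenerate"
  } else if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    dev_obs <- abs(U - mu)
    devs <- apply(idx, 2, function(sel) {
      abs(mw_u_statistic(pooled[sel], pooled[-sel]) - mu)
    })
    p <- mean(devs >= dev_obs - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal approximation (tie-corrected)"
  }
  data.frame(n_good = n1, n_poor = n2,
             median_good = median(x), median_poor = median(y),
             U = U, p_value = p, method = method)
}

#' Correlation clustering of immune features
#'
#' Pairwise Spearman correlations across samples, clustered hierarchically
#' with average linkage on the distance 1 - rho. Columns are processed in
#' alphabetical order, so the result does not depend on input column order.
#' Constant features are excluded with a warning.
#'
#' @param features data.frame/matrix, rows = samples, columns = features
#' @param k number of clusters to cut (default 3)
#' @return list: `rho` (correlation matrix, leaf order), `hclust`,
#'   `clusters` (named integer vector), `excluded`
#' @export
correlation_cluster <- function(features, k = 3) {
  features <- as.data.frame(features)
  assert_that(ncol(features) >= 2, "need >= 2 features")
  assert_that(nrow(features) >= 5, "need >= 5 samples")
  features <- features[, order(colnames(features)), drop = FALSE]
  const <- vapply(features, function(v) sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  if (any(const)) {
    warning(sprintf("excluding constant feature(s): %s",
                    paste(names(features)[const], collapse = ", ")))
    features <- features[, !const, drop = FALSE]
  }
  assert_that(ncol(features) >= 2, "need >= 2 non-constant features")
  rho <- cor(features, method = "spearman", use = "pairwise.complete.obs")
  hc <- hclust(as.dist(1 - rho), method = "average")
  clusters <- cutree(hc, k = min(k, ncol(rho)))
  list(rho = rho[hc$order, hc$order], hclust = hc, clusters = clusters,
       excluded = names(const)[const])
}

#' Test margin-band profiles between outcome groups
#'
#' Overall effect: two-way ANOVA of log1p(density) on band, group and their
#' interaction (densities are heavy-tailed; the log1p variance-stabilises).
#' Per-band: Mann-Whitney for two groups, Kruskal-Wallis otherwise. Bands
#' with an empty group cell are skipped and listed.
#'
#' @param profile data.frame with `sample_id`, `band_lo`, `density_mm2`,
#'   `group` (one row per sample x band)
#' @param min_per_cell minimum samples per band-group cell (default 3)
#' @return list: `anova` (effect, df, F, p), `per_band`, `skipped_bands`
#' @export
margin_profile_test <- function(profile, min_per_cell = 3) {
  need <- c("sample_id", "band_lo", "density_mm2", "group")
  missing_cols <- setdiff(need, names(profile))
  assert_that(length(missing_cols) == 0,
              sprintf("profile missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  profile <- profile[!is.na(profile$density_mm2), ]
  bands <- sort(unique(profile$band_lo))
  assert_that(length(bands) >= 2, "need >= 2 bands")
  groups <- sort(unique(profile$group))
  assert_that(length(groups) >= 2, "need >= 2 groups")

  fit <- aov(log1p(density_mm2) ~ factor(band_lo) * factor(group),
             data = profile)
  tab <- summary(fit)[[1]]
  anova_df <- data.frame(
    effect = c("band", "group", "band:group"),
    df = tab[1:3, "Df"], F = tab[1:3, "F value"], p_value = tab[1:3, "Pr(>F)"],
    row.names = NULL)

  per_band <- list(); skipped <- numeric(0)
  for (b in bands) {
    sub <- profile[profile$band_lo == b, ]
    counts <- table(factor(sub$group, levels = groups))
    if (any(counts < min_per_cell)) {
      skipped <- c(skipped, b)
      next
    }
    if (length(groups) == 2) {
      cmp <- compare_groups(sub$density_mm2[sub$group == groups[1]],
                            sub$density_mm2[sub$group == groups[2]])
      per_band[[length(per_band) + 1]] <-
        data.frame(band_lo = b, test = "mann-whitney", p_value = cmp$p_value)
    } else {
      kw <- kruskal.test(sub$density_mm2, factor(sub$group))
      per_band[[length(per_band) + 1]] <-
        data.frame(band_lo = b, test = "kruskal-wallis", p_value = kw$p.value)
    }
  }
  list(anova = anova_df,
       per_band = do.call(rbind, per_band) %||% data.frame(),
       skipped_bands = skipped)
}

#' Format a count as "k/n (pct%)"
#'
#' Percentages are 100 * k / n rounded to 2 decimals, trailing zeros kept.
#'
#' @param k numerator
#' @param n denominator
#' @return character scalar, e.g. `"16/33 (48.48%)"`
#' @export
format_count_pct <- function(k, n) {
  assert_that(n > 0, "denominator must be > 0")
  sprintf("%d/%d (%.2f%%)", k, n, round(100 * k / n, 2))
}

#' Percentage of a count, rounded to 2 decimals
#'
#' @param k numerator
#' @param n denominator
#' @return numeric percentage
#' @export
count_pct <- function(k, n) {
  assert_that(n > 0, "denominator must be > 0")
  round(100 * k / n, 2)
}

#' Cohort summary table
#'
#' Per outcome group and in total: n; median (range) for continuous
#' variables; count/denominator (percentage to 2 decimals) for binary and
#' categorical variables. Unknown (NA) category values are listed as
#' `unknown` and kept in the denominator.
#'
#' @param patients patient records (see [read_patients()])
#' @param continuous names of continuous columns present in `patients`
#' @param categorical names of categorical/binary columns
#' @param group_col grouping column (default `outcome_group`)
#' @return data.frame: variable, level, group, n, denominator, summary
#' @export
cohort_summary <- function(patients,
                           continuous = intersect(
                             c("breslow_mm", "age_years", "mitotic_rate"),
                             names(patients)),
                           categorical = intersect(
                             c("ulceration", "nodal_status", "gender", "site",
                               "stage"), names(patients)),
                           group_col = "outcome_group") {
  assert_that(nrow(patients) > 0, "empty cohort")
  groups <- c(sort(unique(patients[[group_col]])), "total")
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (g in groups) {
    sub <- if (g == "total") patients else patients[patients[[group_col]] == g, ]
    add(variable = "n", level = "", group = g, n = nrow(sub),
        denominator = nrow(patients),
        summary = format_count_pct(nrow(sub), nrow(patients)))
    for (v in continuous) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      add(variable = v, level = "median (range)", group = g,
          n = length(vals), denominator = nrow(sub),
          summary = if (length(vals) == 0) "NA" else
            sprintf("%.2f (%.2f-%.2f)", median(vals), min(vals), max(vals)))
    }
    for (v in categorical) {
      vals <- as.character(sub[[v]])
      vals[is.na(vals)] <- "unknown"
      for (lev in sort(unique(c(vals, "unknown")))) {
        k <- sum(vals == lev)
        if (lev == "unknown" && k == 0) next
        add(variable = v, level = lev, group = g, n = k,
            denominator = nrow(sub),
            summary = format_count_pct(k, nrow(sub)))
      }
    }
  }
  do.call(rbind, rows)
}
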