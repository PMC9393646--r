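# Synthetic tissue, cohort and flow-cytometry generators with known ground
# truth. The generators embody the statistical structure the analysis
# assumes: a tumor disc with a stromal collar and epidermal rim; melanoma
# cells uniform in the tumor; immune phenotypes placed by an inhomogeneous
# Poisson process whose log-density is linear in signed margin distance
# (clipped at the band extent); bimodal lognormal marker intensities; and
# cohorts whose Weibull hazard depends on chosen immune/clinical covariates.

INTENSITY_MODES <- list(neg = c(meanlog = 1, sdlog = 0.3),
                        pos = c(meanlog = 4, sdlog = 0.3))
# antimode of the two lognormal modes, on the intensity scale
DEFAULT_THRESHOLD <- exp(2.5)

PANEL_MARKERS <- list(
  tcell = c("SOX10", "CD3", "CD8", "CD39", "CD103", "PD1"),
  immune = c("SOX10", "CD3", "CD20", "CD56", "CD1a", "Langerin", "HLA_ABC"))

#' Design a synthetic tissue
#'
#' Geometry is a tumor disc of radius `tumor_radius_um` surrounded by a
#' stromal collar and a thin epidermal rim; the margin polyline is the
#' tumor/stroma circle. Densities are cells per mm^2 of the compartment the
#' phenotype occupies. `margin_attraction` gives, per phenotype, the slope
#' of log-density per micrometre of signed margin distance (negative slope =
#' enrichment on the tumor side), clipped at +/- `attraction_extent_um`.
#'
#' @param tumor_radius_um tumor disc radius (default 1000)
#' @param stroma_width_um stromal collar width (default 600)
#' @param epidermis_width_um epidermal rim width (default 120)
#' @param melanoma_count melanoma cells per panel (default 2000)
#' @param mhc1_pos_frac fraction of melanoma positive for Class I MHC
#' @param cd8_density_mm2 CD8+ T cells per mm^2 of tumor+stroma
#' @param cd8_class_probs designed P1..P8 shares (sum to 1)
#' @param t_noncd8_density_mm2,b_density_mm2,nk_density_mm2 immune densities
#' @param langerhans_density_mm2 Langerhans density per mm^2 of epidermis
#' @param other_density_mm2 non-immune nucleated background density
#' @param margin_attraction named log-linear slopes per phenotype
#' @param attraction_extent_um clip for the attraction gradient
#' @param panel_rotation_deg,panel_shift_um,panel_scale true inter-panel
#'   misalignment (similarity transform)
#' @param landmark_noise_um landmark annotation noise s.d.
#' @param n_landmarks landmark count
#' @param seed generator seed
#' @return a `tissue_design` list
#' @export
tissue_design <- function(tumor_radius_um = 1000, stroma_width_um = 600,
                          epidermis_width_um = 120, melanoma_count = 2000,
                          mhc1_pos_frac = 0.2, cd8_density_mm2 = 150,
                          cd8_class_probs = c(P1 = 0.08, P2 = 0.10, P3 = 0.05,
                                              P4 = 0.13, P5 = 0.06, P6 = 0.08,
                                              P7 = 0.15, P8 = 0.35),
                          t_noncd8_density_mm2 = 100, b_density_mm2 = 30,
                          nk_density_mm2 = 20, langerhans_density_mm2 = 300,
                          other_density_mm2 = 1200,
                          margin_attraction = c(B = 0.004, P1 = -0.002,
                                                P2 = -0.002),
                          attraction_extent_um = 200,
                          panel_rotation_deg = 3, panel_shift_um = c(40, -25),
                          panel_scale = 1.01, landmark_noise_um = 2,
                          n_landmarks = 20, seed = 1L) {
  assert_that(tumor_radius_um > 0 && stroma_width_um > 0 &&
                epidermis_width_um > 0, "geometry must be non-degenerate")
  assert_that(melanoma_count >= 0, "melanoma_count must be >= 0")
  assert_that(abs(sum(cd8_class_probs) - 1) < 1e-9 && all(cd8_class_probs >= 0),
              "cd8_class_probs must be nonnegative and sum to 1")
  assert_that(all(names(cd8_class_probs) == paste0("P", 1:8)),
              "cd8_class_probs must be named P1..P8")
  dens <- c(cd8_density_mm2, t_noncd8_density_mm2, b_density_mm2,
            nk_density_mm2, langerhans_density_mm2, other_density_mm2)
  assert_that(all(dens >= 0), "densities must be nonnegative")
  structure(as.list(environment()), class = "tissue_design")
}

# uniform points in a disc / annulus (polar inversion)
runif_annulus <- function(n, r0, r1, center = c(0, 0)) {
  r <- sqrt(runif(n, r0^2, r1^2))
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# inhomogeneous Poisson sample with log-density linear in signed margin
# distance, by thinning a homogeneous proposal over the tumor+stroma disc
sample_margin_gradient <- function(density_mm2, slope, regions, r_outer,
                                   extent) {
  if (density_mm2 <= 0) return(cbind(numeric(0), numeric(0)))
  area_mm2 <- pi * r_outer^2 / 1e6
  lmax <- density_mm2 * exp(abs(slope) * extent)
  assert_that(lmax * area_mm2 <= 1e7,
              "requested density implies more than 1e7 cells")
  n_prop <- stats::rpois(1, lmax * area_mm2)
  pts <- runif_annulus(n_prop, 0, r_outer)
  if (slope == 0) {
    keep <- runif(n_prop) < density_mm2 / lmax
  } else {
    s <- signed_margin_distance(pts[, 1], pts[, 2], regions)
    s[is.na(s)] <- 0
    lam <- density_mm2 * exp(slope * pmin(extent, pmax(-extent, s)))
    keep <- runif(n_prop) < lam / lmax
  }
  pts[keep, , drop = FALSE]
}

draw_intensity <- function(state) {
  m <- ifelse(state, INTENSITY_MODES$pos["meanlog"], INTENSITY_MODES$neg["meanlog"])
  rlnorm(length(state), meanlog = m, sdlog = INTENSITY_MODES$pos["sdlog"])
}

# true marker states per phenotype label, per panel
true_marker_states <- function(label, panel, mhc1 = FALSE) {
  m <- PANEL_MARKERS[[panel]]
  st <- setNames(rep(FALSE, length(m)), m)
  if (label == "melanoma") {
    st["SOX10"] <- TRUE
    if ("HLA_ABC" %in% m) st["HLA_ABC"] <- mhc1
  } else if (grepl("^P[1-8]$", label)) {
    st[c("CD3", "CD8")] <- TRUE
    k <- as.integer(sub("P", "", label)) - 1L
    st["CD39"] <- k %/% 4 == 0
    st["CD103"] <- (k %/% 2) %% 2 == 0
    st["PD1"] <- k %% 2 == 0
  } else if (label == "T_nonCD8") {
    st["CD3"] <- TRUE
  } else if (label == "B") {
    st["CD20"] <- TRUE
  } else if (label == "NK") {
    st["CD56"] <- TRUE
  } else if (label == "langerhans") {
    st[c("CD1a", "Langerin")] <- TRUE
  }
  st
}

#' Generate a synthetic tissue sample
#'
#' Produces per-cell tables for the T-cell and immune panels, the region
#' set, landmark pairs, the true inter-panel transform and per-cell ground
#' truth. Panel "tcell" is the fixed frame; panel "immune" coordinates are
#' reported in their own (misaligned) frame, with landmarks for
#' registration. The emitted threshold table places every marker threshold
#' at the antimode of the intensity mixture.
#'
#' @param design a [tissue_design()]
#' @param sample_id sample identifier
#' @return list: `cells` (both panels), `regions`, `landmarks`,
#'   `true_transform`, `truth` (per-cell phenotype labels), `thresholds`,
#'   `design`
#' @export
generate_tissue <- function(design = tissue_design(), sample_id = "S1") {
  with_seed(substream_seed(design$seed, paste0("tissue_", sample_id)), {
    r_t <- design$tumor_radius_um
    r_s <- r_t + design$stroma_width_um
    r_e <- r_s + design$epidermis_width_um
    margin <- close_ring(disc_polygon(radius = r_t, n = 128))
    regions <- region_set(
      sample_id,
      polygons = list(tumor = list(disc_polygon(radius = r_t, n = 128)),
                      stroma = list(disc_polygon(radius = r_s, n = 160)),
                      epidermis = list(disc_polygon(radius = r_e, n = 160))),
      margin = list(margin), validate = FALSE)
    ext <- design$attraction_extent_um
    attr_of <- function(ph) {
      a <- design$margin_attraction
      if (ph %in% names(a)) unname(a[[ph]]) else 0
    }

    place <- list()
    for (p_i in paste0("P", 1:8)) {
      d_i <- design$cd8_density_mm2 * design$cd8_class_probs[[p_i]]
      place[[p_i]] <- sample_margin_gradient(d_i, attr_of(p_i), regions, r_s, ext)
    }
    place$T_nonCD8 <- sample_margin_gradient(design$t_noncd8_density_mm2,
                                             attr_of("T_nonCD8"), regions, r_s, ext)
    place$B <- sample_margin_gradient(design$b_density_mm2, attr_of("B"),
                                      regions, r_s, ext)
    place$NK <- sample_margin_gradient(design$nk_density_mm2, attr_of("NK"),
                                       regions, r_s, ext)
    # serial sections: each panel sees its own background cells
    place$other_tcell <- sample_margin_gradient(design$other_density_mm2, 0,
                                                regions, r_s, ext)
    place$other_immune <- sample_margin_gradient(design$other_density_mm2, 0,
                                                 regions, r_s, ext)
    lang_n <- stats::rpois(1, design$langerhans_density_mm2 *
                             pi * (r_e^2 - r_s^2) / 1e6)
    place$langerhans <- runif_annulus(lang_n, r_s, r_e)

    tumor_poly <- regions$polygons$tumor[[1]]
    sample_in_tumor <- function(n) {
      # rejection against the polygon: the disc circumscribes the 128-gon
      out <- matrix(numeric(0), 0, 2)
      while (nrow(out) < n) {
        cand <- runif_annulus(2 * (n - nrow(out)) + 16, 0, r_t)
        keep <- points_in_polygon(cand[, 1], cand[, 2], tumor_poly)
        out <- rbind(out, cand[keep, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    }
    build_panel <- function(panel) {
      labels <- character(0); xs <- numeric(0); ys <- numeric(0)
      mel <- sample_in_tumor(design$melanoma_count)
      labels <- c(labels, rep("melanoma", nrow(mel)))
      xs <- c(xs, mel[, 1]); ys <- c(ys, mel[, 2])
      phes <- if (panel == "tcell") {
        c(paste0("P", 1:8), "T_nonCD8", paste0("other_", panel))
      } else {
        c("B", "NK", "langerhans", paste0("other_", panel))
      }
      for (ph in phes) {
        pts <- place[[ph]]
        lab <- sub("^other_.*$", "other", ph)
        labels <- c(labels, rep(lab, nrow(pts)))
        xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
      }
      mhc1 <- rep(FALSE, length(labels))
      mhc1[labels == "melanoma"] <-
        runif(sum(labels == "melanoma")) < design$mhc1_pos_frac
      markers <- PANEL_MARKERS[[panel]]
      intens <- matrix(NA_real_, length(labels), length(markers),
                       dimnames = list(NULL, markers))
      for (i in seq_along(labels)) {
        st <- true_marker_states(labels[i], panel, mhc1[i])
        intens[i, ] <- draw_intensity(st)
      }
      comp <- classify_points(xs, ys, regions)
      list(df = data.frame(sample_id = sample_id, panel_id = panel,
                           cell_id = seq_along(labels), x_um = xs, y_um = ys,
                           compartment = comp, intens,
                           check.names = FALSE),
           truth = data.frame(sample_id = sample_id, panel_id = panel,
                              cell_id = seq_along(labels),
                              true_label = labels, true_mhc1 = mhc1))
    }
    pa <- build_panel("tcell")
    pb <- build_panel("immune")
    # union the marker columns; NA marks markers not on a cell's panel
    all_m <- unique(unlist(PANEL_MARKERS))
    for (m in setdiff(all_m, names(pa$df))) pa$df[[m]] <- NA_real_
    for (m in setdiff(all_m, names(pb$df))) pb$df[[m]] <- NA_real_
    pb$df <- pb$df[, names(pa$df)]

    # true transform maps immune-frame coords onto the tcell frame;
    # the generator stores immune-panel cells in their own frame
    th <- design$panel_rotation_deg * pi / 180
    R <- design$panel_scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    A_true <- cbind(R, design$panel_shift_um)
    true_tf <- structure(list(A = A_true, rmse_um = 0,
                              n_landmarks = design$n_landmarks,
                              type = "similarity"), class = "planar_transform")
    inv_tf <- invert_transform(true_tf)
    pb$df[, c("x_um", "y_um")] <-
      apply_transform(pb$df, inv_tf)[, c("x_um", "y_um")]

    lm_fixed <- runif_annulus(design$n_landmarks, 0, r_s)
    lm_moving <- t(inv_tf$A[, 1:2] %*% t(lm_fixed)) +
      rep(inv_tf$A[, 3], each = design$n_landmarks)
    lm_moving <- lm_moving + matrix(rnorm(2 * design$n_landmarks,
                                          sd = design$landmark_noise_um),
                                    ncol = 2)
    landmarks <- data.frame(x_moving = lm_moving[, 1], y_moving = lm_moving[, 2],
                            x_fixed = lm_fixed[, 1], y_fixed = lm_fixed[, 2])

    cells <- rbind(pa$df, pb$df)
    cells <- validate_cell_table(cells)
    all_markers <- unique(unlist(PANEL_MARKERS))
    thresholds <- data.frame(sample_id = sample_id, marker = all_markers,
                             threshold = DEFAULT_THRESHOLD)
    list(cells = cells, regions = regions, landmarks = landmarks,
         true_transform = true_tf, truth = rbind(pa$truth, pb$truth),
         thresholds = thresholds, design = design)
  })
}

#' Design a synthetic patient cohort
#'
#' Survival times follow a Weibull proportional-hazards model whose
#' log-hazard is a linear combination of (mean-centred) features; censoring
#' is independent with a controllable expected rate. Defaults emulate a
#' 66-patient primary-melanoma discovery cohort classified by the 5-year
#' outcome rule, with protective %P2-of-CD8 and adverse Breslow effects.
#'
#' @param n patients
#' @param beta named log-hazard coefficients per unit of each feature
#' @param weibull_shape,weibull_scale baseline Weibull parameters
#'   (scale in years)
#' @param censoring_rate expected fraction censored, in `[0, 1)`
#' @param n_noise number of standard-normal noise features (`noise1`, ...)
#' @param seed generator seed
#' @return a `cohort_design` list
#' @export
cohort_design <- function(n = 66,
                          beta = c(pct_p2_tumor = -0.05, breslow_mm = 0.35,
                                   ulceration = 0.4, nodal_status = 0.5,
                                   mitotic_rate = 0.05),
                          weibull_shape = 1.2, weibull_scale = 6,
                          censoring_rate = 0.3, n_noise = 0, seed = 1L) {
  assert_that(weibull_shape > 0 && weibull_scale > 0,
              "Weibull shape and scale must be positive")
  assert_that(censoring_rate >= 0 && censoring_rate < 1,
              "censoring_rate must be in [0, 1)")
  assert_that(all(is.finite(beta)), "beta must be finite")
  structure(as.list(environment()), class = "cohort_design")
}

#' Generate a synthetic patient cohort
#'
#' Draws clinicopathologic and immune features, survival times from the
#' designed Weibull proportional-hazards model, and independent censoring
#' calibrated to the designed rate. Ground-truth coefficients are attached.
#'
#' @param design a [cohort_design()]
#' @return list: `patients` (data.frame), `truth` (beta, shape, scale)
#' @export
generate_cohort <- function(design = cohort_design()) {
  with_seed(substream_seed(design$seed, "cohort"), {
    n <- design$n
    feats <- data.frame(
      pct_p2_tumor = pmin(40, rlnorm(n, log(7), 0.8)),
      breslow_mm = pmax(1, rlnorm(n, log(3.2), 0.45)),
      ulceration = rbinom(n, 1, 0.48),
      nodal_status = rbinom(n, 1, 0.4),
      mitotic_rate = rlnorm(n, log(3), 0.6),
      age_years = pmin(95, pmax(25, rnorm(n, 64, 12))))
    if (design$n_noise > 0) {
      for (j in seq_len(design$n_noise)) {
        feats[[paste0("noise", j)]] <- rnorm(n)
      }
    }
    lp <- rep(0, n)
    for (f in names(design$beta)) {
      assert_that(f %in% names(feats), sprintf("beta names unknown feature '%s'", f))
      lp <- lp + design$beta[[f]] * (feats[[f]] - mean(feats[[f]]))
    }
    u <- runif(n)
    t_event <- design$weibull_scale *
      (-log(u) / exp(lp))^(1 / design$weibull_shape)
    if (design$censoring_rate > 0) {
      # exponential censoring; rate solved so the expected censored
      # fraction matches the design, given the realized event times
      f_cens <- function(r) mean(1 - exp(-r * t_event)) - design$censoring_rate
      r <- stats::uniroot(f_cens, c(1e-8, 1e4))$root
      c_time <- rexp(n, r)
    } else {
      c_time <- rep(Inf, n)
    }
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    patients <- data.frame(patient_id = sprintf("PT%03d", seq_len(n)),
                           rfs_years = time, event = event,
                           outcome_group = derive_outcome_group(time, event),
                           feats)
    list(patients = patients,
         truth = list(beta = design$beta, shape = design$weibull_shape,
                      scale = design$weibull_scale,
                      latent_event_years = t_event))
  })
}

#' Design synthetic flow-cytometry fractions
#'
#' Defaults echo the residency structure of primary-melanoma CD8+ T cells:
#' DN/SP/DP shares 29/50/20% (with 1% CD69-CD103+ excluded), CD39
#' positivity rising with residency, and PD-1 near-ubiquitous (93.5%) in
#' the CD39+ tumor-resident (DP) population.
#'
#' @param n_events total events
#' @param frac_dead,frac_nonlymph upstream gate losses
#' @param frac_cd4,frac_cd8 of lymphocytes
#' @param residency named DN/SP/DP/excluded shares of CD8 (sum <= 1)
#' @param cd39_by_residency CD39+ fraction within DN/SP/DP
#' @param pd1_by names `CD39pos_DN` ... `CD39neg_DP`: PD-1+ fractions
#' @param frac_cd69_cd4 CD69+ fraction of CD4
#' @param seed generator seed
#' @return a `flow_design` list
#' @export
flow_design <- function(n_events = 1e5, frac_dead = 0.1, frac_nonlymph = 0.2,
                        frac_cd4 = 0.389, frac_cd8 = 0.443,
                        residency = c(DN = 0.29, SP = 0.50, DP = 0.20,
                                      excluded = 0.01),
                        cd39_by_residency = c(DN = 0.09, SP = 0.11, DP = 0.50),
                        pd1_by = c(CD39pos_DN = 0.44, CD39neg_DN = 0.316,
                                   CD39pos_SP = 0.654, CD39neg_SP = 0.393,
                                   CD39pos_DP = 0.935, CD39neg_DP = 0.688),
                        frac_cd69_cd4 = 0.265, seed = 1L) {
  assert_that(all(residency >= 0) && sum(residency) <= 1 + 1e-9,
              "residency fractions must be nonnegative and sum to <= 1")
  assert_that(frac_cd4 >= 0 && frac_cd8 >= 0 && frac_cd4 + frac_cd8 <= 1,
              "CD4/CD8 fractions must be nonnegative and sum to <= 1")
  assert_that(n_events >= 0, "n_events must be >= 0")
  structure(as.list(environment()), class = "flow_design")
}

#' Generate synthetic flow-cytometry events
#'
#' Event marker intensities are drawn from the bimodal lognormal mixture so
#' that the default [gating_tree()] recovers the designed fractions.
#'
#' @param design a [flow_design()]
#' @return list: `events` (data.frame of intensities), `truth` (per-event
#'   class labels), `design`
#' @export
generate_flow <- function(design = flow_design()) {
  with_seed(substream_seed(design$seed, "flow"), {
    n <- design$n_events
    if (n == 0) {
      ev <- as.data.frame(matrix(numeric(0), 0, length(FLOW_MARKERS),
                                 dimnames = list(NULL, FLOW_MARKERS)))
      return(list(events = ev, truth = data.frame(), design = design))
    }
    dead <- runif(n) < design$frac_dead
    nonlymph <- !dead & (runif(n) < design$frac_nonlymph)
    lymph <- !dead & !nonlymph
    u <- runif(n)
    cd4 <- lymph & u < design$frac_cd4
    cd8 <- lymph & u >= design$frac_cd4 &
      u < design$frac_cd4 + design$frac_cd8
    res <- rep(NA_character_, n)
    res_p <- design$residency / sum(design$residency)
    res[cd8] <- sample(names(res_p), sum(cd8), replace = TRUE, prob = res_p)
    cd39 <- rep(FALSE, n)
    for (r in c("DN", "SP", "DP")) {
      idx <- which(cd8 & res == r)
      cd39[idx] <- runif(length(idx)) < design$cd39_by_residency[[r]]
    }
    pd1 <- rep(FALSE, n)
    for (r in c("DN", "SP", "DP")) {
      for (c39 in c(TRUE, FALSE)) {
        key <- sprintf("%s_%s", if (c39) "CD39pos" else "CD39neg", r)
        idx <- which(cd8 & res == r & cd39 == c39)
        pd1[idx] <- runif(length(idx)) < design$pd1_by[[key]]
      }
    }
    cd69_cd4 <- cd4 & (runif(n) < design$frac_cd69_cd4)
    state <- data.frame(
      viability = dead,
      scatter = lymph,
      CD3 = cd4 | cd8,
      CD4 = cd4,
      CD8 = cd8,
      CD69 = (cd8 & res %in% c("SP", "DP")) | cd69_cd4,
      CD103 = cd8 & res %in% c("DP", "excluded"),
      CD39 = cd39,
      PD1 = pd1)
    events <- as.data.frame(lapply(state, draw_intensity))
    truth <- data.frame(dead = dead, lymphocyte = lymph, cd4 = cd4, cd8 = cd8,
                        residency = res, cd39 = cd39, pd1 = pd1)
    list(events = events, truth = truth, design = design)
  })
}
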