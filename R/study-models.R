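# Declarative builders for every model family in the study design:
# modality-specific and multimodal integrity factors, the three-factor
# cognitive model, unified neurocognitive models (correlation and
# regression variants, optionally with a higher-order MTL volume factor),
# across-time stability models, latent change score models and the
# change -> future-cognition prediction model.
#
# Variable naming convention, shared with assemble_model_data():
#   neural per hemisphere:  <region>_<modality>_<hemi>_tp<k>   (ratio x100)
#   hemisphere-averaged:    <region>_<modality>_tp<k>
#   cognitive:              <task>_tp<k>
#   adjusted volumes:       <roi>_<hemi>
# Entry values double as the generating truth for simulation-based
# recovery tests; they are engine choices anchored to the emulated world
# (modality gains 4/3/2 on the x100 ratio scale; latent integrity variance
# 1; modality-specific variance 0.64), not claims about the source study.

#' Study design constants
#'
#' Regions, per-region modalities (no FSE for the SN-VTA: the FSE sequence
#' covers only the brainstem), the fixed 10-task cognitive map, age groups
#' and timepoints.
#'
#' @return a list of design constants.
#' @export
study_design <- function() {
  list(
    regions = c("lc", "snvta"),
    modalities = list(lc = c("mtplus", "fse", "mtminus"),
                      snvta = c("mtplus", "mtminus")),
    fse_timepoints = 2L,
    task_map = list(wm = c("spatial_u", "letter_u", "number"),
                    em = c("scene", "list", "face", "object"),
                    gf = c("problem", "analog", "letter")),
    groups = c("younger", "older"),
    timepoints = 1:3
  )
}

# anchor truth values on the x100 ratio scale
MOD_GAIN <- c(mtplus = 4, fse = 3, mtminus = 2)
MOD_INTERCEPT <- c(mtplus = 26, fse = 20, mtminus = 6)
SPECIFIC_VAR <- 0.64
RESID_VAR_NEURAL <- 4

check_region_modalities <- function(region, timepoint, design) {
  region <- match.arg(region, design$regions)
  mods <- design$modalities[[region]]
  if (timepoint != design$fse_timepoints) mods <- setdiff(mods, "fse")
  if (!length(mods))
    stop("design error: no modality available for ", region,
         " at timepoint ", timepoint)
  mods
}

# entries for one first-order factor over left/right indicators
hemi_factor_entries <- function(latent, obs_left, obs_right, lv_var,
                                intercept, resid = RESID_VAR_NEURAL) {
  rbind(
    ent("loading", latent, obs_left, free = FALSE, value = 1),
    ent("loading", latent, obs_right, value = 0.95),
    ent("variance", latent, value = lv_var),
    ent("variance", obs_left, value = resid),
    ent("variance", obs_right, value = resid),
    ent("mean", obs_left, value = intercept),
    ent("mean", obs_right, value = intercept)
  )
}

#' Modality-specific integrity factor model
#'
#' One latent integrity factor per available modality, with the left and
#' right hemispheric peak intensity ratios as indicators, and free
#' covariances among the modality-specific factors.
#'
#' @param region `"lc"` or `"snvta"` (the SN-VTA has no FSE factor).
#' @param timepoint imaging timepoint (FSE exists only at TP2).
#' @param design a [study_design()].
#' @param groups group names for a multi-group model, or `NULL`.
#' @return a [sem_spec()].
#' @export
build_modality_factor_model <- function(region, timepoint = 2L,
                                        design = study_design(),
                                        groups = design$groups) {
  mods <- check_region_modalities(region, timepoint, design)
  lat <- paste0(region, "_", mods)
  obs <- as.vector(t(outer(mods, HEMISPHERES, function(m, h)
    sprintf("%s_%s_%s_tp%d", region, m, h, timepoint))))
  e <- NULL
  for (i in seq_along(mods)) {
    m <- mods[i]
    lv_var <- MOD_GAIN[[m]]^2 * (1 + SPECIFIC_VAR)
    e <- rbind(e, hemi_factor_entries(
      lat[i], sprintf("%s_%s_left_tp%d", region, m, timepoint),
      sprintf("%s_%s_right_tp%d", region, m, timepoint),
      lv_var, MOD_INTERCEPT[[m]]))
  }
  for (i in seq_along(mods)) for (j in seq_len(i - 1L))
    e <- rbind(e, ent("covariance", lat[j], lat[i],
                      value = MOD_GAIN[[mods[j]]] * MOD_GAIN[[mods[i]]]))
  sem_spec(obs, lat, e, groups = groups)
}

#' Multimodal integrity factor model
#'
#' Adds a second-order integrity factor capturing the commonalities across
#' modality-specific factors while leaving modality-specific (disturbance)
#' variance in the first-order factors. With only two first-order factors
#' (SN-VTA) both second-order loadings are fixed to 1 for identification.
#'
#' @inheritParams build_modality_factor_model
#' @return a [sem_spec()].
#' @export
build_multimodal_model <- function(region, timepoint = 2L,
                                   design = study_design(),
                                   groups = design$groups) {
  mods <- check_region_modalities(region, timepoint, design)
  if (length(mods) < 2L)
    stop("degenerate-model error: a multimodal factor needs >= 2 modalities")
  spec <- build_modality_factor_model(region, timepoint, design, groups)
  lat <- paste0(region, "_", mods)
  e <- spec$entries
  # drop first-order covariances; the second-order factor explains them
  e <- e[!(e$kind == "covariance" & e$from %in% lat & e$to %in% lat), ]
  # first-order variances become modality-specific disturbances
  e$value[e$kind == "variance" & e$from %in% lat] <-
    MOD_GAIN[mods]^2 * SPECIFIC_VAR
  so <- region
  fix_all <- length(mods) == 2L
  anchor <- MOD_GAIN[[mods[1L]]]
  for (i in seq_along(mods)) {
    fixed <- i == 1L || fix_all
    e <- rbind(e, ent("loading", so, lat[i], free = !fixed,
                      value = if (fixed) 1 else MOD_GAIN[[mods[i]]] / anchor))
  }
  e <- rbind(e, ent("variance", so, value = anchor^2))
  sem_spec(spec$observed, c(spec$latent, so), e, groups = groups)
}

#' Three-factor cognitive model
#'
#' Correlated latent working memory, episodic memory and fluid
#' intelligence factors over the fixed 10-task battery.
#'
#' @param timepoint cognitive timepoint (1-3).
#' @param design a [study_design()].
#' @param groups group names or `NULL`.
#' @param latent_means free latent means in non-reference groups with
#'   intercepts constrained equal across groups (for latent mean
#'   comparisons); default `FALSE` (configural form).
#' @return a [sem_spec()].
#' @export
build_cognitive_model <- function(timepoint = 2L, design = study_design(),
                                  groups = design$groups,
                                  latent_means = FALSE) {
  tm <- design$task_map
  load_truth <- c(spatial_u = 1, letter_u = 1.1, number = 0.9,
                  scene = 1, list = 0.91, face = 0.82, object = 0.91,
                  problem = 1, analog = 1.1, letter = 0.9)
  fac_var <- c(wm = 0.25, em = 0.30, gf = 0.25)
  e <- NULL; obs <- character(0)
  for (f in names(tm)) {
    tasks <- tm[[f]]
    ind <- sprintf("%s_tp%d", tasks, timepoint)
    obs <- c(obs, ind)
    for (k in seq_along(tasks)) {
      fixed <- k == 1L
      e <- rbind(e,
        ent("loading", f, ind[k], free = !fixed,
            value = if (fixed) 1 else load_truth[[tasks[k]]]),
        ent("variance", ind[k], value = 0.2),
        ent("mean", ind[k], value = 0,
            label = if (latent_means) paste0(".eq.i.", ind[k]) else ""))
    }
    e <- rbind(e, ent("variance", f, value = fac_var[[f]]))
  }
  fs <- names(tm)
  for (i in seq_along(fs)) for (j in seq_len(i - 1L))
    e <- rbind(e, ent("covariance", fs[j], fs[i],
                      value = 0.5 * sqrt(fac_var[[fs[i]]] * fac_var[[fs[j]]])))
  spec <- sem_spec(obs, fs, e, groups = groups)
  if (latent_means && !is.null(groups) && length(groups) > 1L)
    spec <- free_latent_means(spec)
  spec
}

#' Unified neurocognitive model
#'
#' Joins the multimodal integrity factors with the cognitive three-factor
#' model. The `correlation` variant frees covariances between neural and
#' cognitive latents; the statistically equivalent `regression` variant
#' draws directed paths from each neural factor (and the MTL factor, if
#' included) to each cognitive factor, testing unique contributions. With
#' `include_mtl`, hemispheric hippocampal and parahippocampal volume
#' factors load on a higher-order MTL factor that joins the predictors.
#'
#' @param variant `"correlation"` or `"regression"`.
#' @param timepoint imaging/cognitive timepoint.
#' @param design a [study_design()].
#' @param regions neural regions to include.
#' @param include_mtl add the higher-order MTL volume factor.
#' @param groups group names or `NULL` (the MTL control analysis uses
#'   older adults only).
#' @return a [sem_spec()].
#' @export
build_neurocognitive_model <- function(variant = c("correlation", "regression"),
                                       timepoint = 2L,
                                       design = study_design(),
                                       regions = design$regions,
                                       include_mtl = FALSE,
                                       groups = design$groups) {
  variant <- match.arg(variant)
  cog <- build_cognitive_model(timepoint, design, groups = groups)
  obs <- cog$observed; lat <- cog$latent; e <- cog$entries
  neural <- character(0)
  for (r in regions) {
    mm <- build_multimodal_model(r, timepoint, design, groups = groups)
    obs <- c(obs, mm$observed); lat <- c(lat, mm$latent)
    e <- rbind(e, mm$entries)
    neural <- c(neural, r)
  }
  if (include_mtl) {
    for (roi in c("hippocampus", "parahippocampus")) {
      f <- paste0(roi, "_f")
      e <- rbind(e, hemi_factor_entries(
        f, paste0(roi, "_left"), paste0(roi, "_right"),
        lv_var = 1.2, intercept = if (roi == "hippocampus") 24 else 14,
        resid = 1))
      obs <- c(obs, paste0(roi, c("_left", "_right"))); lat <- c(lat, f)
      e <- rbind(e, ent("loading", "mtl", f, free = FALSE, value = 1))
      # first-order variances become disturbances
      e$value[e$kind == "variance" & e$from == f] <- 0.4
    }
    e <- rbind(e, ent("variance", "mtl", value = 0.8))
    lat <- c(lat, "mtl")
    neural <- c(neural, "mtl")
  }
  neural_sd <- c(lc = 4, snvta = 4, mtl = 0.9)
  cog_sd <- c(wm = 0.5, em = sqrt(0.3), gf = 0.5)
  truth_r <- matrix(0.1, 3, 3, dimnames = list(c("lc", "snvta", "mtl"),
                                               c("wm", "em", "gf")))
  truth_r["lc", "em"] <- 0.49; truth_r["snvta", "wm"] <- 0.28
  truth_r["mtl", "em"] <- 0.33
  # associations between predictors
  for (i in seq_along(neural)) for (j in seq_len(i - 1L))
    e <- rbind(e, ent("covariance", neural[j], neural[i],
                      value = 0.25 * neural_sd[[neural[j]]] *
                        neural_sd[[neural[i]]]))
  if (variant == "correlation") {
    for (r in neural) for (f in names(cog_sd))
      e <- rbind(e, ent("covariance", r, f,
                        value = truth_r[r, f] * neural_sd[[r]] * cog_sd[[f]]))
  } else {
    for (r in neural) for (f in names(cog_sd))
      e <- rbind(e, ent("regression", r, f,
                        value = 0.5 * truth_r[r, f] * cog_sd[[f]] /
                          neural_sd[[r]]))
  }
  sem_spec(obs, lat, e, groups = groups)
}

#' Across-time stability model
#'
#' Modality-specific factors at TP1 and TP2 (MT+ and MT-; FSE has no TP1
#' data) with cross-time factor covariances as stability estimates and
#' correlated indicator residuals over time. With `multimodal = TRUE`, a
#' second-order integrity factor per timepoint is added and the stability
#' of interest becomes the covariance between the two multimodal factors;
#' modality-specific disturbances keep their own cross-time covariances.
#'
#' @param region `"lc"` or `"snvta"`.
#' @param design a [study_design()].
#' @param multimodal add per-timepoint second-order factors.
#' @param groups group names or `NULL`. The emulated analysis fits a
#'   single model across both age groups for one stability estimate.
#' @return a [sem_spec()].
#' @export
build_stability_model <- function(region, design = study_design(),
                                  multimodal = FALSE, groups = NULL) {
  mods <- intersect(design$modalities[[region]], c("mtplus", "mtminus"))
  if (!length(mods)) stop("design error: no longitudinal modalities")
  e <- NULL; obs <- character(0); lat <- character(0)
  for (tp in 1:2) for (m in mods) {
    l <- sprintf("%s_%s_t%d", region, m, tp)
    lv_var <- if (multimodal) MOD_GAIN[[m]]^2 * SPECIFIC_VAR
              else MOD_GAIN[[m]]^2 * (1 + SPECIFIC_VAR)
    e <- rbind(e, hemi_factor_entries(
      l, sprintf("%s_%s_left_tp%d", region, m, tp),
      sprintf("%s_%s_right_tp%d", region, m, tp),
      lv_var, MOD_INTERCEPT[[m]]))
    obs <- c(obs, sprintf("%s_%s_%s_tp%d", region, m, HEMISPHERES, tp))
    lat <- c(lat, l)
  }
  # correlated indicator residuals over time
  for (m in mods) for (h in HEMISPHERES)
    e <- rbind(e, ent("covariance",
                      sprintf("%s_%s_%s_tp1", region, m, h),
                      sprintf("%s_%s_%s_tp2", region, m, h), value = 0.5))
  if (!multimodal) {
    # within-time cross-modality and cross-time covariances
    pairs <- expand.grid(a = seq_along(lat), b = seq_along(lat))
    pairs <- pairs[pairs$a < pairs$b, ]
    for (k in seq_len(nrow(pairs))) {
      la <- lat[pairs$a[k]]; lb <- lat[pairs$b[k]]
      ma <- sub("_t[12]$", "", la); mb <- sub("_t[12]$", "", lb)
      same_mod <- ma == mb
      ga <- MOD_GAIN[[sub(paste0(region, "_"), "", ma)]]
      gb <- MOD_GAIN[[sub(paste0(region, "_"), "", mb)]]
      e <- rbind(e, ent("covariance", la, lb,
                        value = (if (same_mod) 0.9 else 0.85) * ga * gb))
    }
  } else {
    for (tp in 1:2) {
      so <- sprintf("%s_mm_t%d", region, tp)
      for (m in mods)
        e <- rbind(e, ent("loading", so, sprintf("%s_%s_t%d", region, m, tp),
                          free = FALSE, value = 1))
      e <- rbind(e, ent("variance", so, value = MOD_GAIN[[mods[1L]]]^2))
      lat <- c(lat, so)
    }
    e <- rbind(e, ent("covariance", sprintf("%s_mm_t1", region),
                      sprintf("%s_mm_t2", region),
                      value = 0.9 * MOD_GAIN[[mods[1L]]]^2))
    # modality-specific disturbance stability
    for (m in mods)
      e <- rbind(e, ent("covariance", sprintf("%s_%s_t1", region, m),
                        sprintf("%s_%s_t2", region, m),
                        value = 0.1 * MOD_GAIN[[m]]^2))
  }
  sem_spec(obs, lat, e, groups = groups)
}

#' Latent change score model
#'
#' For a neural region: hemisphere-averaged MT+ and MT- indicators at TP1
#' and TP2, one baseline and one change (slope) factor per modality with
#' occasion residuals constrained equal within modality, and a
#' higher-order multimodal slope factor (loadings fixed to 1) capturing
#' change shared across sequences. For cognitive tasks: one observed-score
#' change model per task (occasion residuals fixed to 0, the
#' single-indicator identification), with free covariances among baseline
#' and among slope factors when several tasks are given.
#'
#' @param unit a region name (`"lc"`/`"snvta"`) or a character vector of
#'   task names.
#' @param design a [study_design()].
#' @param timepoints the two occasions (cognitive change uses TP1-TP3).
#' @param groups group names or `NULL` (longitudinal change models in the
#'   emulated study are single-group, older adults).
#' @return a [sem_spec()].
#' @export
build_latent_change_model <- function(unit, design = study_design(),
                                      timepoints = NULL, groups = NULL) {
  if (length(unit) == 1L && unit %in% design$regions) {
    tps <- if (is.null(timepoints)) c(1L, 2L) else timepoints
    if (length(tps) != 2L) stop("design error: change needs two timepoints")
    mods <- intersect(design$modalities[[unit]], c("mtplus", "mtminus"))
    e <- NULL; obs <- character(0); lat <- character(0)
    for (m in mods) {
      y1 <- sprintf("%s_%s_tp%d", unit, m, tps[1])
      y2 <- sprintf("%s_%s_tp%d", unit, m, tps[2])
      b <- sprintf("%s_%s_base", unit, m)
      d <- sprintf("%s_%s_slope", unit, m)
      g <- MOD_GAIN[[m]]
      e <- rbind(e,
        ent("loading", b, y1, free = FALSE, value = 1),
        ent("loading", b, y2, free = FALSE, value = 1),
        ent("loading", d, y2, free = FALSE, value = 1),
        ent("variance", b, value = g^2 * (1 + SPECIFIC_VAR)),
        ent("variance", d, value = g^2 * 0.08),
        ent("variance", y1, value = RESID_VAR_NEURAL / 2,
            label = paste0(".eq.res.", unit, "_", m)),
        ent("variance", y2, value = RESID_VAR_NEURAL / 2,
            label = paste0(".eq.res.", unit, "_", m)),
        ent("mean", y1, free = FALSE, value = 0),
        ent("mean", y2, free = FALSE, value = 0),
        ent("mean", b, value = MOD_INTERCEPT[[m]]),
        ent("covariance", b, d, value = -0.1 * g^2))
      obs <- c(obs, y1, y2); lat <- c(lat, b, d)
    }
    D <- paste0(unit, "_slope_mm")
    for (m in mods)
      e <- rbind(e, ent("loading", D, sprintf("%s_%s_slope", unit, m),
                        free = FALSE, value = 1))
    e <- rbind(e,
      ent("variance", D, value = prod(MOD_GAIN[mods]) * 0.15),
      ent("mean", D, value = -0.5),
      ent("covariance", sprintf("%s_%s_base", unit, mods[1]),
          sprintf("%s_%s_base", unit, mods[2]),
          value = 0.85 * prod(MOD_GAIN[mods])))
    return(sem_spec(obs, c(lat, D), e, groups = groups))
  }
  # cognitive task(s): observed-score change (residuals fixed to 0)
  tps <- if (is.null(timepoints)) c(1L, 3L) else timepoints
  if (length(tps) != 2L) stop("design error: change needs two timepoints")
  tasks <- unit
  known <- unlist(design$task_map, use.names = FALSE)
  bad <- setdiff(tasks, known)
  if (length(bad)) stop("design error: unknown task(s): ",
                        paste(bad, collapse = ", "))
  e <- NULL; obs <- character(0); lat <- character(0)
  for (tk in tasks) {
    y1 <- sprintf("%s_tp%d", tk, tps[1]); y2 <- sprintf("%s_tp%d", tk, tps[2])
    b <- paste0(tk, "_base"); d <- paste0(tk, "_slope")
    e <- rbind(e,
      ent("loading", b, y1, free = FALSE, value = 1),
      ent("loading", b, y2, free = FALSE, value = 1),
      ent("loading", d, y2, free = FALSE, value = 1),
      ent("variance", b, value = 0.45),
      ent("variance", d, value = 0.12),
      ent("variance", y1, free = FALSE, value = 0),
      ent("variance", y2, free = FALSE, value = 0),
      ent("mean", y1, free = FALSE, value = 0),
      ent("mean", y2, free = FALSE, value = 0),
      ent("mean", b, value = 0),
      ent("mean", d, value = -0.2),
      ent("covariance", b, d, value = -0.05))
    obs <- c(obs, y1, y2); lat <- c(lat, b, d)
  }
  if (length(tasks) > 1L) {
    for (i in seq_along(tasks)) for (j in seq_len(i - 1L)) {
      e <- rbind(e,
        ent("covariance", paste0(tasks[j], "_base"),
            paste0(tasks[i], "_base"), value = 0.2),
        ent("covariance", paste0(tasks[j], "_slope"),
            paste0(tasks[i], "_slope"), value = 0.03))
    }
  }
  sem_spec(obs, lat, e, groups = groups)
}

#' Neural-change prediction model
#'
#' Single-group (older adults) model in which the multimodal neural change
#' factor (TP1-TP2) and chronological age jointly predict the latent
#' cognitive factor at TP3 (episodic memory for the LC, working memory for
#' the SN-VTA), and age also predicts the change factor (more negative
#' change with increasing age).
#'
#' @param region `"lc"` or `"snvta"`.
#' @param domain `"em"` or `"wm"`.
#' @param design a [study_design()].
#' @return a [sem_spec()] (single group).
#' @export
build_prediction_model <- function(region, domain = c("em", "wm"),
                                   design = study_design()) {
  domain <- match.arg(domain)
  lcs <- build_latent_change_model(region, design)
  e <- lcs$entries; obs <- lcs$observed; lat <- lcs$latent
  D <- paste0(region, "_slope_mm")
  tasks <- design$task_map[[domain]]
  ind <- sprintf("%s_tp3", tasks)
  load_truth <- c(1, 1.1, 0.9, 0.95)[seq_along(tasks)]
  for (k in seq_along(tasks)) {
    fixed <- k == 1L
    e <- rbind(e,
      ent("loading", domain, ind[k], free = !fixed,
          value = if (fixed) 1 else load_truth[k]),
      ent("variance", ind[k], value = 0.2),
      ent("mean", ind[k], value = 0))
  }
  e <- rbind(e,
    ent("variance", domain, value = 0.22),        # disturbance
    ent("variance", "age", value = 16),
    ent("mean", "age", value = 0),
    ent("regression", "age", D, value = -0.05),
    ent("regression", D, domain, value = 0.11),
    ent("regression", "age", domain, value = -0.02))
  mods <- intersect(design$modalities[[region]], c("mtplus", "mtminus"))
  for (m in mods)
    e <- rbind(e, ent("covariance", "age",
                      sprintf("%s_%s_base", region, m), value = -1))
  sem_spec(c(obs, ind, "age"), c(lat, domain), e, groups = NULL)
}

#' Restrict a modeling table to older adults
#'
#' The longitudinal change and prediction models are single-group models of
#' the older cohort; younger-adult rows are excluded with a logged notice.
#'
#' @param data wide modeling table with a `group` column.
#' @param group_col name of the group column.
#' @return the older-adult subset.
#' @export
older_only <- function(data, group_col = "group") {
  if (!group_col %in% names(data)) return(data)
  n_young <- sum(data[[group_col]] != "older")
  if (n_young > 0)
    message("excluding ", n_young,
            " younger-adult row(s) from a single-group older-adult model")
  data[data[[group_col]] == "older", , drop = FALSE]
}

#' Reported model comparisons for a neurocognitive correlation model
#'
#' Builds and tests the constrained variants used in the reported results:
#' per region, (a) all three neural-cognitive associations fixed to zero
#' (delta df = 3), (b) associations constrained equal across cognitive
#' domains (delta df = 2) and (c) equality of the two regions' association
#' with one domain (delta df = 1), each evaluated with a likelihood-ratio
#' test against the free model.
#'
#' @param spec a correlation-variant [build_neurocognitive_model()] spec.
#' @param data data frame holding the model variables.
#' @param group group column/vector for multi-group specs.
#' @param domain domain for the across-region comparison.
#' @param options passed to [fit_model()].
#' @return a `catena_report`: comparison table and the underlying fits.
#' @export
run_reported_comparisons <- function(spec, data, group = NULL,
                                     domain = "em", options = list()) {
  design <- study_design()
  cogs <- names(design$task_map)
  regions <- intersect(design$regions, spec$latent)
  fit_free <- fit_model(spec, data, group, options)
  assert_converged(fit_free, "free neurocognitive model")

  is_assoc <- function(e, r, f) e$kind == "covariance" & e$from == r & e$to == f
  results <- list(); fits <- list(free = fit_free)
  for (r in regions) {
    zero <- spec
    for (f in cogs) {
      k <- is_assoc(zero$entries, r, f)
      zero$entries$free[k] <- FALSE; zero$entries$value[k] <- 0
      zero$entries$label[k] <- ""
    }
    fz <- fit_model(zero, data, group, options)
    results[[paste0(r, "_all_zero")]] <- likelihood_ratio_test(fit_free, fz)
    fits[[paste0(r, "_all_zero")]] <- fz

    eqd <- spec
    for (f in cogs) {
      k <- is_assoc(eqd$entries, r, f)
      eqd$entries$label[k] <- paste0(".eq.assoc.", r)
    }
    fe <- fit_model(eqd, data, group, options)
    results[[paste0(r, "_equal_domains")]] <- likelihood_ratio_test(fit_free, fe)
    fits[[paste0(r, "_equal_domains")]] <- fe
  }
  if (length(regions) == 2L) {
    eqr <- spec
    for (r in regions) {
      k <- is_assoc(eqr$entries, r, domain)
      eqr$entries$label[k] <- paste0(".eq.region.", domain)
    }
    fr <- fit_model(eqr, data, group, options)
    results[[paste0("regions_equal_", domain)]] <-
      likelihood_ratio_test(fit_free, fr)
    fits[[paste0("regions_equal_", domain)]] <- fr
  }
  tab <- data.frame(
    comparison = names(results),
    delta_chi2 = vapply(results, `[[`, 0, "delta_chi2"),
    delta_df = as.integer(vapply(results, `[[`, 0, "delta_df")),
    p = vapply(results, `[[`, 0, "p"),
    verdict = vapply(results, `[[`, "", "verdict"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, lrts = results, fits = fits),
            class = "catena_report")
}

#' @export
print.catena_report <- function(x, ...) {
  t <- x$table
  t$delta_chi2 <- sprintf("%.2f", t$delta_chi2)
  t$p <- ifelse(x$table$p < 0.001, "< 0.001", sprintf("%.3f", x$table$p))
  print(t, row.names = FALSE)
  invisible(x)
}

#' Spatial-position control report
#'
#' Correlates within-person change in extracted ratios with the change in
#' the axial slice index the peak was sampled from, per region and
#' modality. A strong association would indicate that apparent integrity
#' change merely tracks a shift in sampling position.
#'
#' @param ratio_table raw ratio table from [extract_cohort_ratios()]
#'   (needs `peak_slice` and both timepoints).
#' @return data frame: region, modality, n, correlation.
#' @export
position_change_report <- function(ratio_table) {
  t1 <- ratio_table[ratio_table$timepoint == 1L, ]
  t2 <- ratio_table[ratio_table$timepoint == 2L, ]
  key <- c("participant", "region", "modality", "hemisphere")
  m <- merge(t1, t2, by = key, suffixes = c("_tp1", "_tp2"))
  m$dvalue <- m$value_tp2 - m$value_tp1
  m$dslice <- m$peak_slice_tp2 - m$peak_slice_tp1
  out <- do.call(rbind, lapply(split(m, m[c("region", "modality")]), function(s) {
    if (nrow(s) < 3L || sd(s$dslice) == 0 || sd(s$dvalue) == 0)
      return(data.frame(region = s$region[1], modality = s$modality[1],
                        n = nrow(s), correlation = NA_real_))
    data.frame(region = s$region[1], modality = s$modality[1], n = nrow(s),
               correlation = cor(s$dvalue, s$dslice))
  }))
  rownames(out) <- NULL
  out
}
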