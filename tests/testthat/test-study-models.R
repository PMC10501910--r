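test_that("modality factor models match independent hand counts", {
  # LC at TP2, per group: 3 free loadings (left fixed) + 6 residuals +
  # 3 latent variances + 3 covariances + 6 intercepts = 21
  s <- build_modality_factor_model("lc", 2)
  expect_equal(length(s$observed), 6)
  expect_equal(length(s$latent), 3)
  expect_equal(nrow(free_params(s)), 2 * 21)
  # single group
  s1 <- build_modality_factor_model("lc", 2, groups = NULL)
  expect_equal(nrow(free_params(s1)), 21)
  # SN-VTA has no FSE: 2 latents, 1 covariance
  sv <- build_modality_factor_model("snvta", 2, groups = NULL)
  expect_equal(length(sv$latent), 2)
  expect_equal(sum(sv$entries$kind == "covariance"), 1)
  expect_false(any(grepl("fse", sv$observed)))
  # FSE never exists at TP1
  s_tp1 <- build_modality_factor_model("lc", 1, groups = NULL)
  expect_false(any(grepl("fse", s_tp1$observed)))
})

test_that("multimodal models add one second-order factor per region", {
  s <- build_multimodal_model("lc", 2, groups = NULL)
  expect_true("lc" %in% s$latent)
  so_loads <- s$entries[s$entries$kind == "loading" & s$entries$from == "lc", ]
  expect_equal(nrow(so_loads), 3)
  expect_equal(sum(!so_loads$free), 1)  # first fixed, two free
  # with two first-order factors both loadings are fixed for identification
  sv <- build_multimodal_model("snvta", 2, groups = NULL)
  so2 <- sv$entries[sv$entries$kind == "loading" & sv$entries$from == "snvta", ]
  expect_true(all(!so2$free))
  # second-order factors need at least two modalities
  design <- study_design()
  design$modalities$lc <- "mtplus"
  expect_error(build_multimodal_model("lc", 2, design, groups = NULL),
               "degenerate")
})

test_that("second-order loadings are recovered from simulated data", {
  s <- build_multimodal_model("lc", 2, groups = NULL)
  truth <- setNames(free_params(s)$value, free_params(s)$label)
  d <- simulate_spec_data(s, 1000, seed = 101)
  f <- fit_model(s, d, options = sim_options)
  expect_true(f$converged)
  lds <- grep("^loading.lc\\.", names(truth), value = TRUE)
  expect_lt(max(abs(f$theta[lds] - truth[lds])), 0.1)
  # zero cross-modality correlation in truth: second-order variance ~ 0
  s0 <- set_entry_value(s, "variance", "lc", "lc", 1e-8)
  d0 <- simulate_spec_data(s0, 1000, seed = 102)
  f0 <- fit_model(s, d0, options = sim_options)
  expect_lt(f0$theta["variance.lc.lc.all"] /
              truth["variance.lc.lc.all"], 0.1)
})

test_that("the cognitive model has the fixed task structure", {
  s <- build_cognitive_model(2, groups = NULL)
  expect_equal(length(s$observed), 10)
  expect_setequal(s$latent, c("wm", "em", "gf"))
  expect_equal(sum(s$entries$kind == "covariance"), 3)
  tm <- study_design()$task_map
  for (f in names(tm))
    expect_setequal(
      s$entries$to[s$entries$kind == "loading" & s$entries$from == f],
      sprintf("%s_tp2", tm[[f]]))
})

test_that("latent group mean differences are recovered in direction", {
  s <- build_cognitive_model(2, groups = c("younger", "older"),
                             latent_means = TRUE)
  # truth: older latent means below younger on all three factors
  k <- s$entries$kind == "mean" & s$entries$from %in% s$latent &
    s$entries$group == "older"
  expect_equal(sum(k), 3)
  s$entries$value[k] <- -2
  d <- simulate_spec_data(s, 400, seed = 103)
  f <- fit_model(s, d, group = "group", options = sim_options)
  means <- f$theta[grep("^mean\\.(wm|em|gf)", names(f$theta))]
  expect_true(all(means < 0))
  expect_lt(max(abs(means - (-2))), 0.4)
})

test_that("correlation and regression neurocognitive variants are equivalent", {
  sc <- build_neurocognitive_model("correlation", groups = NULL)
  sr <- build_neurocognitive_model("regression", groups = NULL)
  expect_error(build_neurocognitive_model("ridge"), "arg")
  d <- simulate_spec_data(sc, 250, seed = 104)
  f1 <- fit_model(sc, d, options = sim_options)
  f2 <- fit_model(sr, d, options = sim_options)
  expect_equal(f1$df, f2$df)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
})

test_that("regression variant recovers differentiated associations", {
  sr <- build_neurocognitive_model("regression", groups = NULL)
  fp <- free_params(sr)
  truth <- setNames(fp$value, fp$label)
  d <- simulate_spec_data(sr, 1000, seed = 105)
  f <- fit_model(sr, d, options = sim_options)
  st <- standardize(f)
  b <- st[st$kind == "regression", ]
  b_lc_em <- b$std[b$from == "lc" & b$to == "em"]
  b_sn_wm <- b$std[b$from == "snvta" & b$to == "wm"]
  b_lc_gf <- b$std[b$from == "lc" & b$to == "gf"]
  # the emulated pattern: LC->EM and SN-VTA->WM dominate their rows
  expect_gt(b_lc_em, b_lc_gf)
  expect_gt(b_lc_em, 0.1)
  expect_gt(b_sn_wm, 0.05)
})

test_that("MTL control model builds and keeps likelihood equivalence", {
  sc <- build_neurocognitive_model("correlation", include_mtl = TRUE,
                                   groups = NULL)
  sr <- build_neurocognitive_model("regression", include_mtl = TRUE,
                                   groups = NULL)
  expect_true("mtl" %in% sc$latent)
  expect_true(all(c("hippocampus_left", "parahippocampus_right") %in%
                  sc$observed))
  d <- simulate_spec_data(sc, 250, seed = 106)
  f1 <- fit_model(sc, d, options = sim_options)
  f2 <- fit_model(sr, d, options = sim_options)
  expect_equal(f1$df, f2$df)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-5)
})

test_that("stability models expose cross-time covariances", {
  s <- build_stability_model("lc")
  expect_equal(length(s$observed), 8)
  expect_equal(length(s$latent), 4)
  # cross-time residual covariances for matching indicators
  res_cov <- s$entries[s$entries$kind == "covariance" &
                       s$entries$from %in% s$observed, ]
  expect_equal(nrow(res_cov), 4)
  sm <- build_stability_model("lc", multimodal = TRUE)
  expect_true(all(c("lc_mm_t1", "lc_mm_t2") %in% sm$latent))
  expect_error(build_stability_model("lc", design = within(study_design(), {
    modalities$lc <- "fse"
  })), "design error")
})

test_that("noiseless latent change equals the observed mean difference", {
  s <- build_latent_change_model("scene", timepoints = c(1, 3))
  set.seed(107)
  d <- data.frame(scene_tp1 = rnorm(80), scene_tp3 = rnorm(80, -0.4))
  f <- fit_model(s, d, options = sim_options)
  expect_lt(abs(f$theta["mean.scene_slope.scene_slope.all"] -
                mean(d$scene_tp3 - d$scene_tp1)), 1e-6)
  expect_lt(abs(f$theta["mean.scene_base.scene_base.all"] -
                mean(d$scene_tp1)), 1e-6)
})

test_that("neural change models recover their variance structure", {
  s <- build_latent_change_model("lc")
  truth <- setNames(free_params(s)$value, free_params(s)$label)
  d <- simulate_spec_data(s, 1000, seed = 108)
  f <- fit_model(s, d, options = sim_options)
  dv <- "variance.lc_slope_mm.lc_slope_mm.all"
  expect_lt(abs(f$theta[dv] - truth[dv]) / truth[dv], 0.5)
  # single replicate: allow ~3 standard errors (the acceptance suite
  # checks bias over 50 replicates at the 0.1 tolerance)
  expect_lt(abs(f$theta["mean.lc_slope_mm.lc_slope_mm.all"] -
                truth["mean.lc_slope_mm.lc_slope_mm.all"]), 0.2)
  # zero shared slope variance in truth collapses the higher-order slope
  s0 <- set_entry_value(s, "variance", "lc_slope_mm", "lc_slope_mm", 1e-8)
  d0 <- simulate_spec_data(s0, 1000, seed = 109)
  f0 <- fit_model(s, d0, options = sim_options)
  expect_lt(unname(f0$theta[dv]), 0.15)
  # unknown task and single-timepoint errors
  expect_error(build_latent_change_model("no_such_task"), "unknown task")
  expect_error(build_latent_change_model("lc", timepoints = 2),
               "two timepoints")
})

test_that("multi-task change models carry slope covariances", {
  s <- build_latent_change_model(c("scene", "list"), timepoints = c(1, 3))
  sl <- s$entries[s$entries$kind == "covariance" &
                  grepl("_slope$", s$entries$from) &
                  grepl("_slope$", s$entries$to), ]
  expect_equal(nrow(sl), 1)
})

test_that("the prediction model encodes age and change paths", {
  s <- build_prediction_model("lc", "em")
  regs <- s$entries[s$entries$kind == "regression", ]
  expect_setequal(paste(regs$from, regs$to),
                  c("age lc_slope_mm", "lc_slope_mm em", "age em"))
  expect_true("age" %in% s$observed)
  expect_equal(sum(grepl("_tp3$", s$observed)), 4)
  sw <- build_prediction_model("snvta", "wm")
  expect_equal(sum(grepl("_tp3$", sw$observed)), 3)
  # younger rows are excluded with a notice
  d <- data.frame(group = c("younger", "older"), x = 1:2)
  expect_message(out <- older_only(d), "excluding 1")
  expect_equal(nrow(out), 1)
})

test_that("prediction paths are recovered with the right signs", {
  s <- build_prediction_model("lc", "em")
  truth <- setNames(free_params(s)$value, free_params(s)$label)
  d <- simulate_spec_data(s, 1000, seed = 110)
  f <- fit_model(s, d, options = sim_options)
  r1 <- "regression.age.lc_slope_mm.all"
  r2 <- "regression.lc_slope_mm.em.all"
  expect_lt(abs(f$theta[r1] - truth[r1]), 0.1)
  expect_lt(abs(f$theta[r2] - truth[r2]), 0.1)
  st <- standardize(f)
  expect_lt(st$std[st$label == r1], 0)  # more negative change with age
  expect_gt(st$std[st$label == r2], 0)  # change predicts future memory
})

test_that("reported comparisons bookkeeping matches the free model", {
  sc <- build_neurocognitive_model("correlation", groups = NULL)
  d <- simulate_spec_data(sc, 300, seed = 111)
  rep <- run_reported_comparisons(sc, d, options = sim_options)
  expect_setequal(rep$table$comparison,
                  c("lc_all_zero", "lc_equal_domains", "snvta_all_zero",
                    "snvta_equal_domains", "regions_equal_em"))
  expect_equal(rep$table$delta_df[rep$table$comparison == "lc_all_zero"], 3L)
  expect_equal(rep$table$delta_df[rep$table$comparison ==
                                  "lc_equal_domains"], 2L)
  expect_equal(rep$table$delta_df[rep$table$comparison ==
                                  "regions_equal_em"], 1L)
  # each constrained spec has exactly delta-df fewer free parameters
  expect_equal(rep$fits$lc_all_zero$npar, rep$fits$free$npar - 3L)
  expect_equal(rep$fits$lc_equal_domains$npar, rep$fits$free$npar - 2L)
  # with LC->EM = 0.49 in truth, the LC all-zero constraint must be rejected
  expect_lt(rep$table$p[rep$table$comparison == "lc_all_zero"], 0.05)
})

test_that("position-change control report runs on extracted tables", {
  cfg <- tiny_config(n_young = 3, n_old = 3)
  co <- simulate_cohort(cfg, apply_missingness = FALSE)
  raw <- extract_cohort_ratios(co, "lc")
  out <- position_change_report(raw)
  expect_true(all(c("region", "modality", "n", "correlation") %in% names(out)))
  expect_true(all(out$n > 0))
})
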