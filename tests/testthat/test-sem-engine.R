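test_that("implied moments match closed-form path tracing", {
  s <- sem_spec("y", "f", rbind(
    ent("loading", "f", "y", free = FALSE, value = 1),
    ent("variance", "f", value = 1),
    ent("variance", "y", value = 1),
    ent("mean", "y", value = 0)))
  m <- implied_moments(s)$all
  expect_equal(as.numeric(m$cov), 2)
  expect_equal(as.numeric(m$mean), 0)

  s2 <- two_factor_spec(0.37)
  m2 <- implied_moments(s2)$all
  expect_equal(m2$cov["y1", "y3"], 0.37, ignore_attr = TRUE)
  expect_equal(m2$cov["y2", "y4"], 0.37, ignore_attr = TRUE)
  expect_equal(m2$cov["y1", "y2"], 1.0, ignore_attr = TRUE)
  expect_equal(m2$mean, c(y1 = 0.5, y2 = -0.2, y3 = 0, y4 = 1))
})

test_that("implied moments agree with a large Monte-Carlo simulation", {
  # a 6-variable spec mixing loadings, a regression and latent covariance
  s <- sem_spec(
    observed = c("y1", "y2", "y3", "y4", "x"), latent = c("f1", "f2"),
    entries = rbind(
      ent("loading", "f1", "y1", free = FALSE, value = 1),
      ent("loading", "f1", "y2", value = 0.7),
      ent("loading", "f2", "y3", free = FALSE, value = 1),
      ent("loading", "f2", "y4", value = 1.3),
      ent("regression", "x", "f2", value = 0.5),
      ent("covariance", "f1", "f2", value = 0.3),
      ent("variance", "f1", value = 1), ent("variance", "f2", value = 0.6),
      ent("variance", "x", value = 1.5),
      ent("variance", "y1", value = 0.4), ent("variance", "y2", value = 0.4),
      ent("variance", "y3", value = 0.4), ent("variance", "y4", value = 0.4),
      ent("mean", "x", value = 1),
      ent("mean", "y1", value = 0.2), ent("mean", "y2", value = 0),
      ent("mean", "y3", value = -0.5), ent("mean", "y4", value = 0)))
  mom <- implied_moments(s)$all
  d <- simulate_spec_data(s, 1e6, seed = 31)
  emp_cov <- cov(d) * (1 - 1 / 1e6)
  expect_lt(max(abs(emp_cov - mom$cov)), 0.02)
  expect_lt(max(abs(colMeans(d) - mom$mean)), 0.01)
})

test_that("specification invariants are enforced", {
  base <- two_factor_spec()
  # duplicate entry
  expect_error(sem_spec(base$observed, base$latent,
                        rbind(base$entries, ent("variance", "y1", value = 1))),
               "duplicate entries")
  # unknown variable
  expect_error(sem_spec(base$observed, base$latent,
                        rbind(base$entries, ent("variance", "zz", value = 1))),
               "unknown variables")
  # missing scale constraint
  e <- base$entries
  e$free[e$kind == "loading" & e$to == "y1"] <- TRUE
  e$free[e$kind == "loading" & e$to == "y2"] <- TRUE
  expect_error(sem_spec(base$observed, base$latent, e), "identification")
  # cyclic regressions
  expect_error(sem_spec(c("a", "b"), character(0), rbind(
    ent("regression", "a", "b", value = 0.5),
    ent("regression", "b", "a", value = 0.5),
    ent("variance", "a", value = 1), ent("variance", "b", value = 1),
    ent("mean", "a", value = 0), ent("mean", "b", value = 0))),
    "cyclic")
})

test_that("spec JSON serialization round-trips", {
  s <- build_cognitive_model(groups = c("younger", "older"))
  p <- file.path(tempdir(), "spec.json")
  write_spec_json(s, p)
  s2 <- read_spec_json(p)
  expect_equal(s2$observed, s$observed)
  expect_equal(s2$latent, s$latent)
  expect_equal(s2$groups, s$groups)
  expect_equal(free_params(s2), free_params(s))
})

test_that("FIML equals complete-data ML and the casewise dual route", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 300, seed = 5)
  # closed-form complete-data multivariate normal log-likelihood
  mom <- implied_moments(s)$all
  Y <- as.matrix(d)
  Si <- solve(mom$cov)
  ld <- as.numeric(determinant(mom$cov)$modulus)
  llc <- sum(apply(Y, 1, function(y) {
    dif <- y - mom$mean
    -0.5 * (4 * log(2 * pi) + ld + as.numeric(t(dif) %*% Si %*% dif))
  }))
  expect_equal(fiml_loglik(s, NULL, d), llc, tolerance = 1e-8)

  # 30% MCAR: pattern-grouped equals the naive casewise loop
  set.seed(6)
  d2 <- d
  for (j in seq_len(ncol(d2))) d2[runif(nrow(d2)) < 0.3, j] <- NA
  d2 <- d2[rowSums(!is.na(d2)) > 0, ]
  expect_equal(fiml_loglik(s, NULL, d2),
               fiml_loglik(s, NULL, d2, method = "casewise"),
               tolerance = 1e-10)

  # a case with one observed variable contributes a univariate density
  d3 <- d[1, , drop = FALSE]
  d3[1, 2:4] <- NA
  mom1 <- implied_moments(s)$all
  expect_equal(fiml_loglik(s, NULL, d3),
               dnorm(d3$y1, mom1$mean["y1"], sqrt(mom1$cov["y1", "y1"]),
                     log = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)

  # non-positive-definite implied covariance: -Inf surrogate, no exception
  bad <- setNames(free_params(s)$value, free_params(s)$label)
  bad["covariance.f1.f2.all"] <- 10
  expect_identical(fiml_loglik(s, bad, d), -Inf)
})

test_that("log-likelihood is invariant to row and column permutations", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 120, seed = 15)
  set.seed(15)
  d[sample(120, 30), "y2"] <- NA
  ll <- fiml_loglik(s, NULL, d)
  expect_equal(fiml_loglik(s, NULL, d[sample(nrow(d)), ]), ll,
               tolerance = 1e-10)
  expect_equal(fiml_loglik(s, NULL, d[, c(3, 1, 4, 2)]), ll,
               tolerance = 1e-10)
})

test_that("a saturated fit reproduces sample moments (divisor n)", {
  vs <- c("a", "b", "c")
  e <- NULL
  for (i in seq_along(vs)) {
    e <- rbind(e, ent("variance", vs[i], value = 1),
               ent("mean", vs[i], value = 0))
    for (j in seq_len(i - 1)) e <- rbind(e, ent("covariance", vs[j], vs[i],
                                                value = 0.2))
  }
  s <- sem_spec(vs, entries = e)
  set.seed(8)
  d <- as.data.frame(matrix(rnorm(50 * 3), 50, 3))
  names(d) <- vs
  f <- fit_model(s, d, options = sim_options)
  n <- nrow(d)
  S <- cov(as.matrix(d)) * (n - 1) / n
  expect_equal(f$implied$all$cov, S, tolerance = 1e-6)
  expect_equal(f$implied$all$mean, colMeans(d), tolerance = 1e-6)
  expect_equal(f$df, 0)
})

test_that("parameters of a two-factor model are recovered at n = 1000", {
  s <- sem_spec(
    observed = paste0("y", 1:6), latent = c("f1", "f2"),
    entries = rbind(
      ent("loading", "f1", "y1", free = FALSE, value = 1),
      ent("loading", "f1", "y2", value = 0.8),
      ent("loading", "f1", "y3", value = 1.2),
      ent("loading", "f2", "y4", free = FALSE, value = 1),
      ent("loading", "f2", "y5", value = 0.9),
      ent("loading", "f2", "y6", value = 1.1),
      ent("variance", "f1", value = 1), ent("variance", "f2", value = 0.8),
      ent("covariance", "f1", "f2", value = 0.45),
      do.call(rbind, lapply(paste0("y", 1:6), function(v)
        ent("variance", v, value = 0.5))),
      do.call(rbind, lapply(paste0("y", 1:6), function(v)
        ent("mean", v, value = 0.3)))))
  truth <- setNames(free_params(s)$value, free_params(s)$label)
  d <- simulate_spec_data(s, 1000, seed = 44)
  f <- fit_model(s, d, options = sim_options)
  expect_true(f$converged)
  lds <- grep("^loading", names(truth), value = TRUE)
  expect_lt(max(abs(f$theta[lds] - truth[lds])), 0.1)
  r_est <- standardize(f)
  r <- r_est$std[r_est$kind == "covariance" & r_est$from == "f1"]
  expect_lt(abs(r - 0.45 / sqrt(0.8)), 0.1)
})

test_that("standard errors come from the observed information", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 500, seed = 9)
  f <- fit_model(s, d, options = list(starts = 1, se = TRUE))
  expect_true(all(is.finite(f$params$se)))
  # the latent covariance SE should be in a plausible range at n = 500
  se_psi <- f$params$se[f$params$label == "covariance.f1.f2.all"]
  expect_gt(se_psi, 0.01); expect_lt(se_psi, 0.5)
})

test_that("likelihood-ratio machinery enforces nesting and conventions", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 200, seed = 10)
  f_free <- fit_model(s, d, options = sim_options)
  s0 <- fix_entry(s, "covariance", "f1", "f2")
  f_cons <- fit_model(s0, d, options = sim_options)
  l <- likelihood_ratio_test(f_free, f_cons)
  expect_equal(l$delta_df, 1)
  expect_gte(l$delta_chi2, 0)
  # identical models: delta chi2 0, p 1
  l0 <- likelihood_ratio_test(f_free, f_free)
  expect_equal(l0$delta_chi2, 0)
  expect_equal(l0$p, 1)
  # wrong order is a nesting error
  expect_error(likelihood_ratio_test(f_cons, f_free), "nesting")
  # boundary: delta chi2 = 3.841, df = 1 gives p = 0.05
  stub <- function(ll, df) structure(list(loglik = ll, df = df,
                                          converged = TRUE),
                                     class = "catena_fit")
  lb <- likelihood_ratio_test(stub(-1000, 10), stub(-1000 - 3.841459 / 2, 11))
  expect_equal(lb$p, 0.05, tolerance = 1e-5)
  expect_equal(lb$verdict, "significant")
  # trend convention in (0.05, 0.1]
  lt <- likelihood_ratio_test(stub(-1000, 10), stub(-1000 - 3.2 / 2, 11))
  expect_equal(lt$verdict, "trend")
  # non-converged fits are refused
  bad <- stub(-1000, 10); bad$converged <- FALSE
  expect_error(likelihood_ratio_test(bad, stub(-1001, 11)), "converge")
})

test_that("saturated EM equals direct optimization under missingness", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 150, seed = 12)
  set.seed(12)
  for (j in 1:4) d[runif(150) < 0.25, j] <- NA
  d <- d[rowSums(!is.na(d)) > 0, ]
  # route 1: EM on pattern blocks (used by fit_indices)
  blocks <- catena:::pattern_blocks(catena:::prepare_data(s, d)$all)
  em <- catena:::mvn_mle_blocks(blocks, 4)
  # route 2: the generic optimizer on an explicitly saturated spec
  vs <- names(d)
  e <- NULL
  for (i in seq_along(vs)) {
    e <- rbind(e, ent("variance", vs[i], value = 1),
               ent("mean", vs[i], value = 0))
    for (j in seq_len(i - 1)) e <- rbind(e, ent("covariance", vs[j], vs[i],
                                                value = 0.1))
  }
  ssat <- sem_spec(vs, entries = e)
  fsat <- fit_model(ssat, d, options = list(starts = 1, se = FALSE))
  expect_equal(em$loglik, fsat$loglik, tolerance = 1e-5)
})

test_that("fit indices honor their boundary identities", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 250, seed = 13)
  f <- fit_model(s, d, options = sim_options)
  fi <- fit_indices(f)
  expect_gte(fi$chi_square, 0)
  expect_gte(fi$rmsea, 0)
  expect_true(fi$cfi >= 0 && fi$cfi <= 1)
  # independence baseline as the fitted model: CFI = 0
  vs <- names(d)
  e <- NULL
  for (v in vs) e <- rbind(e, ent("variance", v, value = 1),
                           ent("mean", v, value = 0))
  sbase <- sem_spec(vs, entries = e)
  fb <- fit_model(sbase, d, options = sim_options)
  expect_equal(fit_indices(fb)$cfi, 0, tolerance = 1e-6)
  # RMSEA is 0 whenever chi-square <= df
  expect_equal(catena:::rmsea_value(5, 10, 250, 1), 0)
  expect_equal(catena:::rmsea_value(12, 10, 250, 2),
               sqrt(2) * sqrt(2 / (10 * 250)))
})

test_that("standardization rescales correctly and bounds correlations", {
  s <- two_factor_spec()
  d <- simulate_spec_data(s, 400, seed = 14)
  f <- fit_model(s, d, options = sim_options)
  st <- standardize(f)
  r <- st$std[st$kind == "covariance"]
  expect_true(all(abs(r) <= 1))
  # scale invariance: doubling the data leaves r unchanged
  d2 <- d * 2
  f2 <- fit_model(s, d2, options = sim_options)
  st2 <- standardize(f2)
  expect_equal(st2$std[st2$kind == "covariance"], r, tolerance = 1e-4)
})

test_that("the invariance ladder runs and is null on duplicated data", {
  spec <- ladder_spec_all()
  d <- simulate_spec_data(ladder_spec(), 300, seed = 16)
  # duplicate one group's data as the other group: every step is null
  d1 <- d[d$group == "g1", ]
  d2 <- d1; d2$group <- "g2"
  lad <- invariance_ladder(spec, rbind(d1, d2), group = "group",
                           options = sim_options)
  expect_named(lad$fits, c("configural", "weak", "strong", "strict"))
  expect_lt(max(lad$table$delta_chi2), 0.02)
  expect_equal(lad$table$delta_df, c(2L, 2L, 3L))
  expect_error(invariance_ladder(ladder_spec_all(groups = NULL), d),
               "grouping error")
})
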