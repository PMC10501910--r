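# Inference on fitted models: likelihood-ratio tests, fit indices,
# standardized solutions and the measurement-invariance ladder.

format_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))

verdict_from_p <- function(p, alpha = 0.05, trend = 0.1) {
  ifelse(p <= alpha, "significant",
         ifelse(p <= trend, "trend", "ns"))
}

#' Likelihood-ratio test of nested models
#'
#' The parameter of interest is freely estimated in one model and
#' constrained (typically fixed to zero) in the other; a drop in fit
#' indicates its significance. Tested at alpha = 0.05; p values in
#' (0.05, 0.1] are labelled a statistical trend.
#'
#' @param fit_free the less constrained `catena_fit`.
#' @param fit_constrained the nested, more constrained `catena_fit`.
#' @return a `catena_lrt`: `delta_chi2`, `delta_df`, `p`, `verdict`.
#' @export
likelihood_ratio_test <- function(fit_free, fit_constrained) {
  assert_converged(fit_free, "free model")
  assert_converged(fit_constrained, "constrained model")
  delta_df <- fit_constrained$df - fit_free$df
  diff2 <- 2 * (fit_free$loglik - fit_constrained$loglik)
  if (delta_df < 1) {
    # identical models are a degenerate comparison: delta chi2 0, p 1
    if (delta_df == 0 && abs(diff2) < 1e-6)
      return(structure(list(delta_chi2 = 0, delta_df = 0L, p = 1,
                            verdict = "ns"), class = "catena_lrt"))
    stop("nesting error: constrained model must have fewer free parameters")
  }
  if (diff2 < -1e-4)
    stop("nesting error: constrained model fits better than free model ",
         sprintf("(delta logLik = %.6f)", diff2 / 2))
  delta_chi2 <- max(diff2, 0)
  p <- pchisq(delta_chi2, delta_df, lower.tail = FALSE)
  structure(list(delta_chi2 = delta_chi2, delta_df = delta_df, p = p,
                 verdict = verdict_from_p(p)),
            class = "catena_lrt")
}

#' @export
print.catena_lrt <- function(x, ...) {
  cat(sprintf("Delta chi2(df = %d) = %.3f; P %s [%s]\n",
              x$delta_df, x$delta_chi2, format_p(x$p), x$verdict))
  invisible(x)
}

rmsea_value <- function(chi2, df, N, n_groups) {
  if (df <= 0) return(0)
  sqrt(n_groups) * sqrt(max(chi2 - df, 0) / (df * N))
}

cfi_value <- function(chi2_m, df_m, chi2_b, df_b) {
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Absolute and approximate fit indices
#'
#' The chi-square compares the model against a FIML-estimated saturated
#' model (free means and covariances per group), so it is well defined
#' under missingness. RMSEA (multi-group convention: multiplied by the
#' square root of the number of groups) close to or below 0.06 and CFI
#' (independence baseline: free variances and means, zero covariances)
#' close to 0.95 or greater indicate good fit.
#'
#' @param fit a converged `catena_fit`.
#' @param data optional data frame to recompute the sample blocks from;
#'   defaults to the data the model was fitted on.
#' @param group group column/vector when `data` is supplied.
#' @return a `catena_fit_indices`: chi_square, df, p, rmsea, cfi plus the
#'   saturated/baseline log-likelihoods.
#' @export
fit_indices <- function(fit, data = NULL, group = NULL) {
  assert_converged(fit)
  spec <- fit$spec
  if (!is.null(data)) {
    Ys <- prepare_data(spec, data, group)
  } else {
    Ys <- NULL
  }
  blocks <- if (is.null(Ys)) fit$blocks else lapply(Ys, pattern_blocks)
  p <- length(spec$observed)
  G <- length(blocks)
  N <- fit$n

  ll_sat <- 0; ll_base <- 0
  for (gp in names(blocks)) {
    bl <- blocks[[gp]]
    ll_sat <- ll_sat + mvn_mle_blocks(bl, p)$loglik
    ll_base <- ll_base + baseline_loglik_blocks(bl, p)
  }
  chi2_m <- max(2 * (ll_sat - fit$loglik), 0)
  df_m <- fit$df
  df_base <- G * p * (p + 3) / 2 - 2 * p * G
  chi2_b <- max(2 * (ll_sat - ll_base), 0)
  pval <- if (df_m > 0) pchisq(chi2_m, df_m, lower.tail = FALSE) else NA_real_
  note <- if (df_m == 0) "saturated model (df = 0): RMSEA reported as 0" else NULL
  structure(list(chi_square = chi2_m, df = df_m, p = pval,
                 rmsea = rmsea_value(chi2_m, df_m, N, G),
                 cfi = cfi_value(chi2_m, df_m, chi2_b, df_base),
                 loglik = fit$loglik, loglik_saturated = ll_sat,
                 loglik_baseline = ll_base, baseline_df = df_base,
                 note = note),
            class = "catena_fit_indices")
}

# Saturated-model FIML MLE (mu, Sigma) via EM on pattern sufficient
# statistics; with complete data this is the closed-form MLE in one step.
mvn_mle_blocks <- function(blocks, p, max_iter = 500L, tol = 1e-10) {
  if (length(blocks) == 1L && length(blocks[[1L]]$cols) == p) {
    b <- blocks[[1L]]
    return(list(mean = b$ybar, cov = b$S,
                loglik = loglik_from_blocks(blocks, b$ybar, b$S), iter = 0L))
  }
  nobs <- numeric(p)
  mu <- numeric(p); ssq <- numeric(p)
  for (b in blocks) {
    o <- b$cols + 1L
    nobs[o] <- nobs[o] + b$n
    mu[o] <- mu[o] + b$n * b$ybar
  }
  if (any(nobs == 0))
    stop("variable(s) never observed within a group; saturated model undefined")
  mu <- mu / nobs
  Sigma <- diag(p)
  for (b in blocks) {
    o <- b$cols + 1L
    ssq[o] <- ssq[o] + b$n * (diag(b$S) + (b$ybar - mu[o])^2)
  }
  diag(Sigma) <- pmax(ssq / nobs, 1e-8)
  ll_old <- -Inf; ll <- -Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p); n_tot <- 0
    for (b in blocks) {
      o <- b$cols + 1L
      m <- setdiff(seq_len(p), o)
      n <- b$n; n_tot <- n_tot + n
      sum_d <- n * (b$ybar - mu[o])
      sum_dd <- n * (b$S + tcrossprod(b$ybar - mu[o]))
      sum_yo <- n * b$ybar
      sum_yoyo <- n * (b$S + tcrossprod(b$ybar))
      T1[o] <- T1[o] + sum_yo
      T2[o, o] <- T2[o, o] + sum_yoyo
      if (length(m)) {
        W <- Sigma[m, o, drop = FALSE] %*% solve(Sigma[o, o, drop = FALSE])
        C <- Sigma[m, m, drop = FALSE] - W %*% Sigma[o, m, drop = FALSE]
        T1[m] <- T1[m] + n * mu[m] + as.numeric(W %*% sum_d)
        som <- tcrossprod(sum_yo, mu[m]) +
          (sum_dd + tcrossprod(mu[o], sum_d)) %*% t(W)
        T2[o, m] <- T2[o, m] + som
        T2[m, o] <- T2[m, o] + t(som)
        Wd <- as.numeric(W %*% sum_d)
        T2[m, m] <- T2[m, m] + n * tcrossprod(mu[m]) +
          tcrossprod(Wd, mu[m]) + tcrossprod(mu[m], Wd) +
          W %*% sum_dd %*% t(W) + n * C
      }
    }
    mu <- T1 / n_tot
    Sigma <- T2 / n_tot - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- loglik_from_blocks(blocks, mu, Sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mean = mu, cov = Sigma, loglik = ll, iter = it)
}

baseline_loglik_blocks <- function(blocks, p) {
  n <- numeric(p); s1 <- numeric(p); s2 <- numeric(p)
  for (b in blocks) {
    o <- b$cols + 1L
    n[o] <- n[o] + b$n
    s1[o] <- s1[o] + b$n * b$ybar
    s2[o] <- s2[o] + b$n * (diag(b$S) + b$ybar^2)
  }
  ll <- 0
  for (j in seq_len(p)) {
    if (n[j] == 0) next
    m <- s1[j] / n[j]
    v <- max(s2[j] / n[j] - m^2, .Machine$double.eps)
    ll <- ll - 0.5 * n[j] * (log(2 * pi) + log(v) + 1)
  }
  ll
}

#' Standardized solution
#'
#' Covariances are divided by the product of model-implied standard
#' deviations (giving correlations r); regression weights are rescaled by
#' sd(predictor) / sd(outcome) (giving beta); loadings likewise.
#'
#' @param fit a converged `catena_fit`.
#' @return data frame: group, kind, from, to, label, estimate, std.
#' @export
standardize <- function(fit) {
  assert_converged(fit)
  cs <- compile_spec(fit$spec)
  theta <- fit$theta
  out <- list()
  for (gp in cs$groups) {
    m <- fill_matrices(cs, gp, theta)
    B <- solve(diag(cs$nv) - m$A)
    V <- B %*% m$S %*% t(B)
    sds <- sqrt(pmax(diag(V), 0))
    if (any(sds == 0)) {
      zero <- cs$vars[sds == 0]
      stop("standardization error: zero model-implied variance for ",
           paste(zero, collapse = ", "))
    }
    rows <- cs$rows[cs$rows$group == gp, , drop = FALSE]
    i <- match(rows$from, cs$vars); j <- match(rows$to, cs$vars)
    est <- ifelse(rows$free, theta[rows$label], rows$value)
    std <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      std[r] <- switch(rows$kind[r],
        loading = , regression = est[r] * sds[i[r]] / sds[j[r]],
        covariance = V[i[r], j[r]] / (sds[i[r]] * sds[j[r]]),
        variance = est[r] / (sds[i[r]]^2),
        mean = est[r] / sds[i[r]])
    }
    out[[gp]] <- data.frame(group = gp, kind = rows$kind, from = rows$from,
                            to = rows$to, label = rows$label, estimate = est,
                            std = std, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.catena_fit_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, P %s; RMSEA = %.3f; CFI = %.3f\n",
              x$df, x$chi_square,
              if (is.na(x$p)) "= NA" else format_p(x$p), x$rmsea, x$cfi))
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Measurement-invariance ladder

strip_tp <- function(x) sub("_tp[0-9]+$", "", x)

equalize <- function(spec, kinds, prefix, key_fun) {
  e <- spec$entries
  sel <- e$kind %in% kinds & e$free
  e$label[sel] <- paste0(prefix, key_fun(e$from[sel], e$to[sel]))
  spec$entries <- e
  spec
}

# Free latent means in non-reference groups (needed once intercepts are
# equality-constrained across groups).
free_latent_means <- function(spec) {
  gs <- spec_groups(spec)
  add <- do.call(rbind, lapply(gs[-1L], function(gp) {
    do.call(rbind, lapply(spec$latent, function(lv)
      ent("mean", lv, free = TRUE, value = 0, group = gp)))
  }))
  spec$entries <- rbind(spec$entries, add)
  spec
}

#' Measurement-invariance ladder
#'
#' Fits the configural model, then successively equality-constrains
#' (1) factor loadings (weak invariance), (2) indicator intercepts (strong
#' invariance; latent means are freed in the non-reference groups) and
#' (3) residual variances (strict invariance), comparing each step to the
#' previous one with a likelihood-ratio test. With
#' `grouping = "timepoints"` the same criteria are applied across time for
#' longitudinal specs whose variables follow the `name_tp<k>` convention.
#'
#' @param spec a multi-group [sem_spec()] whose measurement entries are
#'   unlabelled and group-scoped `"all"` (the builders produce this form).
#' @param data data frame.
#' @param group group column/vector.
#' @param grouping `"groups"` or `"timepoints"`.
#' @param options passed to [fit_model()].
#' @return a `catena_ladder`: per-step fits, LRT chain and verdicts.
#' @export
invariance_ladder <- function(spec, data, group = NULL,
                              grouping = c("groups", "timepoints"),
                              options = list()) {
  grouping <- match.arg(grouping)
  if (grouping == "groups" && length(spec_groups(spec)) < 2L)
    stop("grouping error: invariance across groups needs >= 2 groups")

  # only measurement entries (observed indicators) take equality labels;
  # latent variances/means always stay group- or time-specific
  reset_latent <- function(s) {
    lv <- s$entries$from %in% spec$latent &
      s$entries$kind %in% c("variance", "mean") & s$entries$free &
      startsWith(s$entries$label, ".eq.")
    s$entries$label[lv] <- ""
    s
  }
  if (grouping == "groups") {
    weak <- reset_latent(
      equalize(spec, "loading", ".eq.l.",
               function(from, to) paste(from, to, sep = ".")))
    strong <- free_latent_means(
      reset_latent(equalize(weak, "mean", ".eq.i.", function(from, to) from)))
    strict <- reset_latent(
      equalize(strong, "variance", ".eq.e.", function(from, to) from))
  } else {
    weak <- reset_latent(
      equalize(spec, "loading", ".eq.l.",
               function(from, to) paste(strip_tp(from), strip_tp(to), sep = ".")))
    strong <- reset_latent(
      equalize(weak, "mean", ".eq.i.", function(from, to) strip_tp(from)))
    strict <- reset_latent(
      equalize(strong, "variance", ".eq.e.", function(from, to) strip_tp(from)))
  }
  steps <- list(configural = spec, weak = weak, strong = strong,
                strict = strict)
  fits <- lapply(steps, function(s) fit_model(s, data, group, options))
  lrts <- list()
  for (i in 2:4) {
    lrts[[names(steps)[i]]] <-
      likelihood_ratio_test(fits[[i - 1L]], fits[[i]])
  }
  tab <- data.frame(
    step = names(lrts),
    delta_chi2 = vapply(lrts, `[[`, 0, "delta_chi2"),
    delta_df = as.integer(vapply(lrts, `[[`, 0, "delta_df")),
    p = vapply(lrts, `[[`, 0, "p"),
    verdict = vapply(lrts, `[[`, "", "verdict"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(fits = fits, lrts = lrts, table = tab),
            class = "catena_ladder")
}

#' @export
print.catena_ladder <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
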