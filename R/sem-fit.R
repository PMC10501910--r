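# Maximum-likelihood estimation of a specification by quasi-Newton
# iteration on the FIML surface. Variances are optimized on the log scale
# so they stay positive; other parameters are unconstrained. Dispersed
# random starts guard against multimodality.

default_fit_options <- function() {
  list(starts = 3L, seed = 11L, se = TRUE, max_iter = 1000L,
       reltol = 1e-12, grad_tol = 1e-2)
}

smart_starts <- function(cs, Ys) {
  spec <- cs$spec
  theta <- numeric(length(cs$labels))
  # available-case means and variances pooled over groups
  allY <- do.call(rbind, Ys)
  mns <- colMeans(allY, na.rm = TRUE)
  vrs <- apply(allY, 2, var, na.rm = TRUE)
  vrs[!is.finite(vrs) | vrs <= 0] <- 1
  mns[!is.finite(mns)] <- 0
  # proxy sd for a variable: follow fixed-loading chains to an observed var
  scale_var <- function(v, depth = 0L) {
    if (v %in% spec$observed) return(vrs[[v]])
    if (depth > 4L) return(1)
    r <- cs$rows
    cand <- r[r$kind == "loading" & r$from == v & !r$free, , drop = FALSE]
    if (!nrow(cand)) return(1)
    scale_var(cand$to[1L], depth + 1L) / 2
  }
  for (k in seq_along(cs$labels)) {
    rows <- cs$rows[cs$rows$free & cs$rows$label == cs$labels[k], , drop = FALSE]
    r1 <- rows[1L, ]
    theta[k] <- switch(
      r1$kind,
      mean = if (r1$from %in% spec$observed) mns[[r1$from]] else 0,
      variance = if (r1$from %in% spec$observed) 0.5 * vrs[[r1$from]]
                 else max(scale_var(r1$from), 1e-3),
      loading = 0.8 * sqrt(scale_var(r1$to) / max(scale_var(r1$from), 1e-8)),
      covariance = 0.2 * sqrt(scale_var(r1$from) * scale_var(r1$to)),
      regression = 0
    )
  }
  theta
}

to_trans <- function(theta, positive) {
  theta[positive] <- log(pmax(theta[positive], 1e-6))
  theta
}
from_trans <- function(theta_t, positive) {
  theta_t[positive] <- exp(theta_t[positive])
  theta_t
}

make_negll <- function(cs, blocks, transformed = TRUE) {
  nv <- cs$nv
  ov <- cs$ov_idx
  I <- diag(nv)
  gs <- cs$groups
  pos <- cs$positive
  BIG <- 1e12
  function(x) {
    theta <- if (transformed) from_trans(x, pos) else x
    if (!transformed && any(theta[pos] <= 0)) return(BIG)
    ll <- 0
    for (gp in gs) {
      m <- fill_matrices(cs, gp, theta)
      B <- tryCatch(solve(I - m$A), error = function(e) NULL)
      if (is.null(B)) return(BIG)
      V <- B %*% m$S %*% t(B)
      mu <- as.numeric(B %*% m$M)
      lg <- fiml_blocks_loglik(blocks[[gp]], mu[ov],
                               V[ov, ov, drop = FALSE])
      if (is.na(lg) || !is.finite(lg)) return(BIG)
      ll <- ll + lg
    }
    -ll
  }
}

central_grad <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  g
}

# forward differences (p + 1 evaluations): used inside the optimizer where
# speed matters; the final convergence check uses central differences
forward_grad <- function(fn, x, h = 1e-7) {
  f0 <- fn(x)
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    g[i] <- (fn(xp) - f0) / hi
  }
  g
}

#' Fit a model by full-information maximum likelihood
#'
#' Maximizes the FIML log-likelihood with BFGS on a log-variance
#' parameterization, from `starts` dispersed starting points (the first is
#' data-informed, the rest are jittered), keeping the best solution.
#' Standard errors come from the inverse observed information. Downstream
#' inference refuses non-converged fits.
#'
#' @param spec a [sem_spec()].
#' @param data data frame of observed variables.
#' @param group group column name or vector for multi-group specs.
#' @param options list overriding `starts`, `seed`, `se`, `max_iter`,
#'   `reltol`, `grad_tol`.
#' @return an object of class `catena_fit`.
#' @export
fit_model <- function(spec, data, group = NULL, options = list()) {
  opt <- modifyList(default_fit_options(), options)
  cs <- compile_spec(spec)
  if (!length(cs$labels)) stop("model has no free parameters")
  Ys <- prepare_data(spec, data, group)
  blocks <- lapply(Ys, pattern_blocks)
  negll <- make_negll(cs, blocks, transformed = TRUE)
  grad <- function(x) forward_grad(negll, x)

  base <- to_trans(smart_starts(cs, Ys), cs$positive)
  best <- NULL
  # up to 3 extra jittered attempts when every planned start fails
  for (s in seq_len(opt$starts + 3L)) {
    if (s > opt$starts && !is.null(best)) break
    x0 <- base
    if (s > 1L) {
      set.seed(opt$seed + s)
      x0 <- base + runif(length(base), -0.5, 0.5)
    }
    res <- tryCatch(
      optim(x0, negll, gr = grad, method = "BFGS",
            control = list(maxit = opt$max_iter, reltol = opt$reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimization failed from every start")
  # polish from the best solution with the more accurate gradient
  res <- tryCatch(
    optim(best$par, negll, gr = function(x) central_grad(negll, x),
          method = "BFGS",
          control = list(maxit = opt$max_iter, reltol = opt$reltol)),
    error = function(e) NULL)
  if (!is.null(res) && res$value <= best$value) best <- res

  g <- central_grad(negll, best$par)
  ll <- -best$value
  converged <- best$convergence == 0 && is.finite(ll) &&
    max(abs(g)) < opt$grad_tol * max(1, abs(ll) / 100)
  theta <- from_trans(best$par, cs$positive)
  names(theta) <- cs$labels

  se <- rep(NA_real_, length(theta))
  if (isTRUE(opt$se)) {
    negll_u <- make_negll(cs, blocks, transformed = FALSE)
    H <- tryCatch(optimHess(theta, negll_u), error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hi)) {
        d <- diag(Hi)
        se[d > 0] <- sqrt(d[d > 0])
      }
    }
  }

  p <- length(spec$observed)
  n_groups <- length(cs$groups)
  moments <- n_groups * p * (p + 3) / 2
  npar <- length(theta)
  mom <- implied_moments(spec, theta)

  structure(list(
    params = data.frame(label = cs$labels, estimate = unname(theta),
                        se = se, kind = unname(cs$par_kind),
                        stringsAsFactors = FALSE),
    theta = theta, loglik = ll, df = moments - npar, npar = npar,
    n_per_group = vapply(Ys, nrow, 0L), n = sum(vapply(Ys, nrow, 0L)),
    converged = converged, grad_max = max(abs(g)),
    implied = mom, spec = spec, blocks = blocks,
    optim = list(counts = best$counts, convergence = best$convergence)),
    class = "catena_fit")
}

#' @export
print.catena_fit <- function(x, ...) {
  cat(sprintf("<catena_fit> logLik = %.3f, npar = %d, df = %d, n = %d%s\n",
              x$loglik, x$npar, x$df, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Extract parameter estimates
#' @param fit a `catena_fit`.
#' @return data frame of labels, estimates, standard errors.
#' @export
coef_table <- function(fit) fit$params

assert_converged <- function(fit, what = "fit") {
  if (!isTRUE(fit$converged))
    stop(what, " did not converge; refusing downstream inference")
  invisible(fit)
}

#' Export a fit as JSON
#' @param fit a `catena_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    loglik = fit$loglik, npar = fit$npar, df = fit$df, n = fit$n,
    converged = fit$converged,
    estimates = fit$params), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
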