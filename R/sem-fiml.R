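# Full-information maximum likelihood under missingness.
#
# Likelihood evaluation groups cases by missingness pattern and reduces
# each pattern to sufficient statistics (see src/fiml.cpp); a naive
# casewise implementation is retained as an independent cross-check.

# Split a data frame into per-group observed matrices in spec order.
prepare_data <- function(spec, data, group = NULL) {
  gs <- spec_groups(spec)
  if (is.character(group) && length(group) == 1L) {
    if (!group %in% names(data)) stop("group column '", group, "' not found")
    glab <- as.character(data[[group]])
  } else if (!is.null(group)) {
    glab <- as.character(group)
  } else if (length(gs) > 1L && "group" %in% names(data)) {
    glab <- as.character(data$group)
  } else {
    glab <- rep(gs[1], nrow(data))
  }
  if (length(gs) > 1L) {
    bad <- setdiff(unique(glab), gs)
    if (length(bad)) stop("data contain unknown group(s): ",
                          paste(bad, collapse = ", "))
  }
  miss <- setdiff(spec$observed, names(data))
  if (length(miss)) stop("data lack model variables: ",
                         paste(miss, collapse = ", "))
  Y <- as.matrix(data[spec$observed])
  storage.mode(Y) <- "double"
  keep <- rowSums(!is.na(Y)) > 0
  if (!all(keep)) {
    warning(sum(!keep), " case(s) with no observed values removed")
    Y <- Y[keep, , drop = FALSE]; glab <- glab[keep]
  }
  lapply(setNames(gs, gs), function(gp) Y[glab == gp, , drop = FALSE])
}

# Missingness-pattern blocks with sufficient statistics (divisor n).
pattern_blocks <- function(Y) {
  if (!nrow(Y)) return(list())
  obs <- !is.na(Y)
  pat <- apply(obs, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(Y)), pat), function(idx) {
    cols <- which(obs[idx[1L], ])
    Yb <- Y[idx, cols, drop = FALSE]
    n <- length(idx)
    ybar <- colMeans(Yb)
    ctr <- sweep(Yb, 2, ybar)
    list(cols = cols - 1L, n = as.double(n), ybar = ybar,
         S = crossprod(ctr) / n)
  })
}

loglik_from_blocks <- function(blocks, mu, Sigma) {
  if (!length(blocks)) return(0)
  ll <- fiml_blocks_loglik(blocks, mu, Sigma)
  if (is.na(ll)) -Inf else ll
}

#' FIML log-likelihood of a specification
#'
#' Sums, over cases, the multivariate normal log-density restricted to each
#' case's observed variables, using that case's group moments. The default
#' groups cases by missingness pattern; `method = "casewise"` evaluates the
#' naive case-by-case sum, which is algebraically identical and retained as
#' an independent cross-check.
#'
#' A non-positive-definite implied covariance yields `-Inf` (an optimizer
#' surrogate), never an exception.
#'
#' @param spec a [sem_spec()].
#' @param params named free-parameter vector (`NULL` uses entry values).
#' @param data data frame of observed variables (optionally with a group
#'   column for multi-group specs).
#' @param group group column name or vector (multi-group specs).
#' @param method `"pattern"` or `"casewise"`.
#' @return scalar log-likelihood.
#' @export
fiml_loglik <- function(spec, params = NULL, data, group = NULL,
                        method = c("pattern", "casewise")) {
  method <- match.arg(method)
  mom <- implied_moments(spec, params)
  Ys <- prepare_data(spec, data, group)
  ll <- 0
  for (gp in names(Ys)) {
    mu <- mom[[gp]]$mean; Sigma <- mom[[gp]]$cov
    if (method == "pattern") {
      ll <- ll + loglik_from_blocks(pattern_blocks(Ys[[gp]]), mu, Sigma)
    } else {
      ll <- ll + loglik_casewise(Ys[[gp]], mu, Sigma)
    }
  }
  ll
}

# Naive casewise reference implementation (R only, no pattern grouping).
loglik_casewise <- function(Y, mu, Sigma) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    S <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    d <- backsolve(ch, Y[i, o] - mu[o], transpose = TRUE)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                      2 * sum(log(diag(ch))) + sum(d^2))
  }
  ll
}

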