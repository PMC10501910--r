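# Declarative latent-variable model specification.
#
# Models are lists of entries over observed and latent variables. Each
# entry is a loading, regression, (co)variance or mean/intercept, either
# free (optionally labelled; shared labels impose equality, including
# across groups) or fixed to a value. Internally the model is compiled to
# the reticular path-matrix (RAM) form: v = A v + u, u ~ N(M, S),
# observed = F v, so that implied moments are
# F (I - A)^-1 S (I - A)^-T F' and F (I - A)^-1 M for any mix of factor,
# regression and change models.

ENTRY_KINDS <- c("loading", "regression", "covariance", "variance", "mean")

#' Create a model entry
#'
#' @param kind one of `"loading"` (latent -> indicator), `"regression"`
#'   (predictor -> outcome), `"covariance"`, `"variance"`, `"mean"`.
#' @param from,to variable names; for `variance` and `mean`, `to` defaults
#'   to `from`.
#' @param free is the parameter estimated?
#' @param value fixed value (when `free = FALSE`) or the value used when
#'   simulating data from the specification (when free).
#' @param label optional label; entries sharing a label share one
#'   parameter, which is how equality constraints are imposed.
#' @param group group name this entry applies to, or `"all"`.
#' @return one-row data frame.
#' @export
ent <- function(kind, from, to = from, free = TRUE, value = NA_real_,
                label = "", group = "all") {
  kind <- match.arg(kind, ENTRY_KINDS)
  if (!free && is.na(value)) stop("fixed entry needs a value")
  data.frame(kind = kind, from = from, to = to, free = free, value = value,
             label = label, group = group, stringsAsFactors = FALSE)
}

#' Create a model specification
#'
#' @param observed,latent character vectors of variable names.
#' @param entries data frame of [ent()] rows.
#' @param groups character vector of group names for multi-group models,
#'   or `NULL` for a single group.
#' @return an object of class `catena_spec`.
#' @export
sem_spec <- function(observed, latent = character(0), entries,
                     groups = NULL) {
  entries <- as.data.frame(entries)
  vars <- c(observed, latent)
  if (anyDuplicated(vars)) stop("duplicate variable names")
  bad <- setdiff(unique(c(entries$from, entries$to)), vars)
  if (length(bad)) stop("entries reference unknown variables: ",
                        paste(bad, collapse = ", "))
  gs <- if (is.null(groups)) "all" else groups
  badg <- setdiff(unique(entries$group), c("all", gs))
  if (length(badg)) stop("entries reference unknown groups: ",
                         paste(badg, collapse = ", "))
  key <- paste(entries$kind, entries$from, entries$to, entries$group)
  if (anyDuplicated(key))
    stop("duplicate entries: ", paste(unique(key[duplicated(key)]),
                                      collapse = "; "))

  # directed acyclicity over loadings + regressions
  adj <- entries[entries$kind %in% c("loading", "regression"), , drop = FALSE]
  if (nrow(adj)) {
    g <- unique(adj[, c("from", "to")])
    nodes <- unique(c(g$from, g$to))
    repeat {
      if (!nrow(g)) break
      sinks <- setdiff(nodes, unique(g$from))   # no outgoing edges
      if (!length(sinks))
        stop("cyclic model: directed paths among {",
             paste(nodes, collapse = ", "), "} form a cycle")
      nodes <- setdiff(nodes, sinks)
      g <- g[g$from %in% nodes & g$to %in% nodes, , drop = FALSE]
    }
  }

  # every latent needs a scale constraint in every group it appears in
  for (gp in gs) {
    sub <- entries[entries$group %in% c("all", gp), , drop = FALSE]
    for (lv in latent) {
      fixed_loading <- any(sub$kind == "loading" & sub$from == lv & !sub$free)
      fixed_var <- any(sub$kind == "variance" & sub$from == lv & !sub$free)
      if (!fixed_loading && !fixed_var)
        stop("identification error: latent '", lv,
             "' has no scale constraint (fix a loading or its variance)",
             if (length(gs) > 1) paste0(" in group '", gp, "'") else "")
    }
  }

  structure(list(observed = observed, latent = latent, entries = entries,
                 groups = groups), class = "catena_spec")
}

#' @export
print.catena_spec <- function(x, ...) {
  cat(sprintf("<catena_spec> %d observed, %d latent, %d entries%s\n",
              length(x$observed), length(x$latent), nrow(x$entries),
              if (is.null(x$groups)) "" else
                paste0(", groups: ", paste(x$groups, collapse = "/"))))
  invisible(x)
}

spec_groups <- function(spec) if (is.null(spec$groups)) "all" else spec$groups

# Expand "all"-group entries per group and auto-label unlabelled free
# entries per group (so unlabelled parameters are group-specific while
# shared labels impose cross-group equality).
compile_spec <- function(spec) {
  gs <- spec_groups(spec)
  e <- spec$entries
  rows <- do.call(rbind, lapply(gs, function(gp) {
    sub <- e[e$group %in% c("all", gp), , drop = FALSE]
    sub$group <- gp
    sub
  }))
  auto <- rows$free & rows$label == ""
  rows$label[auto] <- paste(rows$kind[auto], rows$from[auto], rows$to[auto],
                            rows$group[auto], sep = ".")
  vars <- c(spec$observed, spec$latent)
  nv <- length(vars)
  vi <- setNames(seq_len(nv), vars)

  labels <- unique(rows$label[rows$free])
  par_kind <- vapply(labels, function(l) {
    k <- unique(rows$kind[rows$free & rows$label == l])
    if (length(k) > 1) stop("label '", l, "' mixes entry kinds")
    k
  }, "")
  # a shared-label variance is positive; transform on the log scale
  positive <- par_kind == "variance"
  truth <- vapply(labels, function(l) {
    v <- rows$value[rows$free & rows$label == l]
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA_real_
  }, 0)

  per_group <- lapply(gs, function(gp) {
    sub <- rows[rows$group == gp, , drop = FALSE]
    i <- vi[sub$from]; j <- vi[sub$to]
    kind <- sub$kind
    # target positions: A[to, from] for directed; S symmetric; M vector
    list(
      A_i = j[kind %in% c("loading", "regression")],
      A_j = i[kind %in% c("loading", "regression")],
      A_par = match(sub$label[kind %in% c("loading", "regression")], labels),
      A_val = sub$value[kind %in% c("loading", "regression")],
      A_free = sub$free[kind %in% c("loading", "regression")],
      S_i = i[kind %in% c("covariance", "variance")],
      S_j = j[kind %in% c("covariance", "variance")],
      S_par = match(sub$label[kind %in% c("covariance", "variance")], labels),
      S_val = sub$value[kind %in% c("covariance", "variance")],
      S_free = sub$free[kind %in% c("covariance", "variance")],
      M_i = i[kind == "mean"],
      M_par = match(sub$label[kind == "mean"], labels),
      M_val = sub$value[kind == "mean"],
      M_free = sub$free[kind == "mean"]
    )
  })
  names(per_group) <- gs

  list(spec = spec, groups = gs, vars = vars, nv = nv,
       ov_idx = vi[spec$observed], labels = labels, par_kind = par_kind,
       positive = positive, truth = truth, per_group = per_group,
       rows = rows)
}

# Fill A, S, M for one group given a full named parameter vector.
fill_matrices <- function(cs, gp, theta) {
  g <- cs$per_group[[gp]]
  nv <- cs$nv
  A <- matrix(0, nv, nv); S <- matrix(0, nv, nv); M <- numeric(nv)
  if (length(g$A_i)) {
    vals <- ifelse(g$A_free, theta[g$A_par], g$A_val)
    A[cbind(g$A_i, g$A_j)] <- vals
  }
  if (length(g$S_i)) {
    vals <- ifelse(g$S_free, theta[g$S_par], g$S_val)
    S[cbind(g$S_i, g$S_j)] <- vals
    S[cbind(g$S_j, g$S_i)] <- vals
  }
  if (length(g$M_i)) {
    vals <- ifelse(g$M_free, theta[g$M_par], g$M_val)
    M[g$M_i] <- vals
  }
  list(A = A, S = S, M = M)
}

resolve_params <- function(cs, params) {
  if (is.null(params)) {
    theta <- cs$truth
    if (anyNA(theta))
      stop("no values available for free parameters: ",
           paste(cs$labels[is.na(theta)], collapse = ", "))
    return(theta)
  }
  miss <- setdiff(cs$labels, names(params))
  if (length(miss))
    stop("params missing labels: ", paste(miss, collapse = ", "))
  as.numeric(params[cs$labels])
}

#' Model-implied moments
#'
#' Computes per-group implied mean vector and covariance matrix of the
#' observed variables from the path-matrix representation.
#'
#' @param spec a [sem_spec()].
#' @param params named vector of free-parameter values (labels as produced
#'   by [free_params()]); `NULL` uses the entry values.
#' @return named list per group: `list(mean, cov)`.
#' @export
implied_moments <- function(spec, params = NULL) {
  cs <- compile_spec(spec)
  theta <- resolve_params(cs, params)
  out <- lapply(cs$groups, function(gp) {
    m <- fill_matrices(cs, gp, theta)
    IA <- diag(cs$nv) - m$A
    B <- tryCatch(solve(IA), error = function(e)
      stop("cyclic-model error: (I - A) is singular"))
    V <- B %*% m$S %*% t(B)
    mu <- as.numeric(B %*% m$M)
    ov <- cs$ov_idx
    list(mean = setNames(mu[ov], cs$spec$observed),
         cov = structure(V[ov, ov, drop = FALSE],
                         dimnames = list(cs$spec$observed, cs$spec$observed)))
  })
  names(out) <- cs$groups
  out
}

#' List the free parameters of a specification
#'
#' @param spec a [sem_spec()].
#' @return data frame with label, kind and the entry value (truth used for
#'   simulation), one row per distinct free parameter.
#' @export
free_params <- function(spec) {
  cs <- compile_spec(spec)
  data.frame(label = cs$labels, kind = unname(cs$par_kind),
             value = unname(cs$truth), stringsAsFactors = FALSE)
}

#' Serialize a specification to JSON
#' @param spec a [sem_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(spec, path) {
  jsonlite::write_json(list(observed = spec$observed, latent = spec$latent,
                            groups = spec$groups, entries = spec$entries),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a specification from JSON
#' @param path file written by [write_spec_json()].
#' @return a [sem_spec()].
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- x$groups
  if (!is.null(groups) && !length(groups)) groups <- NULL
  sem_spec(x$observed, if (length(x$latent)) x$latent else character(0),
           x$entries, groups = groups)
}

#' Simulate data from a specification
#'
#' Draws cases from the model-implied distribution: u ~ N(M, S),
#' v = (I - A)^-1 u, observed = F v, per group. This is the generating
#' process used by recovery and calibration simulations.
#'
#' @param spec a [sem_spec()].
#' @param n cases per group (scalar or named by group).
#' @param params named parameter vector; `NULL` uses entry values.
#' @param seed optional integer seed.
#' @return data frame of observed variables, with a `group` column when the
#'   spec is multi-group.
#' @export
simulate_spec_data <- function(spec, n, params = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- compile_spec(spec)
  theta <- resolve_params(cs, params)
  gs <- cs$groups
  if (length(n) == 1L && is.null(names(n))) n <- setNames(rep(n, length(gs)), gs)
  out <- lapply(gs, function(gp) {
    m <- fill_matrices(cs, gp, theta)
    B <- solve(diag(cs$nv) - m$A)
    L <- chol_psd(m$S)
    ng <- n[[gp]]
    U <- matrix(rnorm(ng * cs$nv), ng, cs$nv) %*% t(L)
    U <- sweep(U, 2, m$M, `+`)
    V <- U %*% t(B)
    df <- as.data.frame(V[, cs$ov_idx, drop = FALSE])
    names(df) <- cs$spec$observed
    if (length(gs) > 1L) df$group <- gp
    df
  })
  do.call(rbind, out)
}
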