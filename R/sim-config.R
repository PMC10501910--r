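# Simulation configuration for the synthetic cohort.
#
# The generator states a known world: per-participant latent integrity of
# the LC and SN-VTA and latent cognitive abilities (working memory, episodic
# memory, fluid intelligence) plus a medial temporal lobe (MTL) volume
# factor, rendered into multimodal volumes, task scores and ROI-volume
# tables. Defaults mirror the study design they emulate: 69 younger and 251
# older adults, imaging at TP1/TP2 with FSE only at TP2 (two acquisitions),
# cognition at TP1-TP3 with TP3 restricted to older adults, and the printed
# mean contrast ordering MT+ > FSE > MT-.

SIM_LATENTS <- c("lc", "snvta", "wm", "em", "gf", "mtl")

default_factor_moments <- function() {
  R <- diag(6)
  dimnames(R) <- list(SIM_LATENTS, SIM_LATENTS)
  set <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set("lc", "snvta", 0.25)
  set("lc", "wm", 0.20); set("lc", "em", 0.49); set("lc", "gf", 0.20)
  set("snvta", "wm", 0.28); set("snvta", "em", 0.15); set("snvta", "gf", 0.15)
  set("wm", "em", 0.50); set("wm", "gf", 0.50); set("em", "gf", 0.50)
  set("mtl", "lc", 0.41); set("mtl", "snvta", 0.23)
  set("mtl", "wm", 0.20); set("mtl", "em", 0.33); set("mtl", "gf", 0.20)
  list(
    younger = list(mean = setNames(rep(0, 6), SIM_LATENTS), cov = R),
    older = list(mean = setNames(c(-0.8, -0.8, -2.2, -2.3, -2.1, -1.0),
                                 SIM_LATENTS), cov = R)
  )
}

default_change_model <- function() {
  per <- function(mean, var, cov_baseline, age_slope)
    list(mean = mean, var = var, cov_baseline = cov_baseline,
         age_slope = age_slope)
  Rch <- diag(6)
  dimnames(Rch) <- list(SIM_LATENTS, SIM_LATENTS)
  set <- function(a, b, v) { Rch[a, b] <<- v; Rch[b, a] <<- v }
  set("lc", "em", 0.30); set("snvta", "wm", 0.30)
  set("lc", "snvta", 0.20); set("wm", "em", 0.30)
  list(
    lc = per(-0.02, 0.04, -0.010, -0.010),
    snvta = per(-0.02, 0.04, -0.010, -0.015),
    wm = per(-0.15, 0.09, -0.020, -0.010),
    em = per(-0.15, 0.09, -0.020, -0.010),
    gf = per(-0.10, 0.04, -0.010, -0.005),
    mtl = per(-0.05, 0.01, 0.000, -0.005),
    residual_cor = Rch
  )
}

default_modality_params <- function() {
  list(
    mtplus  = list(gain = 0.04, roi_offset = 0.26, ref_mean = 100,
                   noise_sd = 1.5, specific_sd = 0.8),
    fse     = list(gain = 0.03, roi_offset = 0.20, ref_mean = 100,
                   noise_sd = 1.5, specific_sd = 0.8),
    mtminus = list(gain = 0.02, roi_offset = 0.06, ref_mean = 100,
                   noise_sd = 1.5, specific_sd = 0.8)
  )
}

default_cognitive_loadings <- function() {
  data.frame(
    task = c("spatial_u", "letter_u", "number",
             "scene", "list", "face", "object",
             "problem", "analog", "letter"),
    factor = c(rep("wm", 3), rep("em", 4), rep("gf", 3)),
    loading = c(0.50, 0.55, 0.45, 0.55, 0.50, 0.45, 0.50, 0.50, 0.55, 0.45),
    intercept = 0,
    residual_sd = 0.45,
    stringsAsFactors = FALSE
  )
}

default_availability <- function() {
  list(mtplus = c(tp1 = 0.85, tp2 = 0.95),
       mtminus = c(tp1 = 0.85, tp2 = 0.95),
       fse = c(tp1 = 0, tp2 = 0.90),
       cognitive = c(tp1 = 0.97, tp2 = 0.97, tp3 = 0.95))
}

frac_box <- function(grid, fx, fy, fz) {
  rng <- function(f, n) {
    lo <- max(1L, as.integer(ceiling(f[1] * n)))
    hi <- min(n, as.integer(floor(f[2] * n)))
    if (hi < lo) lo <- hi <- max(1L, min(n, lo))
    lo:hi
  }
  as.matrix(expand.grid(x = rng(fx, grid[1]), y = rng(fy, grid[2]),
                        z = rng(fz, grid[3]), KEEP.OUT.ATTRS = FALSE))
}

#' Default region geometry for a given grid
#'
#' Places desk-scale axial boxes for the LC (pons level) and SN-VTA
#' (midbrain level) with their white-matter reference regions and a
#' hyperintense fourth-ventricle box adjacent to the LC. The LC/SN-VTA
#' *masks* are slightly dilated versions of the true signal boxes; on
#' default-sized grids the LC masks overlap the ventricle, which is what the
#' exclusion mask protects against.
#'
#' @param grid integer vector of 3 voxel counts.
#' @return named list of voxel-coordinate matrices.
#' @export
default_roi_geometry <- function(grid) {
  b <- function(fx, fy, fz) frac_box(grid, fx, fy, fz)
  list(
    lc_left        = b(c(.36, .41), c(.40, .44), c(.52, .62)),
    lc_right       = b(c(.59, .64), c(.40, .44), c(.52, .62)),
    lc_left_mask   = b(c(.36, .46), c(.34, .44), c(.52, .62)),
    lc_right_mask  = b(c(.54, .64), c(.34, .44), c(.52, .62)),
    pontine_ref    = b(c(.44, .56), c(.50, .60), c(.52, .62)),
    snvta_left     = b(c(.34, .40), c(.46, .51), c(.74, .80)),
    snvta_right    = b(c(.60, .66), c(.46, .51), c(.74, .80)),
    snvta_left_mask  = b(c(.34, .40), c(.46, .51), c(.74, .80)),
    snvta_right_mask = b(c(.60, .66), c(.46, .51), c(.74, .80)),
    crus_ref       = b(c(.44, .56), c(.58, .66), c(.74, .80)),
    ventricle      = b(c(.44, .56), c(.28, .36), c(.47, .65))
  )
}

check_psd <- function(m, what) {
  if (any(abs(m - t(m)) > 1e-8)) stop(what, " covariance is not symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("invalid covariance matrix in block '", what,
         "': smallest eigenvalue ", format(min(ev)))
  invisible(TRUE)
}

coords_key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")

#' Create a simulation configuration
#'
#' All arguments have defaults stating the emulated study's conditions; any
#' can be overridden. Validation enforces the configuration invariants:
#' nonnegative variances, positive semi-definite covariance blocks, disjoint
#' signal/reference geometry and availability probabilities in `[0, 1]`.
#'
#' @param n_young,n_old group sizes.
#' @param grid_shape voxel counts for the common-space grid.
#' @param roi_geometry voxel coordinate sets; see [default_roi_geometry()].
#' @param modality_params per-modality rendering parameters: `gain`
#'   (ratio units per latent unit), `roi_offset` (target contrast ratio at
#'   latent = 0), `ref_mean` (reference intensity in scanner units),
#'   `noise_sd` (voxelwise noise, scanner units) and `specific_sd`
#'   (modality-specific true-score noise, latent units).
#' @param cognitive_loadings task table mapping each of the 10 tasks to one
#'   of the factors `wm`, `em`, `gf` with loading, intercept, residual sd.
#' @param factor_moments per age group latent means/covariance at TP1.
#' @param change_model per-latent change mean/variance, covariance with
#'   baseline, linear age slope on change, plus a cross-construct residual
#'   correlation matrix.
#' @param availability per-(modality, timepoint) inclusion probabilities.
#' @param seed integer master seed.
#' @return an object of class `catena_sim_config`.
#' @export
simulation_config <- function(n_young = 69, n_old = 251,
                              grid_shape = c(40L, 50L, 60L),
                              roi_geometry = NULL,
                              modality_params = default_modality_params(),
                              cognitive_loadings = default_cognitive_loadings(),
                              factor_moments = default_factor_moments(),
                              change_model = default_change_model(),
                              availability = default_availability(),
                              seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            n_young >= 0, n_old >= 0, n_young + n_old >= 1)
  if (is.null(roi_geometry)) roi_geometry <- default_roi_geometry(grid_shape)

  for (m in names(modality_params)) {
    p <- modality_params[[m]]
    if (p$noise_sd < 0 || p$specific_sd < 0 || p$ref_mean <= 0)
      stop("invalid modality_params for ", m)
  }
  if (!setequal(names(modality_params), MODALITIES))
    stop("modality_params must cover exactly: ", paste(MODALITIES, collapse = ", "))

  bad <- setdiff(cognitive_loadings$factor, c("wm", "em", "gf"))
  if (length(bad))
    stop("cognitive task mapped to unknown factor: ", paste(bad, collapse = ", "))
  if (any(cognitive_loadings$residual_sd < 0))
    stop("residual_sd must be >= 0")

  for (g in names(factor_moments))
    check_psd(factor_moments[[g]]$cov, paste0("factor_moments$", g))
  check_psd(change_model$residual_cor, "change_model$residual_cor")
  for (l in SIM_LATENTS) {
    if (change_model[[l]]$var < 0) stop("change variance < 0 for ", l)
    if (factor_moments$younger$cov[l, l] < 0) stop("variance < 0 for ", l)
  }

  pr <- unlist(availability)
  if (any(pr < 0 | pr > 1)) stop("availability probabilities must be in [0, 1]")

  # signal boxes, references and ventricle must be pairwise disjoint
  hard <- c("lc_left", "lc_right", "snvta_left", "snvta_right",
            "pontine_ref", "crus_ref", "ventricle")
  keys <- lapply(roi_geometry[hard], coords_key)
  for (i in seq_along(hard)) for (j in seq_len(i - 1L)) {
    if (length(intersect(keys[[i]], keys[[j]])))
      stop("geometry overlap between ", hard[i], " and ", hard[j])
  }
  # masks may be dilated but never into the reference regions
  for (r in c("lc", "snvta")) {
    ref <- if (r == "lc") "pontine_ref" else "crus_ref"
    for (h in c("left", "right")) {
      mk <- coords_key(roi_geometry[[paste0(r, "_", h, "_mask")]])
      if (length(intersect(mk, coords_key(roi_geometry[[ref]]))))
        stop("geometry overlap between ", r, "_", h, "_mask and ", ref)
    }
  }

  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 grid_shape = grid_shape, roi_geometry = roi_geometry,
                 modality_params = modality_params,
                 cognitive_loadings = cognitive_loadings,
                 factor_moments = factor_moments,
                 change_model = change_model,
                 availability = availability,
                 seed = as.integer(seed)),
            class = "catena_sim_config")
}

#' Read a simulation configuration from a JSON file
#'
#' Accepts any subset of the serializable [simulation_config()] fields
#' (`n_young`, `n_old`, `grid_shape`, `seed`, `modality_params`,
#' `availability`); unspecified fields keep their defaults. A `seed`
#' argument overrides the file's seed (the CLI's `--seed` flag).
#'
#' @param path JSON file.
#' @param seed optional seed override.
#' @return a validated `catena_sim_config`.
#' @export
read_sim_config_json <- function(path, seed = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("n_young", "n_old", "grid_shape", "seed"))
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  if (!is.null(x$modality_params))
    args$modality_params <- modifyList(default_modality_params(),
                                       x$modality_params)
  if (!is.null(x$availability)) {
    av <- default_availability()
    for (m in names(x$availability))
      av[[m]][names(x$availability[[m]])] <- unlist(x$availability[[m]])
    args$availability <- av
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(simulation_config, args)
}

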