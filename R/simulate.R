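# Synthetic cohort generation from a fully known latent ground truth.
#
# Every downstream stage (ratio extraction, SEM fitting) is testable against
# this generator. The rendering model is multiplicative on the reference
# intensity: ROI voxels carry ref_mean * (1 + roi_offset + gain * latent),
# reference voxels ref_mean, so the noiseless target contrast ratio
# (max(ROI) - max(Ref)) / max(Ref) equals roi_offset + gain * latent and is
# analytically known.

AGE_MOMENTS <- list(younger = c(mean = 32.7, sd = 3.9),
                    older = c(mean = 72.4, sd = 4.0))
BACKGROUND_FRAC <- 0.7   # background intensity relative to ref_mean
VENTRICLE_FRAC <- 1.5    # ventricle artifact intensity (MT+ / MT- only)
FSE_FOV_FRAC <- 0.68     # FSE covers only the brainstem: slices above are 0

# Deterministic per-participant substreams: adding participants never
# perturbs earlier ones, and purposes (latents, volumes, scores, dropout)
# draw from separate streams.
substream_seed <- function(master, i, purpose) {
  p <- c(latents = 1L, volumes = 2L, cognitive = 3L, roivol = 4L,
         missing = 5L)[[purpose]]
  as.integer((as.double(master) * 48271 + i * 30269 + p * 7919) %% 2147483629)
}

chol_psd <- function(S) {
  # transposed eigen factor: works for PSD matrices with zero eigenvalues
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Generate the latent ground truth for a cohort
#'
#' @param config a [simulation_config()].
#' @return a `catena_truth` object: participant table (id, group, age),
#'   latent scores per construct and timepoint, modality-specific true
#'   scores, analytic noiseless contrast ratios and task true scores.
#' @export
generate_ground_truth <- function(config) {
  n <- config$n_young + config$n_old
  ids <- sprintf("p%05d", seq_len(n))
  group <- rep(c("younger", "older"), c(config$n_young, config$n_old))

  lat1 <- lat2 <- lat3 <- matrix(NA_real_, n, 6,
                                 dimnames = list(ids, SIM_LATENTS))
  age <- numeric(n)
  cm <- config$change_model
  Dch <- sqrt(vapply(SIM_LATENTS, function(l) cm[[l]]$var, 0))
  Sch <- diag(Dch) %*% cm$residual_cor %*% diag(Dch)
  Lch <- chol_psd(Sch)
  L1g <- lapply(config$factor_moments, function(fm) chol_psd(fm$cov))

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i, "latents"))
    g <- group[i]
    fm <- config$factor_moments[[g]]
    am <- AGE_MOMENTS[[g]]
    age[i] <- rnorm(1, am["mean"], am["sd"])
    lat1[i, ] <- fm$mean + as.numeric(L1g[[g]] %*% rnorm(6))
    agec <- age[i] - am["mean"]
    draw_change <- function(base) {
      mu <- vapply(SIM_LATENTS, function(l) {
        p <- cm[[l]]
        vb <- config$factor_moments[[g]]$cov[l, l]
        beta_b <- if (vb > 0) p$cov_baseline / vb else 0
        p$mean + p$age_slope * agec + beta_b * (base[l] - fm$mean[l])
      }, 0)
      mu + as.numeric(Lch %*% rnorm(6))
    }
    lat2[i, ] <- lat1[i, ] + draw_change(lat1[i, ])
    lat3[i, ] <- lat2[i, ] + draw_change(lat2[i, ])
  }

  latents <- do.call(rbind, lapply(1:3, function(tp) {
    m <- list(lat1, lat2, lat3)[[tp]]
    data.frame(participant = rep(ids, 6), latent = rep(SIM_LATENTS, each = n),
               timepoint = tp, value = as.numeric(m), stringsAsFactors = FALSE)
  }))

  # modality-specific true scores for the imaging timepoints
  mt <- expand.grid(participant = ids, region = REGIONS,
                    modality = MODALITIES, timepoint = 1:2,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mt <- mt[order(mt$participant, mt$region, mt$modality, mt$timepoint), ]
  rownames(mt) <- NULL
  spec_sd <- vapply(config$modality_params, `[[`, 0, "specific_sd")
  mt$value <- NA_real_
  mt_rows <- split(seq_len(nrow(mt)), mt$participant)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i, "latents") + 1L)
    rows <- mt_rows[[ids[i]]]
    base <- ifelse(mt$timepoint[rows] == 1L,
                   lat1[i, mt$region[rows]], lat2[i, mt$region[rows]])
    mt$value[rows] <- base +
      rnorm(length(rows)) * spec_sd[mt$modality[rows]]
  }
  gain <- vapply(config$modality_params, `[[`, 0, "gain")
  offset <- vapply(config$modality_params, `[[`, 0, "roi_offset")
  expected_ratio <- mt
  expected_ratio$value <- offset[mt$modality] + gain[mt$modality] * mt$value

  cl <- config$cognitive_loadings
  tt <- expand.grid(participant = ids, task = cl$task, timepoint = 1:3,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tt <- merge(tt, cl, by = "task")
  lat_mat <- rbind(lat1, lat2, lat3)
  row_key <- paste(rep(ids, 3), rep(1:3, each = n))
  fac_val <- lat_mat[cbind(match(paste(tt$participant, tt$timepoint), row_key),
                           match(tt$factor, colnames(lat_mat)))]
  tt$true_score <- tt$intercept + tt$loading * fac_val
  task_truth <- tt[order(tt$participant, tt$timepoint, tt$task),
                   c("participant", "task", "factor", "timepoint", "true_score")]
  rownames(task_truth) <- NULL

  structure(list(
    participants = data.frame(participant = ids, group = group, age = age,
                              stringsAsFactors = FALSE),
    latents = latents, modality_truth = mt, expected_ratio = expected_ratio,
    task_truth = task_truth, seed = config$seed), class = "catena_truth")
}

# All structural volume keys for a cohort (before availability dropout):
# MT+/MT- at TP1 and TP2, FSE only at TP2 with two acquisitions.
volume_keys <- function(truth) {
  unlist(lapply(truth$participants$participant, function(pid) {
    c(sprintf("sub-%s_tp-%d_mod-%s_acq-1", pid, rep(1:2, each = 2),
              c("mtplus", "mtminus")),
      sprintf("sub-%s_tp-2_mod-fse_acq-%d", pid, 1:2))
  }))
}

render_one_volume <- function(config, modality, latent_by_region, participant,
                              timepoint, acquisition) {
  if (any(!is.finite(unlist(latent_by_region))))
    stop("generation error: non-finite latent score for participant ",
         participant)
  p <- config$modality_params[[modality]]
  geo <- config$roi_geometry
  grid <- config$grid_shape
  arr <- array(BACKGROUND_FRAC * p$ref_mean, dim = grid)
  arr[geo$pontine_ref] <- p$ref_mean
  arr[geo$crus_ref] <- p$ref_mean
  roi_val <- function(region)
    p$ref_mean * (1 + p$roi_offset + p$gain * latent_by_region[[region]])
  arr[geo$lc_left] <- roi_val("lc"); arr[geo$lc_right] <- roi_val("lc")
  arr[geo$snvta_left] <- roi_val("snvta"); arr[geo$snvta_right] <- roi_val("snvta")
  if (modality %in% c("mtplus", "mtminus"))
    arr[geo$ventricle] <- VENTRICLE_FRAC * p$ref_mean
  if (p$noise_sd > 0)
    arr <- arr + array(rnorm(prod(grid), 0, p$noise_sd), dim = grid)
  arr[arr < 0] <- 0
  if (modality == "fse")
    arr[, , seq_len(grid[3]) > floor(FSE_FOV_FRAC * grid[3])] <- 0
  brain_volume(arr, modality, participant, timepoint, acquisition)
}

#' Render all imaging volumes for one participant
#'
#' Applies the structural acquisition rules: MT+ and MT- at TP1 and TP2,
#' FSE only at TP2 with two acquisitions sharing the same true score but
#' independent noise.
#'
#' @param truth a `catena_truth` object.
#' @param participant participant id.
#' @param config the [simulation_config()].
#' @return named list of [brain_volume()] objects, keyed
#'   `sub-<id>_tp-<t>_mod-<modality>_acq-<a>`.
#' @export
render_participant_volumes <- function(truth, participant, config) {
  i <- match(participant, truth$participants$participant)
  if (is.na(i)) stop("unknown participant: ", participant)
  set.seed(substream_seed(config$seed, i, "volumes"))
  mt <- truth$modality_truth
  vols <- list()
  for (tp in 1:2) for (m in MODALITIES) {
    if (m == "fse" && tp == 1L) next
    n_acq <- if (m == "fse") 2L else 1L
    lat <- lapply(setNames(REGIONS, REGIONS), function(r)
      mt$value[mt$participant == participant & mt$region == r &
               mt$modality == m & mt$timepoint == tp])
    for (a in seq_len(n_acq)) {
      key <- sprintf("sub-%s_tp-%d_mod-%s_acq-%d", participant, tp, m, a)
      vols[[key]] <- render_one_volume(config, m, lat, participant, tp, a)
    }
  }
  vols
}

#' Generate task-level cognitive scores from the ground truth
#'
#' Scores follow `intercept + loading * factor + residual`. TP3 rows exist
#' only for older adults (the emulated study tested only older adults at
#' TP3).
#'
#' @param truth a `catena_truth` object.
#' @param config the [simulation_config()].
#' @return data frame: participant, task, timepoint, score.
#' @export
generate_cognitive_scores <- function(truth, config) {
  bad <- setdiff(config$cognitive_loadings$factor, c("wm", "em", "gf"))
  if (length(bad)) stop("task mapped to unknown factor: ", bad[1])
  tt <- truth$task_truth
  keep <- tt$timepoint < 3L |
    truth$participants$group[match(tt$participant,
                                   truth$participants$participant)] == "older"
  tt <- tt[keep, ]
  cl <- config$cognitive_loadings
  rsd <- setNames(cl$residual_sd, cl$task)
  tt$score <- NA_real_
  tt_rows <- split(seq_len(nrow(tt)), tt$participant)
  for (i in seq_len(nrow(truth$participants))) {
    pid <- truth$participants$participant[i]
    rows <- tt_rows[[pid]]
    if (is.null(rows)) next
    set.seed(substream_seed(config$seed, i, "cognitive"))
    tt$score[rows] <- tt$true_score[rows] +
      rnorm(length(rows)) * rsd[tt$task[rows]]
  }
  out <- tt[, c("participant", "task", "timepoint", "score")]
  rownames(out) <- NULL
  out
}

generate_roi_volumes <- function(truth, config) {
  base <- c(hippocampus = 3.5, parahippocampus = 2.0)
  n <- nrow(truth$participants)
  out <- expand.grid(participant = truth$participants$participant,
                     region = names(base), hemisphere = HEMISPHERES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$participant, out$region, out$hemisphere), ]
  rownames(out) <- NULL
  lat <- truth$latents
  mtl2 <- lat$value[lat$latent == "mtl" & lat$timepoint == 2L]
  names(mtl2) <- lat$participant[lat$latent == "mtl" & lat$timepoint == 2L]
  out$raw_volume <- NA_real_
  out$tiv <- NA_real_
  out_rows <- split(seq_len(nrow(out)), out$participant)
  for (i in seq_len(n)) {
    pid <- truth$participants$participant[i]
    set.seed(substream_seed(config$seed, i, "roivol"))
    tiv <- rnorm(1, 1450, 130)
    rows <- out_rows[[pid]]
    b <- base[out$region[rows]]
    out$raw_volume[rows] <- b * (1 + 0.05 * mtl2[pid]) +
      rnorm(length(rows), 0, 0.15)
    out$tiv[rows] <- tiv
  }
  out
}

#' Remove volumes and scores at the configured availability rates
#'
#' Missingness is completely at random per (participant, modality,
#' timepoint); structural rules (no FSE at TP1, no younger-adult TP3
#' cognition) are already built into the cohort and never violated here.
#' The ground truth is untouched.
#'
#' @param cohort a `catena_cohort`.
#' @param config the [simulation_config()].
#' @return the cohort with unavailable volumes removed and unavailable
#'   cognitive scores set to `NA`.
#' @export
inject_missingness <- function(cohort, config) {
  av <- config$availability
  ids <- cohort$truth$participants$participant
  drop_keys <- character(0)
  cg_rows <- if (!is.null(cohort$cognitive))
    split(seq_len(nrow(cohort$cognitive)),
          paste(cohort$cognitive$participant, cohort$cognitive$timepoint))
  for (i in seq_along(ids)) {
    set.seed(substream_seed(config$seed, i, "missing"))
    for (m in MODALITIES) for (tp in 1:2) {
      p <- unname(av[[m]][paste0("tp", tp)])
      if (is.na(p)) p <- 1
      u <- runif(1)
      if (u > p)
        drop_keys <- c(drop_keys,
                       sprintf("sub-%s_tp-%d_mod-%s_acq-", ids[i], tp, m))
    }
    if (!is.null(cohort$cognitive) && !is.null(av$cognitive)) {
      for (tp in 1:3) {
        p <- unname(av$cognitive[paste0("tp", tp)])
        if (is.na(p)) p <- 1
        u <- runif(1)
        if (u > p) {
          rows <- cg_rows[[paste(ids[i], tp)]]
          if (!is.null(rows)) cohort$cognitive$score[rows] <- NA_real_
        }
      }
    }
  }
  if (length(cohort$volumes) && length(drop_keys)) {
    keys <- names(cohort$volumes)
    hit <- Reduce(`|`, lapply(drop_keys, function(k) startsWith(keys, k)))
    cohort$volumes <- cohort$volumes[!hit]
  }
  cohort
}

#' Simulate a full synthetic cohort
#'
#' @param config a [simulation_config()].
#' @param render_volumes render in-memory brain volumes (set `FALSE` for
#'   large cohorts where only tables are needed; volumes can still be
#'   rendered per participant with [render_participant_volumes()]).
#' @param apply_missingness apply [inject_missingness()] before returning.
#' @return a `catena_cohort`: volumes, masks, cognitive scores, ROI-volume
#'   table and the `catena_truth` ground truth.
#' @export
simulate_cohort <- function(config, render_volumes = TRUE,
                            apply_missingness = TRUE) {
  truth <- generate_ground_truth(config)
  vols <- list()
  if (render_volumes)
    for (pid in truth$participants$participant)
      vols <- c(vols, render_participant_volumes(truth, pid, config))
  cohort <- structure(list(
    volumes = vols,
    masks = masks_from_geometry(config$roi_geometry, config$grid_shape),
    cognitive = generate_cognitive_scores(truth, config),
    roi_volumes = generate_roi_volumes(truth, config),
    truth = truth, config = config), class = "catena_cohort")
  if (apply_missingness) cohort <- inject_missingness(cohort, config)
  cohort
}

#' @export
print.catena_cohort <- function(x, ...) {
  cat(sprintf("<catena_cohort> n=%d (%d younger, %d older), %d volumes, grid %s\n",
              nrow(x$truth$participants), x$config$n_young, x$config$n_old,
              length(x$volumes), paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk in interchange formats
#'
#' Volumes and masks are written as gzipped NIfTI-1; tables as CSV; the
#' configuration echo as JSON.
#'
#' @param cohort a `catena_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(dir, "tables"), showWarnings = FALSE)
  for (key in names(cohort$volumes))
    write_nifti(cohort$volumes[[key]]$data,
                file.path(dir, "volumes", paste0(key, ".nii.gz")))
  for (r in names(cohort$masks)) {
    ms <- cohort$masks[[r]]
    for (part in c("roi_left", "roi_right", "reference"))
      write_nifti(ms[[part]] + 0,
                  file.path(dir, "masks", sprintf("%s_%s.nii.gz", r, part)))
    if (!is.null(ms$exclusion))
      write_nifti(ms$exclusion + 0,
                  file.path(dir, "masks", sprintf("%s_exclusion.nii.gz", r)))
  }
  write.csv(cohort$cognitive, file.path(dir, "tables", "cognitive.csv"),
            row.names = FALSE)
  write.csv(cohort$roi_volumes, file.path(dir, "tables", "roi_volumes.csv"),
            row.names = FALSE)
  write.csv(cohort$truth$participants,
            file.path(dir, "tables", "participants.csv"), row.names = FALSE)
  write.csv(cohort$truth$latents, file.path(dir, "tables", "truth_latents.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  echo <- list(n_young = cfg$n_young, n_old = cfg$n_old,
               grid_shape = cfg$grid_shape, seed = cfg$seed,
               modality_params = cfg$modality_params,
               availability = cfg$availability,
               n_geometry_voxels = vapply(cfg$roi_geometry, nrow, 0L))
  jsonlite::write_json(echo, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
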