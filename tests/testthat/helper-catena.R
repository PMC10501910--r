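# Shared fixtures and independent oracles for the test suite.

tiny_config <- function(n_young = 3, n_old = 3, seed = 7, ...) {
  simulation_config(n_young = n_young, n_old = n_old,
                    grid_shape = c(20, 24, 30), seed = seed, ...)
}

# Independent brute-force oracle for peak-ratio extraction: exhaustive
# loops over every voxel of every slice, no shared code with
# extract_peak_ratio beyond the ratio formula itself.
bf_peak_ratio <- function(vol, roi, ref, exclusion = NULL) {
  dm <- dim(vol)
  best <- -Inf; n_used <- 0L
  for (z in seq_len(dm[3])) {
    roi_peak <- -Inf; ref_peak <- -Inf
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) {
      if (!is.null(exclusion) && exclusion[x, y, z]) next
      v <- vol[x, y, z]
      if (is.na(v)) next
      if (roi[x, y, z] && v > roi_peak) roi_peak <- v
      if (ref[x, y, z] && v > ref_peak) ref_peak <- v
    }
    if (is.finite(roi_peak) && is.finite(ref_peak) && ref_peak > 0) {
      n_used <- n_used + 1L
      r <- (roi_peak - ref_peak) / ref_peak
      if (r > best) best <- r
    }
  }
  if (!is.finite(best)) return(NULL)
  list(peak_ratio = best, n_slices_used = n_used)
}

# random volume + disjoint random masks on a small grid
random_volume_case <- function(seed, dm = c(12, 12, 10)) {
  set.seed(seed)
  vol <- array(runif(prod(dm), 10, 200), dim = dm)
  idx <- sample(prod(dm))
  n_roi <- 40; n_ref <- 60
  roi <- array(FALSE, dm); roi[idx[seq_len(n_roi)]] <- TRUE
  ref <- array(FALSE, dm); ref[idx[n_roi + seq_len(n_ref)]] <- TRUE
  excl <- array(runif(prod(dm)) < 0.05, dm)
  list(vol = vol, roi = roi, ref = ref, excl = excl)
}

as_bvol <- function(arr, modality = "mtplus", participant = "t1",
                    timepoint = 1L) {
  brain_volume(arr, modality, participant, timepoint)
}

as_masks <- function(roi_left, ref, roi_right = NULL, exclusion = NULL,
                     region = "lc") {
  if (is.null(roi_right)) roi_right <- roi_left
  mask_set(roi_left, roi_right, ref, exclusion = exclusion, region = region)
}

# small, well-identified two-factor spec used across engine tests;
# loadings fixed (2 indicators per factor) so every block is identified
two_factor_spec <- function(psi = 0.4) {
  sem_spec(
    observed = c("y1", "y2", "y3", "y4"), latent = c("f1", "f2"),
    entries = rbind(
      ent("loading", "f1", "y1", free = FALSE, value = 1),
      ent("loading", "f1", "y2", free = FALSE, value = 1),
      ent("loading", "f2", "y3", free = FALSE, value = 1),
      ent("loading", "f2", "y4", free = FALSE, value = 1),
      ent("variance", "f1", value = 1.0),
      ent("variance", "f2", value = 0.8),
      ent("covariance", "f1", "f2", value = psi),
      ent("variance", "y1", value = 0.5), ent("variance", "y2", value = 0.5),
      ent("variance", "y3", value = 0.5), ent("variance", "y4", value = 0.5),
      ent("mean", "y1", value = 0.5), ent("mean", "y2", value = -0.2),
      ent("mean", "y3", value = 0), ent("mean", "y4", value = 1)))
}

fix_entry <- function(spec, kind, from, to, value = 0) {
  k <- spec$entries$kind == kind & spec$entries$from == from &
    spec$entries$to == to
  spec$entries$free[k] <- FALSE
  spec$entries$value[k] <- value
  spec$entries$label[k] <- ""
  spec
}

set_entry_value <- function(spec, kind, from, to, value) {
  k <- spec$entries$kind == kind & spec$entries$from == from &
    spec$entries$to == to
  spec$entries$value[k] <- value
  spec
}

# one-factor three-indicator multi-group spec for invariance ladders
ladder_spec <- function(groups = c("g1", "g2"),
                        loadings = c(1, 0.9, 1.1),
                        loadings2 = loadings) {
  mk <- function(gp, lds) rbind(
    ent("loading", "f", "y1", free = FALSE, value = 1, group = gp),
    ent("loading", "f", "y2", value = lds[2], group = gp),
    ent("loading", "f", "y3", value = lds[3], group = gp),
    ent("variance", "f", value = 1, group = gp),
    ent("variance", "y1", value = 0.5, group = gp),
    ent("variance", "y2", value = 0.5, group = gp),
    ent("variance", "y3", value = 0.5, group = gp),
    ent("mean", "y1", value = 0, group = gp),
    ent("mean", "y2", value = 0.2, group = gp),
    ent("mean", "y3", value = -0.1, group = gp))
  sem_spec(c("y1", "y2", "y3"), "f",
           rbind(mk(groups[1], loadings), mk(groups[2], loadings2)),
           groups = groups)
}

# the same measurement model in the "all"-group unlabelled form that
# invariance_ladder() expects
ladder_spec_all <- function(groups = c("g1", "g2")) {
  sem_spec(c("y1", "y2", "y3"), "f", rbind(
    ent("loading", "f", "y1", free = FALSE, value = 1),
    ent("loading", "f", "y2", value = 0.9),
    ent("loading", "f", "y3", value = 1.1),
    ent("variance", "f", value = 1),
    ent("variance", "y1", value = 0.5),
    ent("variance", "y2", value = 0.5),
    ent("variance", "y3", value = 0.5),
    ent("mean", "y1", value = 0),
    ent("mean", "y2", value = 0.2),
    ent("mean", "y3", value = -0.1)), groups = groups)
}

sim_options <- list(starts = 1L, se = FALSE)
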