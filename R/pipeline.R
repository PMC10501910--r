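# Pipeline orchestration: simulate -> extract -> fit -> report, with plain
# CSV/JSON/NIfTI artifacts per stage, a reproducible manifest, and
# committed-size fixture generation. A single top-level seed derives all
# stage seeds deterministically.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param sim a [simulation_config()] (the demo default simulates 60
#'   participants on the full-size grid).
#' @param families model families fitted by the `fit` stage.
#' @param seed top-level seed; overrides `sim$seed` and derives stage seeds.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `catena_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(n_young = 20, n_old = 40),
                            families = c("modality", "multimodal",
                                         "cognitive", "neurocog"),
                            seed = 42L, log_level = "info") {
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, sim = sim, families = families,
                 seed = as.integer(seed), log_level = log_level),
            class = "catena_pipeline_config")
}

plog <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[catena] ", ...)
}

parse_volume_name <- function(fn) {
  m <- regmatches(fn, regexec(
    "^sub-(.+)_tp-([0-9]+)_mod-(mtplus|mtminus|fse)_acq-([0-9]+)\\.nii(\\.gz)?$",
    fn))[[1]]
  if (!length(m)) return(NULL)
  list(participant = m[2], timepoint = as.integer(m[3]), modality = m[4],
       acquisition = as.integer(m[5]))
}

#' Read the mask set for a region from a masks directory
#'
#' Expects `<region>_roi_left/roi_right/reference[.nii.gz]` and an optional
#' `<region>_exclusion` volume, as written by [write_cohort()].
#'
#' @param dir masks directory.
#' @param region `"lc"` or `"snvta"`.
#' @return a [mask_set()].
#' @export
read_mask_set <- function(dir, region = c("lc", "snvta")) {
  region <- match.arg(region)
  rd <- function(part, required = TRUE) {
    for (sfx in c(".nii.gz", ".nii")) {
      p <- file.path(dir, sprintf("%s_%s%s", region, part, sfx))
      if (file.exists(p)) return(read_nifti(p))
    }
    if (required) stop("mask not found: ", region, "_", part, " in ", dir)
    NULL
  }
  mask_set(rd("roi_left"), rd("roi_right"), rd("reference"),
           exclusion = rd("exclusion", required = FALSE), region = region)
}

#' Extract ratios from a directory of volumes
#'
#' Reads every file matching the
#' `sub-<id>_tp-<t>_mod-<modality>_acq-<a>.nii.gz` pattern, applies the
#' exclusion mask (MT scans only, unless disabled), extracts per-hemisphere
#' peak ratios and averages FSE acquisitions. Files are processed in sorted
#' order so the result is independent of directory listing order.
#'
#' @param volumes_dir directory of NIfTI volumes.
#' @param masks a [mask_set()] or masks directory.
#' @param region `"lc"` or `"snvta"`.
#' @param use_exclusion apply the exclusion mask.
#' @return raw ratio table (see [extract_cohort_ratios()]).
#' @export
extract_dir_ratios <- function(volumes_dir, masks, region = c("lc", "snvta"),
                               use_exclusion = TRUE) {
  region <- match.arg(region)
  if (is.character(masks)) masks <- read_mask_set(masks, region)
  files <- sort(list.files(volumes_dir, pattern = "^sub-.*\\.nii(\\.gz)?$"))
  rows <- list()
  for (fn in files) {
    meta <- parse_volume_name(fn)
    if (is.null(meta)) next
    if (region == "snvta" && meta$modality == "fse") next
    vol <- brain_volume(read_nifti(file.path(volumes_dir, fn)),
                        meta$modality, meta$participant, meta$timepoint,
                        meta$acquisition)
    v <- if (use_exclusion) apply_exclusion(vol, masks$exclusion) else vol
    for (h in HEMISPHERES) {
      ex <- extract_peak_ratio(v, masks, h)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = meta$participant, region = region,
        modality = meta$modality, hemisphere = h,
        timepoint = meta$timepoint, acquisition = meta$acquisition,
        value = ex$peak_ratio, n_slices_used = ex$n_slices_used,
        peak_slice = ex$peak_slice, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no volumes found in ", volumes_dir)
  average_fse_acquisitions(do.call(rbind, rows))
}

pivot_wide <- function(df, ids, names, value = "value") {
  nm <- do.call(paste, c(df[names], sep = "_"))
  out <- data.frame(participant = sort(unique(df[[ids]])),
                    stringsAsFactors = FALSE)
  for (v in sort(unique(nm))) {
    sub <- df[nm == v, ]
    out[[v]] <- sub[[value]][match(out$participant, sub[[ids]])]
  }
  out
}

#' Assemble the wide modeling table from pipeline tables
#'
#' Produces one row per participant with cleaned, scaled neural indicators
#' (per hemisphere and hemisphere-averaged), cognitive task scores,
#' adjusted regional volumes, age and group, named by the convention the
#' model builders use.
#'
#' @param ratio_tables named list (by region) of cleaned ratio tables.
#' @param cognitive cognitive score table.
#' @param participants participant table (participant, group, age).
#' @param roi_volumes optional adjusted volume table (from
#'   [adjust_volumes()]).
#' @return wide data frame keyed by participant.
#' @export
assemble_model_data <- function(ratio_tables, cognitive, participants,
                                roi_volumes = NULL) {
  out <- participants
  for (region in names(ratio_tables)) {
    rt <- ratio_tables[[region]]
    rt$tp <- paste0("tp", rt$timepoint)
    w <- pivot_wide(rt, "participant",
                    c("region", "modality", "hemisphere", "tp"))
    out <- merge(out, w, by = "participant", all.x = TRUE)
    ha <- hemisphere_average(rt)
    ha$tp <- paste0("tp", ha$timepoint)
    w2 <- pivot_wide(ha, "participant", c("region", "modality", "tp"))
    out <- merge(out, w2, by = "participant", all.x = TRUE)
  }
  cg <- cognitive
  cg$tp <- paste0("tp", cg$timepoint)
  wc <- pivot_wide(cg, "participant", c("task", "tp"), value = "score")
  out <- merge(out, wc, by = "participant", all.x = TRUE)
  if (!is.null(roi_volumes)) {
    wv <- pivot_wide(roi_volumes, "participant", c("region", "hemisphere"),
                     value = "adjusted_volume")
    out <- merge(out, wv, by = "participant", all.x = TRUE)
  }
  out[order(out$participant), ]
}

#' Assemble the modeling table directly from an in-memory cohort
#'
#' Runs extraction, cleaning/scaling and volume adjustment on a rendered
#' cohort and returns the wide modeling table.
#'
#' @param cohort a `catena_cohort` with volumes.
#' @param regions regions to extract.
#' @param use_exclusion apply the ventricle exclusion mask.
#' @return wide data frame (see [assemble_model_data()]).
#' @export
cohort_model_data <- function(cohort, regions = c("lc", "snvta"),
                              use_exclusion = TRUE) {
  rts <- lapply(setNames(regions, regions), function(r)
    clean_and_scale(extract_cohort_ratios(cohort, r, use_exclusion)))
  assemble_model_data(rts, cohort$cognitive, cohort$truth$participants,
                      adjust_volumes(cohort$roi_volumes))
}

build_family_spec <- function(family, region = "lc", groups) {
  switch(family,
    modality = build_modality_factor_model(region, groups = groups),
    multimodal = build_multimodal_model(region, groups = groups),
    cognitive = build_cognitive_model(groups = groups),
    neurocog = build_neurocognitive_model("correlation", groups = groups),
    neurocog_regression = build_neurocognitive_model("regression",
                                                     groups = groups),
    stability = build_stability_model(region, groups = NULL),
    lcs = build_latent_change_model(region, groups = NULL),
    prediction = build_prediction_model(region),
    stop("unknown model family: ", family))
}

#' Run the pipeline
#'
#' Executes simulate -> extract -> fit -> report. Each stage writes plain
#' files under `out_dir`; any stage failure halts the run with a manifest
#' recording the failure point. Reruns with the same seed reproduce all
#' CSV/JSON outputs byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (upstream artifacts must exist).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "extract", "fit", "report")) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("catena")),
                   seed = config$seed, stages = list(), status = "ok")
  finalize <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }
  checksums <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    plog(config, "stage: ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- "failed"
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      finalize()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(as.numeric(Sys.time() - t0), 3),
      outputs = checksums(res))
    res
  }

  cohort_dir <- file.path(out, "cohort")
  tables_dir <- file.path(out, "tables")
  fits_dir <- file.path(out, "fits")

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      truth <- generate_ground_truth(config$sim)
      cohort <- structure(list(
        volumes = list(),
        masks = masks_from_geometry(config$sim$roi_geometry,
                                    config$sim$grid_shape),
        cognitive = generate_cognitive_scores(truth, config$sim),
        roi_volumes = generate_roi_volumes(truth, config$sim),
        truth = truth, config = config$sim), class = "catena_cohort")
      cohort <- inject_missingness(cohort, config$sim)
      write_cohort(cohort, cohort_dir)
      # stream volumes one participant at a time to bound memory, then
      # apply the availability pattern by removing dropped files
      vdir <- file.path(cohort_dir, "volumes")
      for (pid in truth$participants$participant) {
        vols <- render_participant_volumes(truth, pid, config$sim)
        for (key in names(vols))
          write_nifti(vols[[key]]$data,
                      file.path(vdir, paste0(key, ".nii.gz")))
      }
      keys <- volume_keys(truth)
      shadow <- structure(list(volumes = setNames(as.list(keys), keys),
                               truth = truth, cognitive = NULL,
                               config = config$sim),
                          class = "catena_cohort")
      shadow <- inject_missingness(shadow, config$sim)
      gone <- setdiff(keys, names(shadow$volumes))
      unlink(file.path(vdir, paste0(gone, ".nii.gz")))
      list.files(cohort_dir, recursive = TRUE, full.names = TRUE)
    })
  }

  if ("extract" %in% stages) {
    run_stage("extract", function() {
      vdir <- file.path(cohort_dir, "volumes")
      mdir <- file.path(cohort_dir, "masks")
      if (!dir.exists(vdir))
        stop("dependency error: no volumes; run the simulate stage first")
      dir.create(tables_dir, showWarnings = FALSE)
      outs <- character(0)
      for (region in c("lc", "snvta")) {
        raw <- extract_dir_ratios(vdir, mdir, region)
        cleaned <- clean_and_scale(raw)
        p_raw <- file.path(tables_dir, paste0("ratios_raw_", region, ".csv"))
        p_cl <- file.path(tables_dir, paste0("ratios_", region, ".csv"))
        write.csv(raw, p_raw, row.names = FALSE)
        write_ratio_table(cleaned, p_cl)
        n_drop <- sum(cleaned$dropped)
        if (n_drop)
          plog(config, "  dropped ", n_drop, " outlier value(s) for ", region,
               ": ", paste(unique(cleaned$participant[cleaned$dropped]),
                           collapse = ", "))
        outs <- c(outs, p_raw, p_cl)
      }
      outs
    })
  }

  if ("fit" %in% stages) {
    run_stage("fit", function() {
      if (!file.exists(file.path(tables_dir, "ratios_lc.csv")))
        stop("dependency error: no ratio tables; run the extract stage first")
      dir.create(fits_dir, showWarnings = FALSE)
      rts <- lapply(setNames(c("lc", "snvta"), c("lc", "snvta")), function(r) {
        raw <- read.csv(file.path(tables_dir, paste0("ratios_raw_", r, ".csv")))
        clean_and_scale(raw)
      })
      cognitive <- read.csv(file.path(cohort_dir, "tables", "cognitive.csv"))
      participants <- read.csv(file.path(cohort_dir, "tables",
                                         "participants.csv"))
      roi_vol <- adjust_volumes(read.csv(file.path(cohort_dir, "tables",
                                                   "roi_volumes.csv")))
      wide <- assemble_model_data(rts, cognitive, participants, roi_vol)
      write.csv(wide, file.path(tables_dir, "model_data.csv"),
                row.names = FALSE)
      outs <- file.path(tables_dir, "model_data.csv")
      groups <- unique(wide$group)
      for (fam in config$families) {
        # the larger joint models are fitted on older adults only (the
        # emulated study's key comparisons are older-adult models)
        single <- fam %in% c("neurocog", "neurocog_regression", "stability",
                             "lcs", "prediction")
        spec <- build_family_spec(
          fam, "lc", groups = if (!single && length(groups) > 1) groups)
        dat <- if (single) wide[wide$group == "older", ] else wide
        fit <- fit_model(spec, dat,
                         group = if (!single) "group",
                         options = list(seed = config$seed, starts = 2))
        if (!fit$converged)
          plog(config, "  non-converged fit: ", fam)
        p <- file.path(fits_dir, paste0(fam, ".json"))
        write_fit_json(fit, p)
        ps <- file.path(fits_dir, paste0(fam, "_spec.json"))
        write_spec_json(spec, ps)
        outs <- c(outs, p, ps)
      }
      outs
    })
  }

  if ("report" %in% stages) {
    run_stage("report", function() {
      if (!dir.exists(fits_dir) ||
          !file.exists(file.path(tables_dir, "model_data.csv")))
        stop("dependency error: no fits; run the fit stage first")
      wide <- read.csv(file.path(tables_dir, "model_data.csv"))
      # reported comparisons are older-adult single-group models
      older <- wide[wide$group == "older", ]
      spec <- build_neurocognitive_model("correlation", groups = NULL)
      rep <- run_reported_comparisons(spec, older,
                                      options = list(seed = config$seed))
      p <- file.path(out, "report.json")
      jsonlite::write_json(rep$table, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      txt <- file.path(out, "report.txt")
      writeLines(c(sprintf("%-28s %10s %8s %8s  %s", "comparison",
                           "delta_chi2", "delta_df", "p", "verdict"),
                   sprintf("%-28s %10.3f %8d %8.4f  %s",
                           rep$table$comparison, rep$table$delta_chi2,
                           rep$table$delta_df, rep$table$p,
                           rep$table$verdict)), txt)
      c(p, txt)
    })
  }
  finalize()
}

#' Generate a committed-size fixture bundle
#'
#' `tiny` simulates 12 participants on a 16^3 grid (< 5 MB on disk);
#' `demo` simulates 60 on the default grid. Fixtures are written through
#' the same writers (and load through the same readers) as user data.
#'
#' @param size `"tiny"` or `"demo"`.
#' @param dir output directory.
#' @param seed seed for the bundle.
#' @return the cohort directory path, invisibly.
#' @export
make_fixtures <- function(size = c("tiny", "demo"), dir, seed = 7L) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    simulation_config(n_young = 6, n_old = 6, grid_shape = c(16, 16, 16),
                      seed = seed)
  } else {
    simulation_config(n_young = 20, n_old = 40, seed = seed)
  }
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, dir)
  invisible(dir)
}
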