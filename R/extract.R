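# Semiautomatic peak-intensity-ratio assessment.
#
# For each axial slice with usable ROI and reference voxels, the slice
# contrast ratio is (max(ROI) - max(Ref)) / max(Ref); the participant-level
# integrity indicator is the maximum ratio over slices, computed per
# hemisphere. Reference peaks are taken slice-wise (symmetric with the ROI
# peak); excluded voxels are marked unusable (NA), never zeroed, so they
# can never create spurious minima.

#' Mark excluded voxels as unusable for peak search
#'
#' The hyperintense fourth-ventricle artifact is removed from MT+ and MT-
#' scans before value extraction; FSE volumes pass through unchanged.
#'
#' @param volume a [brain_volume()].
#' @param exclusion logical/0-1 3D array on the same grid, or `NULL`.
#' @return the volume with excluded voxels set to `NA`.
#' @export
apply_exclusion <- function(volume, exclusion) {
  stopifnot(inherits(volume, "brain_volume"))
  if (is.null(exclusion) || volume$modality == "fse") return(volume)
  if (!identical(dim(volume$data), dim(exclusion)))
    stop("exclusion mask grid does not match volume grid")
  volume$data[exclusion > 0] <- NA_real_
  volume
}

#' Slice-wise contrast ratio
#'
#' @param roi_peak peak ROI intensity on a slice.
#' @param ref_peak peak reference intensity on the same slice; must be > 0.
#' @return `(roi_peak - ref_peak) / ref_peak`.
#' @export
slice_ratio <- function(roi_peak, ref_peak) {
  if (any(!is.na(ref_peak) & ref_peak <= 0))
    stop("degenerate reference: slice reference peak <= 0")
  (roi_peak - ref_peak) / ref_peak
}

#' Extract the peak intensity ratio for one volume and hemisphere
#'
#' Scans axial slices (third grid axis); on every slice with at least one
#' usable ROI voxel and one usable reference voxel it computes the slice
#' ratio of the slice-wise peaks, then returns the maximum over slices
#' together with the full slice profile.
#'
#' @param volume a [brain_volume()] (run [apply_exclusion()] first if an
#'   exclusion mask applies).
#' @param masks a [mask_set()].
#' @param hemisphere `"left"` or `"right"`.
#' @param ref_peak `"slice"` (default) takes the reference peak per slice,
#'   symmetric with the ROI peak; `"global"` uses the single peak over the
#'   whole reference region for every slice.
#' @return list with `peak_ratio`, `peak_slice`, `n_slices_used` and the
#'   `profile` data frame (slice, roi_peak, ref_peak, ratio).
#' @export
extract_peak_ratio <- function(volume, masks, hemisphere = c("left", "right"),
                               ref_peak = c("slice", "global")) {
  hemisphere <- match.arg(hemisphere)
  ref_peak <- match.arg(ref_peak)
  stopifnot(inherits(volume, "brain_volume"), inherits(masks, "mask_set"))
  if (!identical(dim(volume$data), masks$grid))
    stop("volume grid does not match mask grid")
  roi <- if (hemisphere == "left") masks$roi_left else masks$roi_right
  nz <- dim(volume$data)[3]
  global_ref <- if (ref_peak == "global") {
    vals <- volume$data[masks$reference]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else max(vals)
  }
  prof <- data.frame(slice = seq_len(nz), roi_peak = NA_real_,
                     ref_peak = NA_real_, ratio = NA_real_)
  for (z in seq_len(nz)) {
    sl <- volume$data[, , z]
    roi_vals <- sl[roi[, , z]]
    roi_vals <- roi_vals[!is.na(roi_vals)]
    if (ref_peak == "slice") {
      ref_vals <- sl[masks$reference[, , z]]
      ref_vals <- ref_vals[!is.na(ref_vals)]
      fp <- if (length(ref_vals)) max(ref_vals) else NA_real_
    } else {
      fp <- global_ref
    }
    if (!length(roi_vals) || is.na(fp)) next
    rp <- max(roi_vals)
    prof$roi_peak[z] <- rp
    prof$ref_peak[z] <- fp
    if (fp > 0) prof$ratio[z] <- (rp - fp) / fp
  }
  usable <- which(!is.na(prof$ratio))
  if (!length(usable))
    stop(sprintf(
      "extraction error: no usable slice for participant %s, modality %s, tp %d (%s)",
      volume$participant, volume$modality, volume$timepoint, hemisphere))
  peak <- usable[which.max(prof$ratio[usable])]
  list(peak_ratio = prof$ratio[peak], peak_slice = peak,
       n_slices_used = length(usable), profile = prof)
}

#' Extract ratios for every volume of a cohort
#'
#' Applies the exclusion mask (MT scans only), extracts left and right
#' peak ratios per volume and averages the two FSE acquisitions.
#'
#' @param cohort a `catena_cohort` with rendered volumes.
#' @param region `"lc"` or `"snvta"`.
#' @param use_exclusion apply the ventricle exclusion mask (default TRUE).
#' @return raw ratio table: participant, region, modality, hemisphere,
#'   timepoint, value, n_slices_used, peak_slice, single_acquisition.
#' @export
extract_cohort_ratios <- function(cohort, region = c("lc", "snvta"),
                                  use_exclusion = TRUE) {
  region <- match.arg(region)
  masks <- cohort$masks[[region]]
  rows <- list()
  for (key in names(cohort$volumes)) {
    vol <- cohort$volumes[[key]]
    if (region == "snvta" && vol$modality == "fse") next
    v <- if (use_exclusion) apply_exclusion(vol, masks$exclusion) else vol
    for (h in HEMISPHERES) {
      ex <- extract_peak_ratio(v, masks, h)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = vol$participant, region = region,
        modality = vol$modality, hemisphere = h,
        timepoint = vol$timepoint, acquisition = vol$acquisition,
        value = ex$peak_ratio, n_slices_used = ex$n_slices_used,
        peak_slice = ex$peak_slice, stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, rows)
  if (is.null(raw)) stop("no volumes to extract for region ", region)
  average_fse_acquisitions(raw)
}

#' Average the two FSE acquisitions within participants
#'
#' The two FSE acquisitions per participant are averaged elementwise to
#' obtain more stable estimates; if one acquisition is missing, the other
#' is used and flagged.
#'
#' @param table raw ratio table including an `acquisition` column.
#' @return table keyed (participant, region, modality, hemisphere,
#'   timepoint) with `single_acquisition` flags.
#' @export
average_fse_acquisitions <- function(table) {
  key_cols <- c("participant", "region", "modality", "hemisphere", "timepoint")
  agg <- aggregate(table["value"], table[key_cols], mean, na.rm = TRUE)
  agg$value[is.nan(agg$value)] <- NA_real_
  n_acq <- aggregate(list(n_acq = !is.na(table$value)), table[key_cols], sum)
  ns <- aggregate(table["n_slices_used"], table[key_cols], mean)
  ps <- aggregate(table["peak_slice"], table[key_cols], mean)
  out <- merge(merge(merge(agg, n_acq, by = key_cols), ns, by = key_cols),
               ps, by = key_cols)
  expected <- ifelse(out$modality == "fse", 2L, 1L)
  out$single_acquisition <- out$n_acq < expected
  out$n_acq <- NULL
  out[order(out$participant, out$region, out$modality,
            out$hemisphere, out$timepoint), ]
}

single_pass_outliers <- function(values, k) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) {
    warning("stratum with fewer than 3 values: outlier screening skipped")
    return(rep(FALSE, length(values)))
  }
  m <- mean(values[ok]); s <- sd(values[ok])
  # mean/sd computed once before any removal (single pass); sd = 0 drops none
  ifelse(ok, abs(values - m) > k * s, FALSE)
}

#' Outlier screening and linear scaling of ratio tables
#'
#' Within each stratum (region x modality x hemisphere x timepoint, pooled
#' across age groups by default), values beyond `k` standard deviations of
#' the stratum mean are flagged and dropped; all other values are linearly
#' scaled (x100 by default). Mean and s.d. are computed once, before any
#' removal.
#'
#' @param table ratio table with a `value` column.
#' @param k s.d. multiplier (default 3).
#' @param factor linear scaling factor (default 100).
#' @param strata character vector of stratum columns.
#' @return the table with `value` scaled (NA where dropped) and a logical
#'   `dropped` column.
#' @export
clean_and_scale <- function(table, k = 3, factor = 100,
                            strata = c("region", "modality", "hemisphere",
                                       "timepoint")) {
  stopifnot(k > 0)
  strata <- intersect(strata, names(table))
  key <- if (length(strata)) do.call(paste, table[strata]) else
    rep("all", nrow(table))
  table$dropped <- FALSE
  for (s in unique(key)) {
    idx <- which(key == s)
    table$dropped[idx] <- single_pass_outliers(table$value[idx], k)
  }
  table$value <- ifelse(table$dropped, NA_real_, table$value * factor)
  table
}

#' Average ratios across hemispheres
#'
#' @param table a ratio table with a `hemisphere` column.
#' @return table with one row per (participant, region, modality,
#'   timepoint), `value` the mean of available hemispheres.
#' @export
hemisphere_average <- function(table) {
  key_cols <- intersect(c("participant", "region", "modality", "timepoint"),
                        names(table))
  agg <- aggregate(table["value"], table[key_cols], mean, na.rm = TRUE)
  agg$value[is.nan(agg$value)] <- NA_real_
  agg[order(agg$participant, agg$region, agg$modality, agg$timepoint), ]
}

#' Adjust regional gray-matter volumes
#'
#' Applies the same single-pass +/-`k` s.d. outlier screen per stratum
#' (region x hemisphere), then scales (x10,000) and divides by total
#' intracranial volume.
#'
#' @param table volume table with columns participant, region, hemisphere,
#'   `raw_volume` and `tiv`.
#' @param factor linear scaling factor (default 10000).
#' @param k s.d. multiplier (default 3).
#' @return the table with `adjusted_volume` and `dropped` columns.
#' @export
adjust_volumes <- function(table, factor = 10000, k = 3) {
  if (any(table$tiv <= 0, na.rm = TRUE))
    stop("nonpositive total intracranial volume for participant(s): ",
         paste(unique(table$participant[table$tiv <= 0]), collapse = ", "))
  key <- paste(table$region, table$hemisphere)
  table$dropped <- FALSE
  for (s in unique(key)) {
    idx <- which(key == s)
    table$dropped[idx] <- single_pass_outliers(table$raw_volume[idx], k)
  }
  table$adjusted_volume <- ifelse(table$dropped, NA_real_,
                                  table$raw_volume * factor / table$tiv)
  table
}

#' Write a ratio table as CSV with the interchange column set
#'
#' @param table cleaned ratio table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(table, path) {
  cols <- c("participant", "region", "modality", "hemisphere", "timepoint",
            "value", "n_slices_used", "dropped")
  for (c in setdiff(cols, names(table))) table[[c]] <- NA
  write.csv(table[cols], path, row.names = FALSE)
  invisible(path)
}
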