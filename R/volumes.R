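# Containers for brain volumes and region masks.

MODALITIES <- c("mtplus", "mtminus", "fse")
REGIONS <- c("lc", "snvta")
HEMISPHERES <- c("left", "right")

#' Construct a brain volume
#'
#' A single participant/modality/timepoint/acquisition 3D intensity grid in
#' the cohort's common space. Intensities are arbitrary scanner units;
#' `NA` voxels mark positions unusable for peak search (see
#' [apply_exclusion()]).
#'
#' @param data 3D numeric array.
#' @param modality one of `"mtplus"`, `"mtminus"`, `"fse"`.
#' @param participant participant identifier.
#' @param timepoint integer timepoint (1 or 2 for imaging).
#' @param acquisition acquisition index (1; FSE at TP2 also has 2).
#' @return an object of class `brain_volume`.
#' @export
brain_volume <- function(data, modality, participant, timepoint, acquisition = 1L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  modality <- match.arg(modality, MODALITIES)
  if (any(!is.finite(data) & !is.na(data)))
    stop("brain_volume intensities must be finite or NA")
  structure(list(data = data, modality = modality,
                 participant = as.character(participant),
                 timepoint = as.integer(timepoint),
                 acquisition = as.integer(acquisition)),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<brain_volume> sub-%s tp-%d mod-%s acq-%d [%s]\n",
              x$participant, x$timepoint, x$modality, x$acquisition,
              paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Construct a mask set for one region
#'
#' Binary masks sharing the cohort grid: left/right region-of-interest
#' masks, the white-matter reference mask (pontine for the LC, crus cerebri
#' for the SN-VTA) and an optional exclusion mask (the hyperintense fourth
#' ventricle artifact, removed from MT scans before peak search).
#'
#' @param roi_left,roi_right,reference logical/0-1 3D arrays.
#' @param exclusion optional logical/0-1 3D array, or `NULL`.
#' @param region `"lc"` or `"snvta"`.
#' @return an object of class `mask_set`.
#' @export
mask_set <- function(roi_left, roi_right, reference, exclusion = NULL,
                     region = c("lc", "snvta")) {
  region <- match.arg(region)
  as_bin <- function(m) {
    stopifnot(is.array(m), length(dim(m)) == 3L)
    # tolerate near-binary volumes from resampling: values in (0.5, 1] -> 1
    array(round(as.numeric(m)) >= 1, dim = dim(m))
  }
  roi_left <- as_bin(roi_left); roi_right <- as_bin(roi_right)
  reference <- as_bin(reference)
  dm <- dim(roi_left)
  if (!identical(dm, dim(roi_right)) || !identical(dm, dim(reference)))
    stop("mask grids differ")
  if (!is.null(exclusion)) {
    exclusion <- as_bin(exclusion)
    if (!identical(dm, dim(exclusion))) stop("mask grids differ")
  }
  if (any((roi_left | roi_right) & reference))
    stop("ROI and reference masks overlap")
  if (!any(roi_left) || !any(roi_right))
    stop("each hemisphere needs at least one ROI voxel")
  structure(list(roi_left = roi_left, roi_right = roi_right,
                 reference = reference, exclusion = exclusion,
                 region = region, grid = dm),
            class = "mask_set")
}

coords_to_mask <- function(coords, grid) {
  m <- array(FALSE, dim = grid)
  if (nrow(coords)) m[coords] <- TRUE
  m
}

#' Build mask sets from a simulation geometry
#'
#' @param geometry the `roi_geometry` component of a simulation config.
#' @param grid grid dimensions (length 3).
#' @return named list with `lc` and `snvta` [mask_set()] objects.
#' @export
masks_from_geometry <- function(geometry, grid) {
  g <- lapply(geometry, coords_to_mask, grid = grid)
  list(
    lc = mask_set(g$lc_left_mask, g$lc_right_mask, g$pontine_ref,
                  exclusion = g$ventricle, region = "lc"),
    snvta = mask_set(g$snvta_left_mask, g$snvta_right_mask, g$crus_ref,
                     exclusion = g$ventricle, region = "snvta")
  )
}
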