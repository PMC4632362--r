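#' PET SUV volume
#'
#' A standardized-uptake-value scalar field on a voxel grid, together with
#' the two scanner-specific calibration coefficients of the
#' contrast-oriented adaptive thresholding rule
#' \code{T = coeff_a * mean70 + coeff_b * background}.
#'
#' @param grid a \code{voxel_grid}.
#' @param suv non-negative numeric array of SUVs with the grid's dims.
#' @param coeff_a slope applied to the 70\%-isocontour mean SUV.
#' @param coeff_b slope applied to the background mean SUV.
#' @return An object of class \code{pet_volume}.
#' @export
pet_volume <- function(grid, suv, coeff_a, coeff_b) {
  stopifnot(inherits(grid, "voxel_grid"))
  suv <- array(as.numeric(suv), dim = grid$dims)
  if (any(!is.finite(suv)) || any(suv < 0))
    stop("suv must be finite and non-negative")
  if (!is.finite(coeff_a) || !is.finite(coeff_b))
    stop("coefficients must be finite")
  structure(list(grid = grid, suv = suv,
                 coeff_a = coeff_a, coeff_b = coeff_b),
            class = "pet_volume")
}

#' Tumour search region with background reference
#'
#' The tumour region of interest (ROI) the thresholding searches within,
#' and a disjoint background region whose mean SUV enters the threshold.
#'
#' @param roi logical array delimiting the tumour search region.
#' @param background_roi logical array, disjoint from \code{roi}.
#' @return An object of class \code{pet_roi}.
#' @export
pet_roi <- function(roi, background_roi) {
  roi <- as.array(roi); background_roi <- as.array(background_roi)
  stopifnot(identical(dim(roi), dim(background_roi)))
  if (!any(roi)) stop("empty ROI")
  if (!any(background_roi)) stop("empty background ROI")
  if (any(roi & background_roi)) stop("ROI and background ROI must be disjoint")
  structure(list(roi = roi, background_roi = background_roi),
            class = "pet_roi")
}

#' Build a shell-shaped background ROI around a tumour ROI
#'
#' Convenience builder: a shell of configurable thickness starting at a
#' configurable distance outside the ROI surface, for use as the background
#' reference region.
#'
#' @param roi_mask \code{structure_mask} of the tumour ROI.
#' @param distance_mm gap between ROI surface and inner shell face (mm).
#' @param thickness_mm shell thickness (mm); default two voxels at the
#'   grid's minimum spacing.
#' @return a \code{pet_roi}.
#' @export
background_shell <- function(roi_mask, distance_mm = 6,
                             thickness_mm = 2 * min(roi_mask$grid$spacing)) {
  d <- distance_map_mm(roi_mask)
  shell <- d > distance_mm & d <= distance_mm + thickness_mm
  pet_roi(roi_mask$voxels, shell)
}

#' SUV statistics within a tumour ROI
#'
#' @param pet a \code{pet_volume}.
#' @param roi a \code{pet_roi} (grid-shaped).
#' @return named vector: \code{suv_max}, the maximum SUV in the ROI, and
#'   \code{mean70}, the mean SUV over ROI voxels at or above 70\% of
#'   \code{suv_max} (never empty: it contains the max voxel).
#' @export
suv_stats <- function(pet, roi) {
  stopifnot(inherits(pet, "pet_volume"), inherits(roi, "pet_roi"))
  v <- pet$suv[roi$roi]
  if (!length(v)) stop("empty ROI")
  smax <- max(v)
  c(suv_max = smax, mean70 = mean(v[v >= 0.70 * smax]))
}

#' Adaptive segmentation threshold
#'
#' Contrast-oriented threshold \code{T = coeff_a * mean70 + coeff_b * BG}
#' where \code{BG} is the mean SUV over the background region. Returned
#' with its components for audit.
#'
#' @inheritParams suv_stats
#' @return list: \code{threshold}, \code{suv_max}, \code{mean70}, \code{bg}.
#' @export
schaefer_threshold <- function(pet, roi) {
  s <- suv_stats(pet, roi)
  bg <- mean(pet$suv[roi$background_roi])
  thr <- pet$coeff_a * s[["mean70"]] + pet$coeff_b * bg
  if (!is.finite(thr) || thr <= 0 || thr >= s[["suv_max"]])
    stop("degenerate threshold")
  list(threshold = thr, suv_max = s[["suv_max"]], mean70 = s[["mean70"]],
       bg = bg)
}

#' Segment a PET GTV by adaptive thresholding
#'
#' Voxels within the ROI with SUV at or above the adaptive threshold
#' (inclusive comparison). By default only the largest 26-connected
#' component is retained, suppressing physiologic-uptake satellites.
#'
#' @inheritParams suv_stats
#' @param patient_id patient identifier for the resulting mask.
#' @param keep_largest keep only the largest 26-connected component
#'   (default TRUE).
#' @return a \code{structure_mask} (modality PET, observer "auto") with the
#'   threshold audit attached as attribute \code{"audit"}.
#' @export
segment_pet <- function(pet, roi, patient_id = NA_character_,
                        keep_largest = TRUE) {
  thr <- schaefer_threshold(pet, roi)
  vox <- roi$roi & pet$suv >= thr$threshold
  if (!any(vox)) stop("no voxels above threshold")
  m <- structure_mask(pet$grid, vox, patient_id = patient_id,
                      modality = "PET", observer_id = "auto",
                      observer_role = "auto")
  if (keep_largest) {
    lab <- label_components(m)
    counts <- tabulate(lab[lab > 0])
    m$voxels <- array(lab == which.max(counts), dim = pet$grid$dims)
  }
  attr(m, "audit") <- thr
  m
}

#' Calibrate the two threshold coefficients from phantom measurements
#'
#' Least-squares fit of \code{true_threshold = a * mean70 + b * bg} over a
#' set of phantom measurements (no intercept, matching the two-coefficient
#' scanner calibration model).
#'
#' @param measurements data.frame with columns \code{mean70}, \code{bg},
#'   \code{true_threshold}; at least two rows with non-collinear
#'   (mean70, bg).
#' @return list: \code{coeff_a}, \code{coeff_b}, \code{residuals},
#'   \code{fit} (the underlying \code{lm}).
#' @export
calibrate_coefficients <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("mean70", "bg", "true_threshold") %in% names(measurements)))
  if (nrow(measurements) < 2) stop("unidentifiable calibration")
  X <- cbind(measurements$mean70, measurements$bg)
  if (qr(X)$rank < 2) stop("unidentifiable calibration")
  fit <- lm(true_threshold ~ 0 + mean70 + bg, data = measurements)
  cf <- coef(fit)
  list(coeff_a = unname(cf["mean70"]), coeff_b = unname(cf["bg"]),
       residuals = unname(residuals(fit)), fit = fit)
}
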