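#' @useDynLib gtvconcord, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd qnorm ppoints rnorm rlnorm runif quantile lm coef residuals aov TukeyHSD setNames cor median
#' @importFrom utils read.csv write.csv
NULL

MODALITIES <- c("CT", "MR", "CTMR", "PET")
ROLES <- c("radiologist", "oncologist", "auto")

#' Voxel grid geometry
#'
#' Defines the regular, axis-aligned 3-D grid every mask and volume lives on.
#' Physical position of the centre of voxel index \code{(i, j, k)} (1-based,
#' as used throughout this package) is \code{origin + (index - 1) * spacing}.
#' Oblique orientation matrices are not supported.
#'
#' @param dims integer triple, voxels along x, y, z (all >= 1).
#' @param spacing positive real triple, mm per voxel along each axis.
#' @param origin real triple, mm position of the centre of the first voxel.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dims) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dims < 1L)) stop("all dims must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a \code{voxel_grid}.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Test two grids for geometric compatibility
#'
#' Grids are compatible iff dims are equal and spacing and origin agree
#' within \code{tol} mm. Masks compared by the concordance metrics must be
#' on compatible grids.
#'
#' @param a,b \code{voxel_grid} objects.
#' @param tol tolerance in mm (default 1e-6).
#' @return logical.
#' @export
grids_compatible <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Binary structure mask
#'
#' A 3-D binary mask (typically a gross tumour volume, GTV) on a voxel grid,
#' tagged with the patient, imaging modality and observer that produced it.
#'
#' @param grid a \code{voxel_grid}.
#' @param voxels logical array with dim equal to \code{grid$dims}.
#' @param patient_id patient identifier.
#' @param modality one of \code{"CT"}, \code{"MR"}, \code{"CTMR"}, \code{"PET"}.
#' @param observer_id observer identifier; \code{"auto"} for PET.
#' @param observer_role one of \code{"radiologist"}, \code{"oncologist"},
#'   \code{"auto"}.
#' @return An object of class \code{structure_mask}.
#' @export
structure_mask <- function(grid, voxels, patient_id = NA_character_,
                           modality = "CT", observer_id = NA_character_,
                           observer_role = "auto") {
  stopifnot(inherits(grid, "voxel_grid"))
  voxels <- array(as.logical(voxels), dim = grid$dims)
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  modality <- match.arg(modality, MODALITIES)
  observer_role <- match.arg(observer_role, ROLES)
  structure(list(grid = grid, voxels = voxels,
                 patient_id = as.character(patient_id),
                 modality = modality,
                 observer_id = as.character(observer_id),
                 observer_role = observer_role),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask [%s / %s / %s]: %d voxels, %.3f cm^3\n",
              x$patient_id, x$modality, x$observer_id,
              sum(x$voxels), volume_cm3(x)))
  invisible(x)
}

is_empty_mask <- function(mask) !any(mask$voxels)

stop_if_empty <- function(mask) {
  if (is_empty_mask(mask)) stop("empty structure")
  invisible(mask)
}

#' Structure volume in cm^3
#'
#' @param mask a \code{structure_mask}.
#' @return (true voxel count) x (voxel volume mm^3) / 1000; 0 for an empty mask.
#' @export
volume_cm3 <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask$grid) / 1000
}

# physical centre coordinates (mm) of all true voxels; n x 3 matrix
mask_coords_mm <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  g <- mask$grid
  cbind(g$origin[1] + (idx[, 1] - 1) * g$spacing[1],
        g$origin[2] + (idx[, 2] - 1) * g$spacing[2],
        g$origin[3] + (idx[, 3] - 1) * g$spacing[3])
}

#' Geometric centre (centroid) in mm
#'
#' Unweighted mean of the physical centre coordinates of all true voxels.
#'
#' @param mask a non-empty \code{structure_mask}.
#' @return numeric triple (mm).
#' @export
centroid_mm <- function(mask) {
  stop_if_empty(mask)
  colMeans(mask_coords_mm(mask))
}

#' Rigid spatial transform
#'
#' A 4x4 homogeneous matrix whose upper-left 3x3 block must be a proper
#' rotation (orthonormal, det +1). Maps source-frame physical coordinates
#' (mm) into the target frame.
#'
#' @param matrix 4x4 numeric matrix.
#' @param source_frame,target_frame frame identifiers.
#' @param tol orthonormality tolerance (default 1e-6).
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(matrix, source_frame = "source",
                            target_frame = "target", tol = 1e-6) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("transform not rigid")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > tol)
    stop("transform not rigid")
  structure(list(matrix = matrix, source_frame = source_frame,
                 target_frame = target_frame),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @param frame frame identifier for both source and target.
#' @return a \code{rigid_transform}.
#' @export
identity_transform <- function(frame = "common") {
  rigid_transform(diag(4), frame, frame)
}

#' Resample a binary mask onto a target grid through a rigid transform
#'
#' Nearest-neighbour semantics that preserve binariness: a target voxel is
#' true iff its physical centre, mapped through the inverse transform into
#' the source frame, falls inside a true source voxel. With the identity
#' transform and a compatible grid the result is voxel-identical to the
#' input.
#'
#' @param mask a \code{structure_mask} in the transform's source frame.
#' @param transform a \code{rigid_transform} (source -> target frame).
#' @param target a \code{voxel_grid} in the target frame.
#' @return a \code{structure_mask} on \code{target}.
#' @export
resample_to_grid <- function(mask, transform, target) {
  stopifnot(inherits(mask, "structure_mask"),
            inherits(transform, "rigid_transform"),
            inherits(target, "voxel_grid"))
  # fast path: identity transform on a compatible grid
  if (grids_compatible(mask$grid, target) &&
      max(abs(transform$matrix - diag(4))) < 1e-12) {
    out <- mask
    out$grid <- target
    return(out)
  }
  d <- target$dims
  # physical centres of all target voxels (column-major order matches array)
  i <- rep.int(seq_len(d[1]), d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  pts <- cbind(target$origin[1] + (i - 1) * target$spacing[1],
               target$origin[2] + (j - 1) * target$spacing[2],
               target$origin[3] + (k - 1) * target$spacing[3])
  inv <- solve(transform$matrix)
  src <- pts %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(pts), 3, byrow = TRUE)
  g <- mask$grid
  si <- as.integer(round((src[, 1] - g$origin[1]) / g$spacing[1])) + 1L
  sj <- as.integer(round((src[, 2] - g$origin[2]) / g$spacing[2])) + 1L
  sk <- as.integer(round((src[, 3] - g$origin[3]) / g$spacing[3])) + 1L
  ok <- si >= 1L & si <= g$dims[1] & sj >= 1L & sj <= g$dims[2] &
    sk >= 1L & sk <= g$dims[3]
  vox <- logical(prod(d))
  lin <- (sk[ok] - 1L) * (g$dims[1] * g$dims[2]) +
    (sj[ok] - 1L) * g$dims[1] + si[ok]
  vox[ok] <- mask$voxels[lin]
  structure_mask(target, array(vox, dim = d),
                 patient_id = mask$patient_id, modality = mask$modality,
                 observer_id = mask$observer_id,
                 observer_role = mask$observer_role)
}

#' Euclidean distance map to a mask (mm)
#'
#' Exact Euclidean distance from every voxel centre to the nearest true
#' voxel centre of the mask, honouring anisotropic spacing. True voxels map
#' to 0. Computed with a separable exact distance transform.
#'
#' @param mask a non-empty \code{structure_mask}.
#' @return numeric array (mm) with the grid's dims.
#' @export
distance_map_mm <- function(mask) {
  stop_if_empty(mask)
  cpp_edt(mask$voxels, mask$grid$dims, mask$grid$spacing)
}

# signed distance: negative inside the mask, positive outside (mm)
signed_distance_mm <- function(mask) {
  g <- mask$grid
  outside <- cpp_edt(mask$voxels, g$dims, g$spacing)
  inv <- !mask$voxels
  if (!any(inv)) return(array(-outside, dim = g$dims))
  inside <- cpp_edt(inv, g$dims, g$spacing)
  outside - inside
}

#' Label 26-connected components of a mask
#' @param mask a \code{structure_mask}.
#' @return integer array of component labels (0 = background), labels in
#'   first-encounter order.
#' @export
label_components <- function(mask) {
  cpp_label26(mask$voxels, mask$grid$dims)
}
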