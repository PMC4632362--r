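# deterministic sub-stream seed from a base seed and a character path
derive_seed <- function(seed, ...) {
  parts <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(parts)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# separable Gaussian blur of a 3-D array; sigma in mm, per-axis spacing.
# Truncated kernels are renormalised at the edges.
gaussian_blur <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma_mm <= 0) next
    n <- d[ax]
    x <- (seq_len(n) - 1) * spacing[ax]
    K <- exp(-outer(x, x, "-")^2 / (2 * sigma_mm^2))
    K <- K / rowSums(K)
    if (ax == 1) {
      arr <- array(K %*% matrix(arr, d[1]), dim = d)
    } else if (ax == 2) {
      a <- aperm(arr, c(2, 1, 3))
      a <- array(K %*% matrix(a, d[2]), dim = c(d[2], d[1], d[3]))
      arr <- aperm(a, c(2, 1, 3))
    } else {
      a <- aperm(arr, c(3, 2, 1))
      a <- array(K %*% matrix(a, d[3]), dim = c(d[3], d[2], d[1]))
      arr <- aperm(a, c(3, 2, 1))
    }
  }
  arr
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# signed distance with a sub-voxel refinement term: the voxel-centre EDT is
# quantized in steps of one spacing (large tie blocks at the surface), so a
# smoothed-indicator term interpolates the surface position within the
# boundary layer. Negative inside, positive outside.
smooth_signed_distance <- function(mask) {
  sp <- min(mask$grid$spacing)
  sdf <- signed_distance_mm(mask)
  sm <- gaussian_blur(mask$voxels + 0, sp, mask$grid$spacing)
  sdf + sp * (0.5 - sm)
}

#' Synthetic study configuration
#'
#' Defines the conditions of a generated multi-observer, multi-modality GTV
#' delineation study. Defaults emulate an 11-patient oropharyngeal cohort
#' contoured by two radiologists and three oncologists on CT, MR and
#' combined CT-MR, with a single auto-segmented PET contour per patient:
#' modality volume multipliers ordered PET < CT < MR < CT-MR, boundary
#' observer noise largest on CT and smallest on MR, oncologists contouring
#' systematically larger than radiologists, and realistic contour
#' incompleteness on MR and CT-MR.
#'
#' @param n_patients number of patients (default 11).
#' @param observers data.frame with columns id, role (default 2
#'   radiologists + 3 oncologists).
#' @param dims,spacing_mm grid geometry (default 64^3 at 2 mm isotropic).
#' @param volume_median_cm3 median of the log-normal base tumour volume
#'   distribution (default 12 cm^3).
#' @param volume_sdlog log-scale dispersion of base volumes (default 0.45).
#' @param modality_multipliers named volume multipliers relative to the
#'   base tumour shape.
#' @param observer_amp_mm named per-modality radial volume-noise SD (mm):
#'   an observer's contour volume deviates from the modality truth by the
#'   equivalent-sphere surface area times a normal radial error of this SD,
#'   so these amplitudes set the per-patient volume SD scale.
#' @param observer_field_mm named per-modality boundary-field amplitude
#'   (mm): the SD of the smooth random radial field that displaces the
#'   contour surface locally, setting the shape-disagreement (overlap
#'   metric) scale. Volume and shape scales are separate because a binary
#'   mask realises local surface displacements only at whole-voxel
#'   granularity while its total volume is adjustable to sub-voxel
#'   precision.
#' @param role_bias_mm named radial offset per observer role (mm); the
#'   oncologist-minus-radiologist gap sets the role volume effect.
#' @param field_smooth_mm correlation length of the boundary noise field
#'   (Gaussian smoothing sigma, mm).
#' @param missingness named per-modality probability that a human contour
#'   was not completed.
#' @param pet list of PET phantom parameters: blur_fwhm_mm, suv_bg,
#'   suv_ratio (tumour:background), noise_sd, roi_margin_mm,
#'   bg_distance_mm, coeff_a, coeff_b.
#' @param seed base seed; every generated artefact is a pure function of
#'   (config, seed).
#' @return list of class \code{study_config}.
#' @export
study_config <- function(n_patients = 11,
                         observers = data.frame(
                           id = c("R1", "R2", "O1", "O2", "O3"),
                           role = c("radiologist", "radiologist",
                                    "oncologist", "oncologist", "oncologist"),
                           stringsAsFactors = FALSE),
                         dims = c(64L, 64L, 64L),
                         spacing_mm = c(2, 2, 2),
                         volume_median_cm3 = 11.5,
                         volume_sdlog = 0.35,
                         modality_multipliers = c(CT = 1.00, MR = 1.07,
                                                  CTMR = 1.19, PET = 0.80),
                         observer_amp_mm = c(CT = 1.75, CTMR = 1.22,
                                             MR = 0.74),
                         observer_field_mm = c(CT = 5, CTMR = 4.5, MR = 4.2),
                         role_bias_mm = c(radiologist = -0.6,
                                          oncologist = 0.6),
                         field_smooth_mm = 6,
                         missingness = c(CT = 0, MR = 4 / 55, CTMR = 13 / 55),
                         pet = list(blur_fwhm_mm = 7, suv_bg = 1,
                                    suv_ratio = 8, noise_sd = 0.15,
                                    roi_margin_mm = 8, bg_distance_mm = 6,
                                    coeff_a = 0.44, coeff_b = 0.77),
                         seed = 1L) {
  stopifnot(all(modality_multipliers > 0), all(observer_amp_mm >= 0),
            all(observer_field_mm >= 0),
            all(missingness >= 0 & missingness <= 1),
            all(c("radiologist", "oncologist") %in%
                  unique(observers$role) | nrow(observers) == 0))
  if (any(missingness >= 1)) stop("infeasible design")
  structure(list(n_patients = n_patients, observers = observers,
                 dims = as.integer(dims), spacing_mm = spacing_mm,
                 volume_median_cm3 = volume_median_cm3,
                 volume_sdlog = volume_sdlog,
                 modality_multipliers = modality_multipliers,
                 observer_amp_mm = observer_amp_mm,
                 observer_field_mm = observer_field_mm,
                 role_bias_mm = role_bias_mm,
                 field_smooth_mm = field_smooth_mm,
                 missingness = missingness, pet = pet, seed = as.integer(seed)),
            class = "study_config")
}

#' Ground-truth tumour and per-modality truth masks for one patient
#'
#' Draws the patient's base tumour as a superposition of 2-4 overlapping
#' ellipsoids, smoothed and thresholded, rescaled to a volume drawn from
#' the configured log-normal distribution. Each modality's systematic
#' volume offset is realised by moving the base surface along its signed
#' distance field until the rendered volume matches the configured
#' multiplier (order-statistic thresholding, exact to voxel resolution).
#'
#' @param config a \code{study_config}.
#' @param patient integer patient index (1-based).
#' @return list: \code{base} (structure_mask), \code{volume_cm3},
#'   \code{centroid_mm}, \code{modality} (named list of structure_masks).
#' @export
generate_truth <- function(config, patient) {
  grid <- voxel_grid(config$dims, config$spacing_mm)
  vv <- voxel_volume_mm3(grid)
  pid <- sprintf("P%02d", patient)
  set.seed(derive_seed(config$seed, "truth", patient))
  target <- rlnorm(1, log(config$volume_median_cm3), config$volume_sdlog)
  k_base <- round(target * 1000 / vv)
  if (k_base < 8) stop("grid too coarse")
  extent <- (config$dims - 1) * config$spacing_mm
  centre <- extent / 2 + runif(3, -6, 6)
  r_eq <- (3 * target * 1000 / (4 * pi))^(1 / 3)
  n_ell <- sample(2:4, 1)
  x <- (seq_len(config$dims[1]) - 1) * config$spacing_mm[1]
  y <- (seq_len(config$dims[2]) - 1) * config$spacing_mm[2]
  z <- (seq_len(config$dims[3]) - 1) * config$spacing_mm[3]
  ind <- array(0, dim = config$dims)
  for (e in seq_len(n_ell)) {
    c_e <- centre + runif(3, -0.4, 0.4) * r_eq
    ax <- r_eq * runif(3, 0.6, 1.1)
    q <- outer(outer(((x - c_e[1]) / ax[1])^2,
                     ((y - c_e[2]) / ax[2])^2, "+"),
               ((z - c_e[3]) / ax[3])^2, "+")
    ind[q <= 1] <- 1
  }
  if (!any(ind > 0)) stop("grid too coarse")
  sm <- gaussian_blur(ind, 3, config$spacing_mm)
  shape <- structure_mask(grid, sm >= 0.5, patient_id = pid)
  if (!any(shape$voxels)) shape$voxels <- array(ind > 0, dim = config$dims)
  sdf <- smooth_signed_distance(shape)
  s_sorted <- sort(as.vector(sdf))
  carve <- function(k, modality, observer_id = "truth",
                    observer_role = "auto") {
    k <- max(1L, min(length(s_sorted) - 1L, as.integer(k)))
    structure_mask(grid, sdf <= s_sorted[k], patient_id = pid,
                   modality = modality, observer_id = observer_id,
                   observer_role = observer_role)
  }
  base <- carve(k_base, "CT")
  mods <- lapply(names(config$modality_multipliers), function(m)
    carve(round(k_base * config$modality_multipliers[[m]]), m))
  names(mods) <- names(config$modality_multipliers)
  list(base = base, volume_cm3 = volume_cm3(base),
       centroid_mm = centroid_mm(base), modality = mods, sdf = sdf)
}

#' Simulate one observer's delineation of a truth mask
#'
#' Two-scale observer model. The contour's total volume follows the
#' record-level model: modality-truth volume plus the equivalent-sphere
#' surface area times (role bias + a normal radial error with the
#' modality's volume-noise SD). Its shape follows a smooth band-limited
#' random radial field with the modality's boundary-field amplitude: the
#' mask is carved from the truth's signed distance minus the field by an
#' order-statistic threshold that lands exactly on the target volume.
#' Oncologist contours are thereby systematically larger than radiologist
#' contours, per-patient volume SDs carry the configured modality
#' ordering, and overlap metrics between observers degrade with the field
#' amplitude.
#'
#' @param truth a modality-truth \code{structure_mask}.
#' @param observer_id,role observer identity and role.
#' @param modality modality being contoured (selects the noise amplitudes).
#' @param config a \code{study_config}.
#' @param seed base seed (observer id, patient and modality feed the
#'   sub-stream, so different observers get different contours).
#' @return a \code{structure_mask}.
#' @export
simulate_observer <- function(truth, observer_id, role, modality, config,
                              seed = config$seed) {
  amp_vol <- config$observer_amp_mm[[modality]]
  amp_field <- config$observer_field_mm[[modality]]
  bias <- config$role_bias_mm[[role]]
  if (amp_vol == 0 && amp_field == 0 && bias == 0) {
    out <- truth
    out$observer_id <- as.character(observer_id)
    out$observer_role <- role
    return(out)
  }
  sdf <- smooth_signed_distance(truth)
  set.seed(derive_seed(seed, "obs", truth$patient_id, modality, observer_id))
  eps_mm <- rnorm(1, 0, amp_vol)
  v_truth <- volume_cm3(truth)
  r_cm <- (3 * v_truth / (4 * pi))^(1 / 3)
  area_cm2 <- 4 * pi * r_cm^2
  v_target <- v_truth + area_cm2 * (bias + eps_mm) / 10
  vv <- voxel_volume_mm3(truth$grid)
  k <- round(v_target * 1000 / vv)
  k <- max(8L, min(as.integer(k), prod(config$dims) - 1L))
  key <- if (amp_field > 0) {
    field <- array(rnorm(prod(config$dims)), dim = config$dims)
    field <- gaussian_blur(field, config$field_smooth_mm, config$spacing_mm)
    sdf - field / sd(field) * amp_field
  } else sdf
  thr <- sort(as.vector(key), partial = k)[k]
  structure_mask(truth$grid, key <= thr, patient_id = truth$patient_id,
                 modality = modality, observer_id = as.character(observer_id),
                 observer_role = role)
}

#' Render a blurred PET phantom for a tumour truth mask
#'
#' SUV field equal to the background level plus the configured contrast
#' inside the PET-modality truth, convolved with an isotropic Gaussian of
#' the configured FWHM (scanner point-spread blurring), plus Gaussian
#' noise (truncated at zero). Also returns the tumour search ROI (truth
#' dilated by the configured margin) and a background shell ROI.
#'
#' @param truth the PET-modality truth \code{structure_mask}.
#' @param config a \code{study_config}.
#' @param seed base seed.
#' @return list: \code{pet} (a \code{pet_volume}), \code{roi} (a
#'   \code{pet_roi}).
#' @export
render_pet <- function(truth, config, seed = config$seed) {
  p <- config$pet
  if (p$blur_fwhm_mm > 0 && p$blur_fwhm_mm < min(config$spacing_mm))
    warning("PET blur FWHM below voxel spacing")
  suv <- p$suv_bg * (1 + (p$suv_ratio - 1) *
                       gaussian_blur(truth$voxels + 0,
                                     fwhm_to_sigma(p$blur_fwhm_mm),
                                     config$spacing_mm))
  if (p$noise_sd > 0) {
    set.seed(derive_seed(seed, "pet", truth$patient_id))
    suv <- suv + array(rnorm(length(suv), 0, p$noise_sd), dim = dim(suv))
  }
  suv[suv < 0] <- 0
  pet <- pet_volume(truth$grid, suv, p$coeff_a, p$coeff_b)
  d <- distance_map_mm(truth)
  roi_vox <- d <= p$roi_margin_mm
  roi_mask <- structure_mask(truth$grid, roi_vox,
                             patient_id = truth$patient_id)
  roi <- background_shell(roi_mask, distance_mm = p$bg_distance_mm)
  list(pet = pet, roi = roi)
}

#' Generate a complete synthetic delineation study
#'
#' Ground truths for every patient, observer contours for every human
#' modality with the configured missingness applied (PET is never
#' removed), rendered PET phantoms and their auto-segmented contours, and
#' the study manifest tying them together. Fully deterministic under
#' (config, seed).
#'
#' @param config a \code{study_config}.
#' @return list of class \code{synthetic_study}: \code{manifest}
#'   (data.frame), \code{masks} (named list of structure_masks),
#'   \code{pet} (per-patient list of pet_volume + roi), \code{truth}
#'   (per-patient ground-truth registry), \code{config}.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  masks <- list()
  pets <- list()
  truths <- list()
  rows <- list()
  human_mods <- names(config$observer_amp_mm)
  for (p in seq_len(config$n_patients)) {
    tr <- generate_truth(config, p)
    pid <- tr$base$patient_id
    truths[[pid]] <- tr[c("base", "volume_cm3", "centroid_mm", "modality")]
    set.seed(derive_seed(config$seed, "missing", p))
    for (m in human_mods) {
      for (i in seq_len(nrow(config$observers))) {
        if (runif(1) < config$missingness[[m]]) next
        ob <- config$observers[i, ]
        mk <- simulate_observer(tr$modality[[m]], ob$id, ob$role, m, config)
        key <- paste(pid, m, ob$id, sep = "/")
        masks[[key]] <- mk
        rows[[length(rows) + 1]] <-
          data.frame(patient_id = pid, modality = m, observer_id = ob$id,
                     observer_role = ob$role, mask_id = key,
                     stringsAsFactors = FALSE)
      }
    }
    rp <- render_pet(tr$modality$PET, config)
    pm <- segment_pet(rp$pet, rp$roi, patient_id = pid)
    key <- paste(pid, "PET", "auto", sep = "/")
    masks[[key]] <- pm
    pets[[pid]] <- rp
    rows[[length(rows) + 1]] <-
      data.frame(patient_id = pid, modality = "PET", observer_id = "auto",
                 observer_role = "auto", mask_id = key,
                 stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  # flag patient x modality cells left with < 2 observers by missingness
  low <- list()
  hm <- manifest[manifest$modality != "PET", ]
  for (m in human_mods) for (pid in unique(manifest$patient_id)) {
    n <- sum(hm$modality == m & hm$patient_id == pid)
    if (n < 2) low[[length(low) + 1]] <-
        data.frame(patient_id = pid, modality = m, n_observers = n)
  }
  attr(manifest, "underfilled_cells") <-
    if (length(low)) do.call(rbind, low) else NULL
  structure(list(manifest = manifest, masks = masks, pet = pets,
                 truth = truths, config = config),
            class = "synthetic_study")
}

#' Generate volume records directly (no voxelisation)
#'
#' Fast record-level counterpart of \code{\link{generate_study}} for
#' statistical simulation at many replicates: draws per-patient base
#' volumes, applies the configured modality multipliers, and converts the
#' boundary-noise and role-bias parameters to volume space through the
#' equivalent-sphere surface area (dV = area x dr), so the record-level
#' and voxel-level generators share one parameterisation.
#'
#' @param config a \code{study_config}.
#' @param seed overriding seed (default the config's).
#' @param include_pet include the single auto PET record per patient
#'   (default TRUE).
#' @return a volume record data.frame.
#' @export
generate_volume_records <- function(config = study_config(),
                                    seed = config$seed, include_pet = TRUE) {
  set.seed(derive_seed(seed, "records"))
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    vbase <- rlnorm(1, log(config$volume_median_cm3), config$volume_sdlog)
    for (m in names(config$observer_amp_mm)) {
      vm <- vbase * config$modality_multipliers[[m]]
      r_cm <- (3 * vm / (4 * pi))^(1 / 3)
      area_cm2 <- 4 * pi * r_cm^2
      for (i in seq_len(nrow(config$observers))) {
        if (runif(1) < config$missingness[[m]]) next
        ob <- config$observers[i, ]
        dr_cm <- (config$role_bias_mm[[ob$role]] +
                    rnorm(1, 0, config$observer_amp_mm[[m]])) / 10
        v <- max(vm + area_cm2 * dr_cm, 0.05)
        rows[[length(rows) + 1]] <-
          data.frame(patient_id = pid, modality = m, observer_id = ob$id,
                     observer_role = ob$role, volume_cm3 = v,
                     stringsAsFactors = FALSE)
      }
    }
    if (include_pet && "PET" %in% names(config$modality_multipliers)) {
      rows[[length(rows) + 1]] <-
        data.frame(patient_id = pid, modality = "PET", observer_id = "auto",
                   observer_role = "auto",
                   volume_cm3 = vbase * config$modality_multipliers[["PET"]],
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
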