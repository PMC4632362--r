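# fixture builders and the independent brute-force metric oracle

mk_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_grid(dims, spacing, origin)
}

# mask from a matrix of 1-based voxel indices
mk_mask <- function(grid, idx, ...) {
  vox <- array(FALSE, dim = grid$dims)
  idx <- matrix(idx, ncol = 3)
  vox[idx] <- TRUE
  structure_mask(grid, vox, ...)
}

# axis-aligned solid block, corner (1-based) and size in voxels
block_mask <- function(grid, corner, size, ...) {
  vox <- array(FALSE, dim = grid$dims)
  vox[corner[1]:(corner[1] + size[1] - 1),
      corner[2]:(corner[2] + size[2] - 1),
      corner[3]:(corner[3] + size[3] - 1)] <- TRUE
  structure_mask(grid, vox, ...)
}

# connected random blob: ellipsoid with jittered centre/axes
random_blob <- function(grid, r_vox = NULL) {
  d <- grid$dims
  if (is.null(r_vox)) r_vox <- runif(1, 1.2, max(1.6, d[1] / 3))
  cen <- (d - 1) / 2 + runif(3, -d[1] / 6, d[1] / 6)
  ax <- r_vox * runif(3, 0.6, 1.2)
  x <- seq_len(d[1]) - 1; y <- seq_len(d[2]) - 1; z <- seq_len(d[3]) - 1
  q <- outer(outer(((x - cen[1]) / ax[1])^2, ((y - cen[2]) / ax[2])^2, "+"),
             ((z - cen[3]) / ax[3])^2, "+")
  vox <- q <= 1
  if (!any(vox)) vox[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  structure_mask(grid, vox)
}

# naive triple-loop-equivalent oracle for all six metrics
naive_metrics <- function(a, b) {
  ia <- which(a$voxels)
  ib <- which(b$voxels)
  inter <- length(intersect(ia, ib))
  uni <- length(union(ia, ib))
  ca <- mask_coords_mm_test(a)
  cb <- mask_coords_mm_test(b)
  cga <- colMeans(ca)
  cgb <- colMeans(cb)
  only_a <- setdiff(ia, ib)
  only_b <- setdiff(ib, ia)
  dists <- c()
  coords_of <- function(mask, lin) {
    idx <- arrayInd(lin, mask$grid$dims)
    sweep(sweep(idx - 1, 2, mask$grid$spacing, "*"), 2, mask$grid$origin, "+")
  }
  if (length(only_a)) {
    pa <- coords_of(a, only_a)
    for (i in seq_len(nrow(pa)))
      dists <- c(dists, sqrt(min(colSums((t(cb) - pa[i, ])^2))))
  }
  if (length(only_b)) {
    pb <- coords_of(b, only_b)
    for (i in seq_len(nrow(pb)))
      dists <- c(dists, sqrt(min(colSums((t(ca) - pb[i, ])^2))))
  }
  list(ci = inter / uni,
       dice = 2 * inter / (length(ia) + length(ib)),
       se_idx = inter / length(ia),
       incl_idx = inter / length(ib),
       cgd_mm = sqrt(sum((cga - cgb)^2)),
       mdc_mm = if (length(dists)) mean(dists) else 0)
}

mask_coords_mm_test <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$grid$spacing, "*"), 2, mask$grid$origin, "+")
}

# noiseless blurred-sphere PET phantom with ROI and background shell
sphere_phantom <- function(radius_mm, ratio = 8, bg = 1, fwhm_mm = 7,
                           n = 48, sp = 2, noise_sd = 0, seed = 1) {
  grid <- voxel_grid(rep(n, 3), rep(sp, 3))
  cen <- (n - 1) * sp / 2
  x <- (seq_len(n) - 1) * sp
  q <- outer(outer((x - cen)^2, (x - cen)^2, "+"), (x - cen)^2, "+")
  truth <- structure_mask(grid, q <= radius_mm^2, patient_id = "phantom",
                          modality = "PET")
  cfg <- study_config(dims = rep(n, 3), spacing_mm = rep(sp, 3),
                      pet = list(blur_fwhm_mm = fwhm_mm, suv_bg = bg,
                                 suv_ratio = ratio, noise_sd = noise_sd,
                                 roi_margin_mm = 8, bg_distance_mm = 6,
                                 coeff_a = 0.44, coeff_b = 0.77),
                      seed = seed)
  rp <- render_pet(truth, cfg)
  list(truth = truth, pet = rp$pet, roi = rp$roi, grid = grid, config = cfg)
}

# calibrate (a, b) from noiseless sphere phantoms via volume-matching
# thresholds, using only suv_stats + background means as inputs
calibrate_on_spheres <- function(radii = c(5, 7.5, 10, 12.5, 15),
                                 ratios = c(4, 8)) {
  rows <- list()
  for (r in radii) for (ra in ratios) {
    ph <- sphere_phantom(r, ratio = ra)
    s <- suv_stats(ph$pet, ph$roi)
    bgm <- mean(ph$pet$suv[ph$roi$background_roi])
    k <- sum(ph$truth$voxels)
    v <- sort(ph$pet$suv[ph$roi$roi], decreasing = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      mean70 = s[["mean70"]], bg = bgm,
      true_threshold = (v[k] + v[k + 1]) / 2)
  }
  calibrate_coefficients(do.call(rbind, rows))
}
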