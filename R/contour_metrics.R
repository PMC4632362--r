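#' Pairwise contour concordance metrics
#'
#' Computes the six 3-D concordance metrics for an ordered pair of binary
#' structure masks on a common grid:
#' \describe{
#'   \item{ci}{conformity index, the Jaccard overlap |A n B| / |A u B|}
#'   \item{dice}{DICE index, 2|A n B| / (|A| + |B|)}
#'   \item{se_idx}{sensitivity index, the proportion of A inside B}
#'   \item{incl_idx}{inclusion index, the proportion of B inside A}
#'   \item{cgd_mm}{centre-of-gravity distance, Euclidean distance between
#'     the two centroids (mm)}
#'   \item{mdc_mm}{mean distance to conformity: over every voxel in the
#'     symmetric difference, the distance to the nearest true voxel of the
#'     other mask, averaged (mm)}
#' }
#'
#' @param a,b non-empty \code{structure_mask} objects on compatible grids.
#' @return a one-row data.frame with columns ci, dice, se_idx, incl_idx,
#'   cgd_mm, mdc_mm, label_a, label_b.
#' @export
concordance <- function(a, b) {
  ov <- overlap_metrics(a, b)
  data.frame(ci = ov[["ci"]], dice = ov[["dice"]],
             se_idx = ov[["se_idx"]], incl_idx = ov[["incl_idx"]],
             cgd_mm = cgd_mm(a, b), mdc_mm = mdc_mm(a, b),
             label_a = mask_label(a), label_b = mask_label(b),
             stringsAsFactors = FALSE)
}

mask_label <- function(m) paste(m$patient_id, m$modality, m$observer_id,
                                sep = "/")

check_pair <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!grids_compatible(a$grid, b$grid)) stop("grid mismatch")
  stop_if_empty(a)
  stop_if_empty(b)
  invisible(TRUE)
}

#' Volume-overlap indices for a mask pair
#'
#' @inheritParams concordance
#' @return named numeric vector (ci, dice, se_idx, incl_idx).
#' @export
overlap_metrics <- function(a, b) {
  check_pair(a, b)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  i <- sum(a$voxels & b$voxels)
  c(ci = i / (na + nb - i),
    dice = 2 * i / (na + nb),
    se_idx = i / na,
    incl_idx = i / nb)
}

#' Centre-of-gravity distance (mm)
#' @inheritParams concordance
#' @return Euclidean distance between the two mask centroids, mm.
#' @export
cgd_mm <- function(a, b) {
  check_pair(a, b)
  sqrt(sum((centroid_mm(a) - centroid_mm(b))^2))
}

#' Mean distance to conformity (mm)
#'
#' Mean, over all voxels in the symmetric difference of the two masks, of
#' the Euclidean distance from the voxel centre to the nearest true voxel
#' of the companion mask. Symmetric in its arguments; 0 for identical masks.
#'
#' @inheritParams concordance
#' @return non-negative distance in mm.
#' @export
mdc_mm <- function(a, b) {
  check_pair(a, b)
  only_a <- a$voxels & !b$voxels
  only_b <- b$voxels & !a$voxels
  if (!any(only_a) && !any(only_b)) return(0)
  d <- numeric(0)
  if (any(only_a)) d <- c(d, distance_map_mm(b)[only_a])
  if (any(only_b)) d <- c(d, distance_map_mm(a)[only_b])
  mean(d)
}

metric_cols <- c("ci", "dice", "se_idx", "incl_idx", "cgd_mm", "mdc_mm")

# mean per metric over rows of concordance results
mean_metrics <- function(df) colMeans(df[metric_cols])

#' Inter-observer concordance summary for one modality
#'
#' For each patient, all unordered observer pairs within the modality are
#' compared and the per-patient mean taken per metric; the cohort summary is
#' the mean and SD of the per-patient means across patients (each patient
#' weighted equally regardless of available pair count). Only the four
#' symmetric metrics (CI, DICE, CGD, MDC) are reported; the directional
#' sensitivity/inclusion indices are not meaningful for unordered pairs.
#' Patients with fewer than two observer masks in the modality are skipped.
#'
#' @param masks list of \code{structure_mask} objects.
#' @param modality modality to summarise ("CT", "MR" or "CTMR").
#' @return list with \code{per_patient} (data.frame patient x metric means)
#'   and \code{summary} (data.frame metric, comparison, mean, sd, n_patients).
#' @export
interobserver_summary <- function(masks, modality) {
  modality <- match.arg(modality, MODALITIES)
  sel <- Filter(function(m) m$modality == modality, masks)
  pats <- unique(vapply(sel, function(m) m$patient_id, character(1)))
  rows <- list()
  for (p in pats) {
    pm <- Filter(function(m) m$patient_id == p, sel)
    if (length(pm) < 2) next
    pair_rows <- list()
    for (i in seq_len(length(pm) - 1))
      for (j in seq(i + 1, length(pm)))
        pair_rows[[length(pair_rows) + 1]] <- concordance(pm[[i]], pm[[j]])
    df <- do.call(rbind, pair_rows)
    rows[[length(rows) + 1]] <-
      data.frame(patient_id = p, t(mean_metrics(df)),
                 n_pairs = nrow(df), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("insufficient observers")
  per_patient <- do.call(rbind, rows)
  sym <- c("ci", "dice", "cgd_mm", "mdc_mm")
  summ <- data.frame(
    metric = sym,
    comparison = modality,
    mean = vapply(sym, function(mc) mean(per_patient[[mc]]), numeric(1)),
    sd = vapply(sym, function(mc)
      if (nrow(per_patient) > 1) sd(per_patient[[mc]]) else 0, numeric(1)),
    n_patients = nrow(per_patient),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_patient = per_patient, summary = summ)
}

#' Inter-modality concordance summary
#'
#' For each ordered modality pair, each clinician's mask in the first
#' modality is compared with the same clinician's mask in the second; pairs
#' involving PET compare each clinician's mask against the single
#' auto-segmented PET mask. Per-patient means are taken over clinicians,
#' then the cohort mean and SD across patients. The sensitivity index is
#' the proportion of the first-named GTV inside the second; the inclusion
#' index the proportion of the second inside the first. Clinicians missing
#' either modality of a pair are skipped.
#'
#' @param masks list of \code{structure_mask} objects (PET masks carry
#'   observer_id "auto").
#' @param pairs list of 2-element character vectors of modalities; default
#'   the six study comparisons.
#' @return list with \code{per_patient} and \code{summary} data.frames.
#' @export
intermodality_summary <- function(masks,
                                  pairs = list(c("CT", "PET"), c("MR", "PET"),
                                               c("CTMR", "PET"), c("CT", "MR"),
                                               c("CT", "CTMR"),
                                               c("MR", "CTMR"))) {
  key <- function(m) paste(m$patient_id, m$modality, m$observer_id, sep = "\r")
  lut <- setNames(masks, vapply(masks, key, character(1)))
  pats <- unique(vapply(masks, function(m) m$patient_id, character(1)))
  obs <- unique(vapply(Filter(function(m) m$modality != "PET", masks),
                       function(m) m$observer_id, character(1)))
  pp <- list()
  for (pr in pairs) {
    comp <- paste(pr[1], pr[2], sep = "-")
    for (p in pats) {
      rows <- list()
      for (o in obs) {
        a <- lut[[paste(p, pr[1], if (pr[1] == "PET") "auto" else o,
                        sep = "\r")]]
        b <- lut[[paste(p, pr[2], if (pr[2] == "PET") "auto" else o,
                        sep = "\r")]]
        if (is.null(a) || is.null(b)) next
        rows[[length(rows) + 1]] <- concordance(a, b)
      }
      if (!length(rows)) next
      df <- unique(do.call(rbind, rows))  # PET-PET style duplicates collapse
      pp[[length(pp) + 1]] <-
        data.frame(comparison = comp, patient_id = p, t(mean_metrics(df)),
                   n_pairs = nrow(df), stringsAsFactors = FALSE)
    }
  }
  if (!length(pp)) stop("no comparable pairs")
  per_patient <- do.call(rbind, pp)
  summ <- do.call(rbind, lapply(split(per_patient, per_patient$comparison),
    function(d) {
      data.frame(
        metric = metric_cols,
        comparison = d$comparison[1],
        mean = vapply(metric_cols, function(mc) mean(d[[mc]]), numeric(1)),
        sd = vapply(metric_cols, function(mc)
          if (nrow(d) > 1) sd(d[[mc]]) else 0, numeric(1)),
        n_patients = nrow(d),
        row.names = NULL, stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(per_patient = per_patient, summary = summ)
}
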