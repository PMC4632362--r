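#' Cube-root transform for volume normalisation
#'
#' Volumes are cube-root transformed before mixed-effects modelling so the
#' transformed populations are approximately normal (a volume is a length
#' cubed, so the transform returns it to a length scale).
#'
#' @param v positive volume(s).
#' @return v^(1/3).
#' @export
cube_root <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("non-positive volume")
  v^(1 / 3)
}

#' Build volume records from structure masks
#'
#' @param masks list of \code{structure_mask} objects.
#' @return data.frame: patient_id, modality, observer_id, observer_role,
#'   volume_cm3.
#' @export
volume_records <- function(masks) {
  df <- do.call(rbind, lapply(masks, function(m)
    data.frame(patient_id = m$patient_id, modality = m$modality,
               observer_id = m$observer_id, observer_role = m$observer_role,
               volume_cm3 = volume_cm3(m), stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "modality", "observer_id", "observer_role",
                  "volume_cm3") %in% names(records)))
  if (any(records$volume_cm3 <= 0)) stop("non-positive volume")
  if (!all(records$modality %in% MODALITIES)) stop("invalid modality")
  invisible(records)
}

#' Linear mixed-effects model of GTV volume
#'
#' Fits a mixed model on cube-root transformed volumes. Without PET
#' (\code{include_pet = FALSE}, PET records dropped): fixed effects modality
#' and observer role, random intercepts for patient and observer. With PET
#' (\code{include_pet = TRUE}): the single auto observer per patient makes
#' observer terms unidentifiable, so fixed effect is modality only with a
#' patient random intercept. Pairwise modality contrasts are computed with
#' unadjusted p-values and flagged at the alpha = 0.02 significance level
#' used to compensate for the multiple-model comparisons.
#'
#' @param records volume record data.frame (see \code{\link{volume_records}}).
#' @param include_pet logical; include PET records and drop observer terms.
#' @param alpha significance level for contrast flags (default 0.02).
#' @return list of class \code{gtv_mixed_model}: \code{fit}, \code{fixed_effects},
#'   \code{random_effect_variances}, \code{contrasts} (data.frame with
#'   estimate, se, df, p_value, significant), \code{singular},
#'   \code{transform = "cube_root"}, \code{included_modalities}.
#' @export
fit_volume_model <- function(records, include_pet = FALSE, alpha = 0.02) {
  check_records(records)
  d <- records
  if (!include_pet) d <- d[d$modality != "PET", , drop = FALSE]
  if (length(unique(d$modality)) < 2) stop("need >= 2 modalities")
  if (length(unique(d$patient_id)) < 2) stop("need >= 2 patients")
  d$y <- cube_root(d$volume_cm3)
  d$modality <- factor(d$modality, levels = intersect(MODALITIES, d$modality))
  d$patient_id <- factor(d$patient_id)
  d$observer_id <- factor(d$observer_id)
  notes <- character(0)
  fit <- withCallingHandlers({
    if (include_pet) {
      lmerTest::lmer(y ~ modality + (1 | patient_id), data = d, REML = TRUE)
    } else {
      d$observer_role <- factor(d$observer_role,
                                levels = c("radiologist", "oncologist"))
      lmerTest::lmer(y ~ modality + observer_role +
                       (1 | patient_id) + (1 | observer_id),
                     data = d, REML = TRUE)
    }
  }, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  sing <- lme4::isSingular(fit)
  cs <- as.data.frame(coef(summary(fit)))
  fixed <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                      se = cs[, "Std. Error"], df = cs[, "df"],
                      p_value = cs[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  rev <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  em <- emmeans::emmeans(fit, "modality")
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  contrasts <- data.frame(contrast = as.character(ctr$contrast),
                          estimate = ctr$estimate, se = ctr$SE, df = ctr$df,
                          p_value = ctr$p.value,
                          significant = ctr$p.value < alpha,
                          stringsAsFactors = FALSE)
  structure(list(fit = fit, fixed_effects = fixed,
                 random_effect_variances = rev, contrasts = contrasts,
                 singular = sing, diagnostics = notes,
                 transform = "cube_root", alpha = alpha,
                 included_modalities = levels(d$modality)),
            class = "gtv_mixed_model")
}

#' @export
print.gtv_mixed_model <- function(x, ...) {
  cat(sprintf("mixed model on cube-root volumes (%s)%s\n",
              paste(x$included_modalities, collapse = ", "),
              if (x$singular) " [singular fit]" else ""))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Quantile-based normality check
#'
#' Correlation between ordered sample values and standard-normal quantiles
#' (the numeric analogue of Q-Q plot inspection). Samples from a normal
#' distribution give correlations close to 1.
#'
#' @param x numeric sample, n >= 3.
#' @param cutoff pass threshold on the correlation (default 0.95).
#' @return list: \code{statistic} (the correlation), \code{pass}.
#' @export
normality_check <- function(x, cutoff = 0.95) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("insufficient data")
  if (sd(x) == 0) stop("zero variance")
  r <- stats::cor(sort(x), qnorm(ppoints(length(x))))
  list(statistic = r, pass = r >= cutoff)
}

#' Per-patient inter-observer volume SD table
#'
#' Sample standard deviation (n - 1 denominator) of observer volumes for
#' each patient within each human-contoured modality (PET is excluded: it
#' has a single automatic observer), plus the column mean across patients.
#' Cells with fewer than two observers are reported missing and excluded
#' from the column mean.
#'
#' @param records volume record data.frame.
#' @return list of class \code{sd_table}: \code{table} (data.frame patient x
#'   modality of SDs, cm^3), \code{column_means} (named vector).
#' @export
sd_table <- function(records) {
  check_records(records)
  d <- records[records$modality != "PET", , drop = FALSE]
  mods <- intersect(MODALITIES, unique(d$modality))
  pats <- unique(d$patient_id)
  tab <- data.frame(patient_id = pats, stringsAsFactors = FALSE)
  for (m in mods) {
    tab[[m]] <- vapply(pats, function(p) {
      v <- d$volume_cm3[d$patient_id == p & d$modality == m]
      if (length(v) < 2) NA_real_ else sd(v)
    }, numeric(1))
  }
  cm <- vapply(mods, function(m) mean(tab[[m]], na.rm = TRUE), numeric(1))
  structure(list(table = tab, column_means = cm), class = "sd_table")
}

#' @export
print.sd_table <- function(x, ...) {
  print(x$table, digits = 3)
  cat("column means (cm^3):\n")
  print(round(x$column_means, 2))
  invisible(x)
}

#' ANOVA + Tukey comparison of inter-observer SD across modalities
#'
#' One-way ANOVA on the per-patient SDs across modalities, followed by
#' Tukey honest-significant-difference pairwise comparisons at 95\%
#' confidence. Per-patient SDs are treated as independent observations, as
#' the study's variability comparison does.
#'
#' @param table an \code{sd_table}.
#' @param conf_level Tukey family confidence level (default 0.95).
#' @return list: \code{anova} (the aov fit), \code{f_statistic},
#'   \code{p_value}, \code{tukey} (data.frame comparison, diff, lwr, upr,
#'   p_adj, significant).
#' @export
compare_sd_across_modalities <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "sd_table"))
  tab <- table$table
  mods <- setdiff(names(tab), "patient_id")
  long <- do.call(rbind, lapply(mods, function(m)
    data.frame(modality = m, sd = tab[[m]], stringsAsFactors = FALSE)))
  long <- long[!is.na(long$sd), , drop = FALSE]
  counts <- vapply(split(long$sd, long$modality), length, integer(1))
  if (sum(counts >= 2) < 2) stop("need >= 2 modalities with >= 2 patients")
  if (sd(long$sd) == 0)
    return(list(anova = NULL, f_statistic = NA_real_, p_value = NA_real_,
                tukey = NULL, degenerate = TRUE))
  long$modality <- factor(long$modality)
  fit <- aov(sd ~ modality, data = long)
  an <- summary(fit)[[1]]
  tk <- as.data.frame(TukeyHSD(fit, conf.level = conf_level)$modality)
  tukey <- data.frame(comparison = rownames(tk), diff = tk$diff,
                      lwr = tk$lwr, upr = tk$upr, p_adj = tk$`p adj`,
                      significant = tk$`p adj` < (1 - conf_level),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(anova = fit, f_statistic = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1], tukey = tukey, degenerate = FALSE)
}

#' Radiologist-vs-oncologist volume contrast
#'
#' The observer-role fixed effect from the mixed volume model, fitted per
#' modality and pooled over the human-contoured modalities.
#'
#' @param records volume record data.frame (PET excluded internally).
#' @param alpha significance level for flags (default 0.02).
#' @return data.frame: modality ("pooled" plus each modality), estimate
#'   (oncologist minus radiologist on the cube-root scale), se, p_value,
#'   significant, plus raw per-role mean volumes (cm^3).
#' @export
role_contrast <- function(records, alpha = 0.02) {
  check_records(records)
  d <- records[records$modality != "PET", , drop = FALSE]
  if (length(unique(d$observer_role)) < 2) stop("role contrast unavailable")
  one <- function(dd, label) {
    dd$y <- cube_root(dd$volume_cm3)
    dd$observer_role <- factor(dd$observer_role,
                               levels = c("radiologist", "oncologist"))
    fit <- if (length(unique(dd$modality)) > 1) {
      lmerTest::lmer(y ~ modality + observer_role + (1 | patient_id) +
                       (1 | observer_id), data = dd, REML = TRUE)
    } else {
      lmerTest::lmer(y ~ observer_role + (1 | patient_id) + (1 | observer_id),
                     data = dd, REML = TRUE)
    }
    cs <- coef(summary(fit))
    row <- cs["observer_roleoncologist", ]
    data.frame(modality = label, estimate = row[["Estimate"]],
               se = row[["Std. Error"]], p_value = row[["Pr(>|t|)"]],
               significant = row[["Pr(>|t|)"]] < alpha,
               mean_radiologist =
                 mean(dd$volume_cm3[dd$observer_role == "radiologist"]),
               mean_oncologist =
                 mean(dd$volume_cm3[dd$observer_role == "oncologist"]),
               stringsAsFactors = FALSE)
  }
  out <- list(one(d, "pooled"))
  for (m in intersect(MODALITIES, unique(d$modality))) {
    dm <- d[d$modality == m, , drop = FALSE]
    if (length(unique(dm$observer_role)) == 2)
      out[[length(out) + 1]] <- one(dm, m)
  }
  do.call(rbind, out)
}
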