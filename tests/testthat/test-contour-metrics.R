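test_that("overlap metrics match hand-derived values", {
  g <- mk_grid(c(6, 6, 6))
  a <- block_mask(g, c(1, 1, 1), c(2, 2, 2))
  # identity
  expect_equal(unname(overlap_metrics(a, a)), c(1, 1, 1, 1))
  # disjoint
  b <- block_mask(g, c(5, 5, 5), c(2, 2, 2))
  expect_equal(unname(overlap_metrics(a, b)), c(0, 0, 0, 0))
  # 2x2x2 cubes offset by one voxel in x: |a| = |b| = 8, I = 4, union = 12
  c2 <- block_mask(g, c(2, 1, 1), c(2, 2, 2))
  ov <- overlap_metrics(a, c2)
  expect_equal(unname(ov), c(4 / 12, 0.5, 0.5, 0.5))
})

test_that("cgd and mdc match hand-derived values", {
  g <- mk_grid(c(6, 6, 6))
  a <- block_mask(g, c(1, 1, 1), c(2, 2, 2))
  expect_equal(cgd_mm(a, a), 0)
  expect_equal(mdc_mm(a, a), 0)
  p0 <- mk_mask(g, c(1, 1, 1))
  p3 <- mk_mask(g, c(4, 1, 1))
  expect_equal(cgd_mm(p0, p3), 3.0)
  p2 <- mk_mask(g, c(3, 1, 1))
  expect_equal(mdc_mm(p0, p2), 2.0)  # both non-conforming voxels at 2 mm
  off <- block_mask(g, c(2, 1, 1), c(2, 2, 2))
  expect_equal(cgd_mm(a, off), 1.0)
  expect_equal(mdc_mm(a, off), 1.0)  # all 8 symmetric-difference voxels at 1 mm
})

test_that("metric errors: grid mismatch and empty masks", {
  g <- mk_grid(c(4, 4, 4))
  g2 <- mk_grid(c(4, 4, 4), spacing = c(2, 2, 2))
  a <- block_mask(g, c(1, 1, 1), c(2, 2, 2))
  b <- block_mask(g2, c(1, 1, 1), c(2, 2, 2))
  expect_error(overlap_metrics(a, b), "grid mismatch")
  empty <- structure_mask(g, array(FALSE, dim = g$dims))
  expect_error(overlap_metrics(a, empty), "empty structure")
  expect_error(mdc_mm(empty, a), "empty structure")
})

test_that("metric identities hold on random pairs", {
  set.seed(42)
  g <- mk_grid(c(10, 10, 10), spacing = c(1.5, 1.5, 2))
  for (rep in 1:25) {
    a <- random_blob(g)
    b <- random_blob(g)
    res <- concordance(a, b)
    # Jaccard <= Dice, exact algebraic link
    expect_equal(res$dice, 2 * res$ci / (1 + res$ci), tolerance = 1e-12)
    if (res$dice > 0) expect_lte(res$ci, res$dice)
    # directional indices swap under argument exchange
    rev <- concordance(b, a)
    expect_equal(res$se_idx, rev$incl_idx, tolerance = 1e-12)
    expect_equal(res$incl_idx, rev$se_idx, tolerance = 1e-12)
    # symmetry of the distance metrics
    expect_equal(res$cgd_mm, rev$cgd_mm, tolerance = 1e-12)
    expect_equal(res$mdc_mm, rev$mdc_mm, tolerance = 1e-12)
  }
})

test_that("metrics are translation-equivariant", {
  set.seed(5)
  g <- mk_grid(c(12, 12, 12), spacing = c(2, 2, 2))
  a <- random_blob(g, r_vox = 2.5)
  b <- random_blob(g, r_vox = 2.5)
  shift <- function(m, by) {
    vox <- array(FALSE, dim = g$dims)
    idx <- which(m$voxels, arr.ind = TRUE)
    idx <- sweep(idx, 2, as.integer(by), "+")
    vox[idx] <- TRUE
    structure_mask(g, vox)
  }
  r0 <- concordance(a, b)
  r1 <- concordance(shift(a, c(2, 1, 1)), shift(b, c(2, 1, 1)))
  for (mc in c("ci", "dice", "se_idx", "incl_idx", "cgd_mm", "mdc_mm"))
    expect_equal(r1[[mc]], r0[[mc]], tolerance = 1e-12)
})

test_that("growing the overlap strictly increases ci and dice", {
  g <- mk_grid(c(12, 6, 6))
  prev <- NULL
  for (off in 4:0) {  # fixed-size cubes sliding together
    a <- block_mask(g, c(1, 1, 1), c(4, 4, 4))
    b <- block_mask(g, c(1 + off, 1, 1), c(4, 4, 4))
    ov <- overlap_metrics(a, b)
    if (!is.null(prev)) {
      expect_gt(ov[["ci"]], prev[["ci"]])
      expect_gt(ov[["dice"]], prev[["dice"]])
    }
    prev <- ov
  }
})

test_that("six metrics agree with the naive oracle on random small masks", {
  set.seed(77)
  for (rep in 1:20) {
    g <- mk_grid(sample(4:10, 3, replace = TRUE),
                 spacing = runif(3, 0.8, 2.5))
    a <- random_blob(g)
    b <- random_blob(g)
    res <- concordance(a, b)
    oracle <- naive_metrics(a, b)
    for (mc in c("ci", "dice", "se_idx", "incl_idx", "cgd_mm", "mdc_mm"))
      expect_equal(res[[mc]], oracle[[mc]], tolerance = 1e-9)
  }
})

test_that("interobserver summary equals brute-force pair averaging", {
  g <- mk_grid(c(8, 8, 8), spacing = c(2, 2, 2))
  masks <- list()
  set.seed(3)
  for (p in c("P1", "P2")) for (o in c("A", "B", "C")) {
    m <- random_blob(g, r_vox = 2.5)
    m$patient_id <- p; m$modality <- "CT"; m$observer_id <- o
    m$observer_role <- "oncologist"
    masks[[paste(p, o)]] <- m
  }
  res <- interobserver_summary(masks, "CT")
  expect_equal(res$summary$n_patients, rep(2L, 4), ignore_attr = TRUE)
  expect_equal(res$per_patient$n_pairs, c(3, 3))
  # brute force: mean of the three pairwise results for P1
  p1 <- Filter(function(m) m$patient_id == "P1", masks)
  pairs <- rbind(concordance(p1[[1]], p1[[2]]),
                 concordance(p1[[1]], p1[[3]]),
                 concordance(p1[[2]], p1[[3]]))
  expect_equal(res$per_patient$dice[1], mean(pairs$dice), tolerance = 1e-12)
  expect_equal(res$per_patient$mdc_mm[1], mean(pairs$mdc_mm),
               tolerance = 1e-12)
  # cohort mean is the mean of per-patient means
  expect_equal(res$summary$mean[res$summary$metric == "dice"],
               mean(res$per_patient$dice), tolerance = 1e-12)
})

test_that("identical masks give perfect inter-observer concordance", {
  g <- mk_grid(c(6, 6, 6))
  base <- block_mask(g, c(2, 2, 2), c(3, 3, 3))
  masks <- list()
  for (p in c("P1", "P2")) for (o in c("A", "B")) {
    m <- base; m$patient_id <- p; m$observer_id <- o
    masks[[paste(p, o)]] <- m
  }
  res <- interobserver_summary(masks, "CT")
  s <- res$summary
  expect_equal(s$mean[s$metric == "ci"], 1)
  expect_equal(s$mean[s$metric == "dice"], 1)
  expect_equal(s$mean[s$metric == "cgd_mm"], 0)
  expect_equal(s$mean[s$metric == "mdc_mm"], 0)
  expect_equal(s$sd, rep(0, 4))
})

test_that("patients missing an observer contribute remaining pairs only", {
  g <- mk_grid(c(6, 6, 6))
  masks <- list()
  set.seed(8)
  for (o in c("A", "B", "C")) {
    m <- random_blob(g, r_vox = 2)
    m$patient_id <- "P1"; m$observer_id <- o
    masks[[paste("P1", o)]] <- m
  }
  for (o in c("A", "B")) {  # P2 lacks observer C
    m <- random_blob(g, r_vox = 2)
    m$patient_id <- "P2"; m$observer_id <- o
    masks[[paste("P2", o)]] <- m
  }
  res <- interobserver_summary(masks, "CT")
  expect_equal(res$per_patient$n_pairs, c(3, 1))
  single <- masks[c("P1 A", "P1 B")]
  expect_error(interobserver_summary(single, "MR"), "insufficient observers")
})

test_that("intermodality summary matches brute force and footnote directions", {
  g <- mk_grid(c(8, 8, 8), spacing = c(2, 2, 2))
  masks <- list()
  set.seed(12)
  for (p in c("P1", "P2")) {
    for (m in c("CT", "MR")) for (o in c("A", "B")) {
      mk <- random_blob(g, r_vox = 2.5)
      mk$patient_id <- p; mk$modality <- m; mk$observer_id <- o
      masks[[paste(p, m, o)]] <- mk
    }
    pet <- random_blob(g, r_vox = 2)
    pet$patient_id <- p; pet$modality <- "PET"; pet$observer_id <- "auto"
    masks[[paste(p, "PET")]] <- pet
  }
  res <- intermodality_summary(masks, pairs = list(c("CT", "PET"),
                                                   c("CT", "MR")))
  s <- res$summary
  # CT-PET per patient: mean over the two clinicians vs the single PET mask
  bf <- mean(c(concordance(masks[["P1 CT A"]], masks[["P1 PET"]])$se_idx,
               concordance(masks[["P1 CT B"]], masks[["P1 PET"]])$se_idx))
  pp <- res$per_patient
  expect_equal(pp$se_idx[pp$comparison == "CT-PET" & pp$patient_id == "P1"],
               bf, tolerance = 1e-12)
  # se_idx of CT-PET is proportion of CT inside PET; incl_idx of PET in CT
  one <- concordance(masks[["P2 CT A"]], masks[["P2 PET"]])
  i <- sum(masks[["P2 CT A"]]$voxels & masks[["P2 PET"]]$voxels)
  expect_equal(one$se_idx, i / sum(masks[["P2 CT A"]]$voxels))
  expect_equal(one$incl_idx, i / sum(masks[["P2 PET"]]$voxels))
  # cohort mean = mean of per-patient means
  ctmr <- pp[pp$comparison == "CT-MR", ]
  expect_equal(s$mean[s$comparison == "CT-MR" & s$metric == "dice"],
               mean(ctmr$dice), tolerance = 1e-12)
})

test_that("single patient single clinician intermodality has sd 0 and n 1", {
  g <- mk_grid(c(6, 6, 6))
  a <- block_mask(g, c(1, 1, 1), c(3, 3, 3), patient_id = "P1",
                  modality = "CT", observer_id = "A",
                  observer_role = "oncologist")
  b <- block_mask(g, c(2, 2, 2), c(3, 3, 3), patient_id = "P1",
                  modality = "MR", observer_id = "A",
                  observer_role = "oncologist")
  res <- intermodality_summary(list(a, b), pairs = list(c("CT", "MR")))
  expect_equal(unique(res$summary$sd), 0)
  expect_equal(unique(res$summary$n_patients), 1L)
  one <- concordance(a, b)
  expect_equal(res$summary$mean[res$summary$metric == "dice"], one$dice)
  expect_error(intermodality_summary(list(a), pairs = list(c("CT", "MR"))),
               "no comparable pairs")
})
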