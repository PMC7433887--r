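test_that("maximum-intensity projection takes the per-pixel max over z", {
  acq <- acquisition_params(frame_shape = c(64, 64), n_z_planes = 1)
  one <- generate_well_stack(phenotype_params(n_organoids = 0), acq, seed = 1)
  pr <- project_stack(one$stack)
  expect_equal(pr$actin_2d, one$stack$actin[, , 1])

  # planted max in a known plane
  stack <- structure(list(nuclei = array(0, c(4, 4, 6)),
                          actin = array(0, c(4, 4, 6)),
                          acquisition = acq, well_id = "x"),
                     class = "image_stack")
  stack$actin[2, 3, 4] <- 10
  pr <- project_stack(stack)
  expect_equal(pr$actin_2d[2, 3], 10)
  expect_equal(pr$focus_map[2, 3], 4L)

  # 25-plane stack projects to a single frame per channel
  acq25 <- small_acq(96)
  st <- generate_well_stack(phenotype_params(n_organoids = 1,
                                             organoid_radius_mean = 25,
                                             organoid_radius_sd = 2),
                            acq25, seed = 2)$stack
  pr <- project_stack(st)
  expect_equal(dim(pr$actin_2d), c(96, 96))
  expect_true(all(pr$focus_map >= 1 & pr$focus_map <= 25))

  bad <- st
  bad$nuclei <- bad$nuclei[, , 1:10]
  expect_error(project_stack(bad), "shapes differ")
})

test_that("organoid segmentation recovers well-separated organoids", {
  acq <- small_acq(192)
  blank <- generate_well_stack(phenotype_params(n_organoids = 0), acq,
                               seed = 3)
  expect_equal(max(segment_organoids(project_stack(blank$stack))), 0)

  res <- generate_well_stack(phenotype_params(n_organoids = 5), acq, seed = 4)
  lab <- segment_organoids(project_stack(res$stack))
  expect_equal(max(lab), 5)
  # labels are consecutive positive integers
  expect_setequal(unique(as.vector(lab)), 0:5)
  # each ground-truth centre is covered by exactly one label, within a radius
  for (i in seq_len(nrow(res$truth))) {
    tr <- res$truth[i, ]
    oid <- lab[round(tr$y), round(tr$x)]
    expect_gt(oid, 0)
    idx <- which(lab == oid, arr.ind = TRUE)
    cen <- colMeans(idx)
    d_px <- sqrt(sum((cen - c(tr$y, tr$x))^2)) * acq$pixel_size
    expect_lt(d_px, tr$radius_um)
  }
})

test_that("touching organoids are split by seeded watershed", {
  # two discs overlapping by less than 30% of the radius, nuclei density
  # seeds at their centres
  pr <- manual_projection(frame = 128,
                          discs = list(c(60, 45, 20, 700),
                                       c(60, 80, 20, 700)),
                          blobs = list(c(60, 45), c(60, 80),
                                       c(52, 40), c(68, 50),
                                       c(52, 85), c(68, 75)))
  # seed smoothing/separation scaled to the fixture's 20 px organoids
  lab <- segment_organoids(pr, min_area = 300, seed_sigma = 8,
                           min_seed_dist = 15)
  expect_equal(max(lab), 2)
  expect_gt(sum(lab == 1), 300)
  expect_gt(sum(lab == 2), 300)
})

test_that("lumens are detected with correct parent assignment", {
  acq <- small_acq(192)
  solid <- generate_well_stack(
    phenotype_params(n_organoids = 2, lumen_fraction = 0), acq, seed = 6)
  m <- segment_well(solid$stack)
  expect_length(m$parent_of_lumen, 0)

  res <- generate_well_stack(
    phenotype_params(n_organoids = 2, lumen_fraction = 0.5), acq, seed = 7)
  m <- segment_well(res$stack)
  expect_length(m$parent_of_lumen, 2)
  expect_setequal(unname(m$parent_of_lumen), c(1, 2))
  # projected concentric discs: lumen/organoid area ratio ~ 0.25 (+-20%)
  for (oid in 1:2) {
    lid <- as.integer(names(m$parent_of_lumen)[m$parent_of_lumen == oid])
    ratio <- sum(m$lumen_labels %in% lid) / sum(m$organoid_labels == oid)
    expect_gt(ratio, 0.25 * 0.8)
    expect_lt(ratio, 0.25 * 1.2)
  }
})

test_that("nuclei are counted and assigned to their organoid", {
  acq <- small_acq(160)
  res <- generate_well_stack(
    phenotype_params(n_organoids = 2, nuclei_per_organoid_mean = 12,
                     organoid_radius_mean = 45, organoid_radius_sd = 2),
    acq, seed = 3, nuclei_placement = "ring")
  m <- segment_well(res$stack)
  got <- table(factor(m$parent_of_nucleus, levels = 1:2))
  expect_equal(sort(as.integer(got)), sort(res$truth$n_nuclei))

  blank <- generate_well_stack(phenotype_params(n_organoids = 0), acq,
                               seed = 5)
  mb <- segment_well(blank$stack)
  expect_length(mb$parent_of_nucleus, 0)

  # a nucleus blob outside any organoid is not assigned
  pr <- manual_projection(frame = 128,
                          discs = list(c(40, 40, 18, 700)),
                          blobs = list(c(40, 40), c(100, 100)))
  lab <- segment_organoids(pr, min_area = 300)
  nuc <- segment_nuclei(pr, lab)
  expect_true(all(unname(nuc$parent) == 1))
})

test_that("out-of-focus and border organoids are filtered, idempotently", {
  acq <- small_acq(192)
  # all in focus: filtering is a no-op
  res <- generate_well_stack(phenotype_params(n_organoids = 4), acq, seed = 8)
  m0 <- segment_well(res$stack, filter = FALSE)
  m1 <- filter_objects(m0, res$stack)
  expect_equal(max(m1$organoid_labels), max(m0$organoid_labels))

  # generator-flagged out-of-focus organoids disappear
  resf <- generate_well_stack(
    phenotype_params(n_organoids = 5, oof_fraction = 0.2), acq, seed = 11)
  expect_equal(sum(!resf$truth$in_focus), 1)
  mf <- segment_well(resf$stack)
  n_in <- sum(resf$truth$in_focus)
  expect_equal(max(mf$organoid_labels), n_in)
  # surviving labels sit on in-focus ground-truth organoids
  for (i in which(resf$truth$in_focus)) {
    tr <- resf$truth[i, ]
    expect_gt(mf$organoid_labels[round(tr$y), round(tr$x)], 0)
  }
  oof <- resf$truth[!resf$truth$in_focus, ]
  expect_equal(mf$organoid_labels[round(oof$y), round(oof$x)], 0L)

  # idempotence
  mf2 <- filter_objects(mf, resf$stack)
  expect_identical(mf$organoid_labels, mf2$organoid_labels)
  expect_identical(mf$parent_of_nucleus, mf2$parent_of_nucleus)

  # an organoid clipped by the frame border is removed
  pr <- manual_projection(frame = 128, discs = list(c(5, 60, 16, 700),
                                                    c(70, 60, 18, 700)),
                          blobs = list(c(70, 60)))
  lab <- segment_organoids(pr, min_area = 200)
  stack0 <- structure(list(
    nuclei = array(pr$nuclei_2d, c(128, 128, 1)),
    actin = array(pr$actin_2d, c(128, 128, 1)),
    acquisition = acquisition_params(frame_shape = c(128, 128),
                                     n_z_planes = 1),
    well_id = "x"), class = "image_stack")
  masks <- structure(list(organoid_labels = lab,
                          lumen_labels = array(0L, dim(lab)),
                          parent_of_lumen = integer(0),
                          nucleus_labels = array(0L, dim(lab)),
                          parent_of_nucleus = integer(0),
                          focus_map = pr$focus_map),
                     class = "label_masks")
  out <- filter_objects(masks, stack0)
  expect_equal(max(out$organoid_labels), 1)
  expect_equal(out$organoid_labels[70, 60], 1L)
})

test_that("masks nest: lumens inside parents, nuclei inside organoids", {
  acq <- small_acq(192)
  res <- generate_well_stack(phenotype_params(n_organoids = 4), acq, seed = 13)
  m <- segment_well(res$stack)
  for (lid in as.integer(names(m$parent_of_lumen))) {
    oid <- m$parent_of_lumen[[as.character(lid)]]
    sel <- m$lumen_labels == lid
    expect_true(all(m$organoid_labels[sel] == oid))
  }
  for (nid in as.integer(names(m$parent_of_nucleus))) {
    oid <- m$parent_of_nucleus[[as.character(nid)]]
    idx <- which(m$nucleus_labels == nid, arr.ind = TRUE)
    cen <- round(colMeans(idx))
    expect_equal(m$organoid_labels[cen[1], cen[2]], oid)
  }
})
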