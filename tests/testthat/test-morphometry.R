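# build a label_masks object around hand-made masks for direct feature tests
masks_from_labels <- function(olab, lumen = NULL, lum_parent = integer(0),
                              nuc = NULL, nuc_parent = integer(0),
                              actin = NULL, nuclei = NULL) {
  d <- dim(olab)
  if (is.null(lumen)) lumen <- array(0L, d)
  if (is.null(nuc)) nuc <- array(0L, d)
  if (is.null(actin)) actin <- matrix(100, d[1], d[2])
  if (is.null(nuclei)) nuclei <- matrix(100, d[1], d[2])
  m <- structure(list(organoid_labels = olab, lumen_labels = lumen,
                      parent_of_lumen = lum_parent, nucleus_labels = nuc,
                      parent_of_nucleus = nuc_parent,
                      focus_map = array(1L, d)),
                 class = "label_masks")
  m$projection <- structure(list(nuclei_2d = nuclei, actin_2d = actin,
                                 focus_map = m$focus_map),
                            class = "channel_projection")
  m
}

test_that("shape descriptors match brute-force geometry oracles", {
  disc <- disc_mask(32, 16, 16, 10)
  m <- masks_from_labels(array(as.integer(disc), c(32, 32)))
  rec <- extract_organoid_features(m, pixel_size = 2)

  # area: exact pixel count; um2 conversion
  expect_equal(rec$organoid_area_px, sum(disc))
  expect_equal(rec$organoid_area_um2, sum(disc) * 4)
  # solidity of a filled disc ~ 1; hull area matches lattice-count oracle
  expect_gte(rec$organoid_solidity, 0.98)
  expect_lte(rec$organoid_solidity, 1)
  idx <- which(disc, arr.ind = TRUE)
  expect_equal(organoidscreen:::hull_area_px(idx[, 1], idx[, 2]),
               oracle_hull_area(disc), tolerance = 0.01)
  # perimeter within 2% of an independently marched boundary length
  expect_equal(rec$organoid_perimeter_px, oracle_perimeter(disc),
               tolerance = 0.02)

  # crescent: disc minus offset disc is strongly non-convex
  cres <- disc_mask(32, 16, 16, 10) & !disc_mask(32, 16, 22, 8)
  mc <- masks_from_labels(array(as.integer(cres), c(32, 32)))
  rc <- extract_organoid_features(mc, pixel_size = 2)
  expect_lt(rc$organoid_solidity, 0.9)
  expect_equal(rc$organoid_area_px, sum(cres))
  expect_equal(organoidscreen:::hull_area_px(
    which(cres, arr.ind = TRUE)[, 1], which(cres, arr.ind = TRUE)[, 2]),
    oracle_hull_area(cres), tolerance = 0.01)

  # ellipse eccentricity and perimeter against the oracle
  n <- 48
  ix <- matrix(rep(seq_len(n), each = n), n, n)
  iy <- matrix(rep(seq_len(n), n), n, n)
  ell <- ((ix - 24) / 18)^2 + ((iy - 24) / 9)^2 <= 1
  me <- masks_from_labels(array(as.integer(ell), c(n, n)))
  re <- extract_organoid_features(me, pixel_size = 1)
  expect_equal(re$organoid_eccentricity, sqrt(1 - (9 / 18)^2),
               tolerance = 0.05)
  expect_equal(re$organoid_perimeter_px, oracle_perimeter(ell),
               tolerance = 0.02)
})

test_that("rendered nucleus counts propagate into the feature table", {
  acq <- small_acq(160)
  res <- generate_well_stack(
    phenotype_params(n_organoids = 1, nuclei_per_organoid_mean = 12),
    acq, seed = 21, nuclei_placement = "ring")
  m <- segment_well(res$stack)
  rec <- extract_organoid_features(m, pixel_size = acq$pixel_size)
  expect_equal(rec$organoid_nucleus_count, res$truth$n_nuclei)
})

test_that("branch point counting distinguishes blobs from branched shapes", {
  # a plus-shaped ribbon has a 4-way junction; a disc has none
  n <- 41
  plus <- matrix(FALSE, n, n)
  plus[19:23, 5:37] <- TRUE
  plus[5:37, 19:23] <- TRUE
  expect_gte(organoidscreen:::count_branch_points(plus), 1)
  expect_equal(organoidscreen:::count_branch_points(disc_mask(21, 11, 11, 7)),
               0)
})

test_that("well aggregation computes mean/median/sd/sum and counts", {
  reg <- feature_registry()
  rec <- as.data.frame(matrix(0, 2, length(reg$per_organoid)))
  names(rec) <- reg$per_organoid
  rec$organoid_area_px <- c(100, 200)
  rec$organoid_lumen_count <- c(1, 0)
  rec$organoid_nucleus_count <- c(3, 4)
  rec <- cbind(data.frame(well_id = "w", organoid_id = 1:2), rec)
  prof <- aggregate_well(rec, list(well = "w", compound = "X", dose_nM = 1,
                                   role = "treated"))
  expect_equal(prof$organoid_area_px__mean, 150)
  expect_equal(prof$organoid_area_px__sum, 300)
  expect_equal(prof$organoid_area_px__median, 150)
  expect_equal(prof$n_organoids, 2)
  expect_equal(prof$n_lumens_total, 1)
  expect_equal(prof$n_nuclei_total, 7)

  # single organoid: mean = median = value, sd = 0
  p1 <- aggregate_well(rec[1, ], list(well = "w", compound = "X",
                                      dose_nM = 1, role = "treated"))
  expect_equal(p1$organoid_area_px__mean, 100)
  expect_equal(p1$organoid_area_px__median, 100)
  expect_equal(p1$organoid_area_px__sd, 0)

  # empty well: degenerate profile
  expect_warning(p0 <- aggregate_well(rec[0, ],
                                      list(well = "w", compound = "X",
                                           dose_nM = 1, role = "treated")),
                 "degenerate")
  expect_equal(p0$n_organoids, 0)
})

test_that("the registry expands to at least 600 stable well columns", {
  reg <- feature_registry()
  expect_gte(length(reg$well_columns), 600)
  expect_false(any(duplicated(reg$well_columns)))
  expect_identical(reg$well_columns, feature_registry()$well_columns)
})

test_that("features are translation invariant and scale as areas should", {
  disc <- disc_mask(64, 30, 28, 10)
  shifted <- disc_mask(64, 35, 41, 10)
  set.seed(9)
  # constant background; textured intensities only under the object, carried
  # verbatim to the shifted position
  img <- matrix(200, 64, 64)
  img[which(disc)] <- rnorm(sum(disc), 400, 30)
  img_s <- matrix(200, 64, 64)
  img_s[which(shifted)] <- img[which(disc)]
  m1 <- masks_from_labels(array(as.integer(disc), c(64, 64)), actin = img,
                          nuclei = img)
  m2 <- masks_from_labels(array(as.integer(shifted), c(64, 64)),
                          actin = img_s, nuclei = img_s)
  r1 <- extract_organoid_features(m1, pixel_size = 2)
  r2 <- extract_organoid_features(m2, pixel_size = 2)
  fc <- setdiff(names(r1), c("well_id", "organoid_id"))
  expect_equal(as.numeric(r1[, fc]), as.numeric(r2[, fc]),
               tolerance = 1e-10)

  # doubling linear size: area x4 (+-5%), shape ratios stable (+-0.05)
  small <- disc_mask(64, 32, 32, 8)
  large <- disc_mask(64, 32, 32, 16)
  rs <- extract_organoid_features(
    masks_from_labels(array(as.integer(small), c(64, 64))), pixel_size = 1)
  rl <- extract_organoid_features(
    masks_from_labels(array(as.integer(large), c(64, 64))), pixel_size = 1)
  expect_equal(rl$organoid_area_px / rs$organoid_area_px, 4,
               tolerance = 0.05)
  expect_lt(abs(rl$organoid_solidity - rs$organoid_solidity), 0.05)
  expect_lt(abs(rl$organoid_eccentricity - rs$organoid_eccentricity), 0.05)
})

test_that("profiles share an identical schema across wells and runs", {
  acq <- small_acq(128)
  p <- lapply(c(31, 32), function(s) {
    res <- generate_well_stack(phenotype_params(n_organoids = 2), acq,
                               seed = s)
    profile_well(res$stack, list(well = paste0("W", s), compound = "X",
                                 dose_nM = 1, role = "treated"))
  })
  expect_identical(names(p[[1]]), names(p[[2]]))
  expect_gte(length(profile_feature_columns(p[[1]])), 600)
})
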