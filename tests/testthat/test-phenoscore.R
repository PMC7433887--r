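# synthetic profile table: n1 control wells + n2 high-dose wells (+ optional
# intermediate doses), p features of unit-variance noise with `planted`
# features shifted by `shift` SD in treated wells proportional to theta
synthetic_profiles <- function(n1 = 8, n2 = 8, p = 600, planted = integer(0),
                               shift = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  X[(n1 + 1):(n1 + n2), planted] <- X[(n1 + 1):(n1 + n2), planted] + shift
  colnames(X) <- sprintf("f%03d", seq_len(p))
  data.frame(well = sprintf("W%02d", seq_len(n1 + n2)),
             compound = rep(c("DMSO", "CMP"), c(n1, n2)),
             dose_nM = rep(c(0, 100), c(n1, n2)),
             role = rep(c("control", "treated"), c(n1, n2)),
             n_organoids = 5, X, check.names = FALSE)
}

test_that("planted discriminating features are ranked into the top k", {
  prof <- synthetic_profiles(planted = 1:3, seed = 11)
  sel <- train_feature_space(prof, k = 10)
  expect_length(sel$selected_features, 10)
  expect_true(all(c("f001", "f002", "f003") %in% sel$selected_features))
  expect_true(all(sel$train_sd > 0))
})

test_that("selection is deterministic and well-defined with no signal", {
  prof <- synthetic_profiles(planted = integer(0), seed = 3)
  s1 <- train_feature_space(prof, k = 10)
  s2 <- train_feature_space(prof, k = 10)
  expect_identical(s1$selected_features, s2$selected_features)
  expect_identical(s1$control_centroid, s2$control_centroid)
  expect_true(is.finite(s1$separation))
})

test_that("an insensitive line yields no dose-response fit", {
  # full dose series of pure-noise profiles: chance separation between the
  # training classes inflates top-dose distances (top-10-of-600 selection
  # bias), but the dose trend has no explanatory power, so the r-squared
  # rule must reject the curve
  doses <- 3160 / (10^0.5)^(0:8)
  set.seed(31)
  n_ctrl <- 8; n_rep <- 8; p <- 600
  wells <- data.frame(
    well = sprintf("W%03d", seq_len(n_ctrl + 9 * n_rep)),
    compound = c(rep("DMSO", n_ctrl), rep("C", 9 * n_rep)),
    dose_nM = c(rep(0, n_ctrl), rep(doses, each = n_rep)),
    role = c(rep("control", n_ctrl), rep("treated", 9 * n_rep)),
    n_organoids = 5)
  X <- matrix(rnorm(nrow(wells) * p), nrow(wells), p)
  colnames(X) <- sprintf("f%03d", seq_len(p))
  res <- analyze_screen(cbind(wells, X), control_label = "DMSO")
  expect_equal(res$fits[["C"]]$status, "no_fit")
})

test_that("k equal to the feature count selects everything, errors beyond", {
  prof <- synthetic_profiles(p = 12, planted = 1, seed = 5)
  sel <- train_feature_space(prof, k = 12)
  expect_setequal(sel$selected_features, sprintf("f%03d", 1:12))
  expect_error(train_feature_space(prof, k = 13), "k exceeds")
  expect_error(train_feature_space(prof[c(1, 9:16), ], k = 3),
               "at least 2")
})

test_that("distances equal the brute-force standardized Euclidean form", {
  set.seed(7)
  for (rep in 1:5) {
    feats <- sprintf("g%02d", 1:10)
    sel <- structure(list(
      selected_features = feats,
      train_mean = setNames(rnorm(10), feats),
      train_sd = setNames(runif(10, 0.5, 3), feats),
      component_loadings = setNames(rep(0.3, 10), feats),
      control_centroid = setNames(rnorm(10, 0, 0.3), feats)),
      class = "feature_selection")
    x <- setNames(rnorm(10, 1, 2), feats)
    prof <- as.data.frame(as.list(x))
    names(prof) <- feats
    d <- score_well(prof, sel)$distance
    # independent accumulation loop
    acc <- 0
    for (f in feats) {
      z <- (x[[f]] - sel$train_mean[[f]]) / sel$train_sd[[f]]
      acc <- acc + (z - sel$control_centroid[[f]])^2
    }
    expect_equal(d, sqrt(acc), tolerance = 1e-9)

    # D = 0 exactly at the control centroid
    x0 <- sel$train_mean + sel$train_sd * sel$control_centroid
    p0 <- as.data.frame(as.list(x0)); names(p0) <- feats
    expect_equal(score_well(p0, sel)$distance, 0, tolerance = 1e-12)

    # unit displacement along one standardized axis gives D = 1
    x1 <- x0
    x1[[3]] <- x1[[3]] + sel$train_sd[[3]]
    p1 <- as.data.frame(as.list(x1)); names(p1) <- feats
    expect_equal(score_well(p1, sel)$distance, 1, tolerance = 1e-12)
  }

  # missing feature is an error
  sel <- structure(list(selected_features = c("a", "b"),
                        train_mean = c(a = 0, b = 0),
                        train_sd = c(a = 1, b = 1),
                        control_centroid = c(a = 0, b = 0)),
                   class = "feature_selection")
  expect_error(score_well(data.frame(a = 1), sel), "missing")
})

test_that("distances are invariant to rescaling a raw feature", {
  prof <- synthetic_profiles(planted = 1:3, seed = 13)
  sel <- train_feature_space(prof, k = 10)
  d0 <- score_plate(prof, sel)$distances$distance

  prof2 <- prof
  prof2$f001 <- prof2$f001 * 37.5
  prof2$f200 <- prof2$f200 * 0.004
  sel2 <- train_feature_space(prof2, k = 10)
  d1 <- score_plate(prof2, sel2)$distances$distance
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("plate summaries group by condition with replicate counts", {
  prof <- synthetic_profiles(n1 = 4, n2 = 8, p = 20, planted = 1:2, seed = 2)
  # make the 8 treated wells two identical groups of replicates
  prof$dose_nM[prof$role == "treated"] <- rep(c(10, 100), each = 4)
  for (f in sprintf("f%03d", 1:20))
    prof[[f]][prof$dose_nM == 10] <- prof[[f]][prof$dose_nM == 10][1]
  sel <- train_feature_space(prof, k = 5)
  sc <- score_plate(prof, sel)
  summ <- sc$summary
  expect_equal(summ$n[summ$dose_nM == 10], 4)
  expect_equal(summ$sd_distance[summ$dose_nM == 10], 0)
  expect_equal(nrow(sc$distances), nrow(prof))
})

test_that("selections persist through JSON round-trip", {
  prof <- synthetic_profiles(planted = 1:3, p = 50, seed = 17)
  sel <- train_feature_space(prof, k = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_feature_selection(sel, path)
  back <- load_feature_selection(path)
  expect_identical(back$selected_features, sel$selected_features)
  expect_equal(back$train_mean, sel$train_mean, tolerance = 1e-12)
  d1 <- score_well(prof[3, ], sel)$distance
  d2 <- score_well(prof[3, ], back)$distance
  expect_equal(d1, d2, tolerance = 1e-10)
})
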