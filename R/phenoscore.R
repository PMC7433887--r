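# Phenotypic fingerprinting: discriminating-feature selection between
# vehicle-control and high-dose wells, then Euclidean-distance scoring of
# every well against the control centroid in the standardized selected
# feature space.

#' Train the discriminating feature space
#'
#' Takes per-well profiles for one compound (plus its vehicle controls),
#' forms two training classes — control wells and wells at the highest dose —
#' drops zero-variance features, standardizes by the training mean and the
#' control-class standard deviation (so effect sizes are expressed in units
#' of control replicate variability and are not shrunk by the between-class
#' shift), fits a principal component analysis on the standardized
#' training matrix, picks the component whose scores best separate the two
#' classes (largest absolute class-mean difference in pooled-SD units; or
#' unconditionally PC1 with `strategy = "pc1"`), and retains the `k` features
#' with the largest absolute loadings on that component. Ties are broken by
#' feature name order. The control centroid in the standardized space is
#' stored for scoring.
#'
#' @param profiles Profile data.frame (rows = wells) as produced by
#'   [aggregate_well()] / [screen_profiles()]; wells of one compound plus
#'   controls.
#' @param control_label Label of the control condition in `compound`
#'   (default `"DMSO"`).
#' @param high_dose_rule Function mapping the treated subset of `profiles`
#'   to a logical vector marking high-dose training wells; the default
#'   selects the wells at each compound's maximum dose, so a multi-compound
#'   table trains one shared feature space against the whole series' top
#'   doses.
#' @param k Number of features to retain (default 10).
#' @param strategy `"best_separating"` (default) or `"pc1"`.
#' @param redundancy_cutoff Features whose within-class correlation with an
#'   already-selected feature exceeds this value are skipped during
#'   selection (default 0.9; 1 disables), so the k slots hold distinct
#'   morphological axes rather than near-duplicates of one statistic.
#' @return An object of class `feature_selection`: `selected_features`,
#'   `train_mean`, `train_sd`, `component_loadings`, `control_centroid`,
#'   `training_wells`, `component`, `separation`, `strategy`.
#' @export
train_feature_space <- function(profiles, control_label = "DMSO",
                                high_dose_rule = NULL, k = 10,
                                strategy = c("best_separating", "pc1"),
                                redundancy_cutoff = 0.9) {
  strategy <- match.arg(strategy)
  profiles <- profiles[profiles$n_organoids > 0, , drop = FALSE]
  is_ctrl <- profiles$compound == control_label | profiles$role == "control"
  treated <- profiles[!is_ctrl, , drop = FALSE]
  if (is.null(high_dose_rule))
    high_dose_rule <- function(tr)
      tr$dose_nM >= stats::ave(tr$dose_nM, tr$compound, FUN = max)
  hi <- treated[high_dose_rule(treated), , drop = FALSE]
  ctl <- profiles[is_ctrl, , drop = FALSE]
  if (nrow(ctl) < 2 || nrow(hi) < 2)
    stop("need at least 2 control and 2 high-dose wells for training")

  fcols <- profile_feature_columns(profiles)
  Xc <- as.matrix(ctl[, fcols, drop = FALSE])
  Xh <- as.matrix(hi[, fcols, drop = FALSE])
  X <- rbind(Xc, Xh)
  cls <- rep(c(0L, 1L), c(nrow(Xc), nrow(Xh)))

  tot_sd <- apply(X, 2, stats::sd)
  keep <- which(tot_sd > 0 & apply(is.finite(X), 2, all))
  if (length(keep) < 1) stop("no informative features")
  if (k > length(keep)) stop("k exceeds the number of usable features")
  X <- X[, keep, drop = FALSE]

  mu <- colMeans(X)
  csd <- apply(X[cls == 0, , drop = FALSE], 2, stats::sd)
  # scale by the control-class SD so effect sizes are in units of control
  # replicate variability, floored at a fraction of the total training SD:
  # with few control wells the smallest of ~600 sample SDs is tiny by
  # chance, and an unfloored denominator would let a single feature
  # dominate every distance
  sdv <- pmax(csd, 0.2 * tot_sd[keep])
  Z <- scale(X, center = mu, scale = sdv)

  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (strategy == "pc1") {
    comp <- 1L
    sep_all <- component_separation(pc$x, cls)
  } else {
    sep_all <- component_separation(pc$x, cls)
    comp <- which.max(sep_all)
  }
  ld <- pc$rotation[, comp]
  # deterministic sign: largest-|loading| entry positive
  imax <- which.max(abs(ld))
  if (ld[imax] < 0) ld <- -ld
  ord <- order(-abs(ld), names(ld))

  # redundancy filter: walk the ranking and skip features whose
  # within-class (residual) correlation with an already-accepted feature
  # exceeds the cutoff — near-duplicate statistics of the same measurement
  # would otherwise fill every slot and leave the distance with a single
  # undiversified axis. If the filter exhausts the list, the best remaining
  # features top up to k.
  R <- Z
  R[cls == 0, ] <- scale(Z[cls == 0, , drop = FALSE], scale = FALSE)
  R[cls == 1, ] <- scale(Z[cls == 1, , drop = FALSE], scale = FALSE)
  accepted <- integer(0)
  for (j in ord) {
    if (length(accepted) >= k) break
    if (length(accepted)) {
      r <- suppressWarnings(abs(stats::cor(R[, j], R[, accepted,
                                                     drop = FALSE])))
      if (any(r > redundancy_cutoff, na.rm = TRUE)) next
    }
    accepted <- c(accepted, j)
  }
  if (length(accepted) < k)
    accepted <- c(accepted,
                  setdiff(ord, accepted)[seq_len(k - length(accepted))])
  selected <- colnames(Z)[accepted]

  cz <- scale(Xc[, selected, drop = FALSE], center = mu[selected],
              scale = sdv[selected])
  structure(list(selected_features = selected,
                 train_mean = mu[selected], train_sd = sdv[selected],
                 component_loadings = ld[selected],
                 control_centroid = colMeans(cz),
                 training_wells = list(control = ctl$well, high = hi$well),
                 component = comp, separation = unname(sep_all[comp]),
                 strategy = strategy),
            class = "feature_selection")
}

# absolute class-mean difference of each component's scores, in pooled
# within-class SD units (Inf when the scores separate perfectly)
component_separation <- function(scores, cls) {
  apply(scores, 2, function(s) {
    d <- abs(mean(s[cls == 1]) - mean(s[cls == 0]))
    sp <- sqrt((stats::var(s[cls == 0]) + stats::var(s[cls == 1])) / 2)
    if (sp < 1e-12) {
      if (d < 1e-12) 0 else Inf
    } else d / sp
  })
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("feature selection (", x$strategy, ", component ", x$component,
      ", separation ", signif(x$separation, 3), "):\n", sep = "")
  cat(paste0("  ", x$selected_features, collapse = "\n"), "\n")
  invisible(x)
}

#' Euclidean phenotypic distance of one well
#'
#' Standardizes the well's selected features with the training mean/SD and
#' returns the Euclidean distance to the control centroid:
#' `D = sqrt(sum_f ((x_f - mu_f)/sd_f - c_f)^2)`.
#'
#' @param profile One-row profile data.frame (or named vector/list) holding
#'   all selected features.
#' @param selection A `feature_selection` from [train_feature_space()].
#' @param control_centroid Optional override of the stored centroid.
#' @return A one-row data.frame `well, compound, dose_nM, distance` (metadata
#'   columns `NA` when not present in `profile`).
#' @export
score_well <- function(profile, selection, control_centroid = NULL) {
  stopifnot(inherits(selection, "feature_selection"))
  if (is.null(control_centroid)) control_centroid <-
      selection$control_centroid
  getf <- function(f) {
    v <- if (is.data.frame(profile) || is.list(profile)) profile[[f]]
    else profile[f]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stop("profile is missing selected feature ", f)
    as.numeric(v)
  }
  x <- vapply(selection$selected_features, getf, numeric(1))
  z <- (x - selection$train_mean) / selection$train_sd
  d <- sqrt(sum((z - control_centroid)^2))
  meta <- function(f) if (!is.null(profile[[f]])) profile[[f]] else NA
  data.frame(well = meta("well"), compound = meta("compound"),
             dose_nM = meta("dose_nM"), distance = d)
}

#' Score every well of a plate and summarise by condition
#'
#' Scores all non-degenerate wells with [score_well()] and groups the
#' distances by (compound, dose), reporting the mean distance, its standard
#' deviation and the replicate count, as plotted in replicate-mean dose
#' response curves.
#'
#' @param profiles Profile data.frame.
#' @param selection A `feature_selection`.
#' @return A list with `distances` (well-level data.frame) and `summary`
#'   (per-condition data.frame `compound, dose_nM, mean_distance,
#'   sd_distance, n`).
#' @export
score_plate <- function(profiles, selection) {
  profiles <- profiles[profiles$n_organoids > 0, , drop = FALSE]
  dist <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i)
    score_well(profiles[i, , drop = FALSE], selection)))
  key <- interaction(dist$compound, dist$dose_nM, drop = TRUE)
  summ <- do.call(rbind, lapply(split(dist, key), function(g)
    data.frame(compound = g$compound[1], dose_nM = g$dose_nM[1],
               mean_distance = mean(g$distance),
               sd_distance = if (nrow(g) > 1) stats::sd(g$distance) else 0,
               n = nrow(g))))
  summ <- summ[order(summ$compound, summ$dose_nM), ]
  rownames(summ) <- NULL
  list(distances = dist, summary = summ)
}

#' Persist a feature selection as JSON
#' @param selection A `feature_selection`.
#' @param path Output file.
#' @export
save_feature_selection <- function(selection, path) {
  jsonlite::write_json(unclass(selection), path, auto_unbox = TRUE,
                       digits = NA)
}

#' Load a feature selection saved by [save_feature_selection()]
#' @param path JSON file.
#' @return A `feature_selection`.
#' @export
load_feature_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("train_mean", "train_sd", "component_loadings",
              "control_centroid"))
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]),
                                obj$selected_features)
  structure(obj, class = "feature_selection")
}
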