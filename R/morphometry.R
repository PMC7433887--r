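# Morphometric feature extraction.
#
# Features are computed per organoid for three mask classes (organoid, lumen,
# nucleus), covering size, shape (solidity, eccentricity, form factor,
# extent), topology (skeleton branch points, lumen/nucleus counts) and
# intensity statistics per channel for the whole object and its boundary
# shell, in both pixel and micrometre units. Per-well aggregation (mean,
# median, sd, sum) expands the registry to > 600 columns.

shape_descriptors <- c("area_px", "area_um2", "equiv_diameter_px",
                       "equiv_diameter_um", "perimeter_px", "perimeter_um",
                       "radius_mean_px", "radius_sd_px", "major_axis_px",
                       "minor_axis_px", "aspect_ratio", "eccentricity",
                       "solidity", "extent", "form_factor", "branch_points")

intensity_descriptors <- as.vector(outer(
  c("mean", "sd", "median", "mad", "q10", "q25", "q75", "q90"),
  as.vector(outer(c("actin", "nuclei"), c("object", "shell"),
                  function(ch, rg) paste(ch, rg, sep = "_"))),
  function(st, chrg) paste0("int_", chrg, "_", st)))

relational_descriptors <- c("lumen_count", "nucleus_count",
                            "lumen_area_total_px", "lumen_area_total_um2",
                            "lumen_area_ratio", "has_lumen",
                            "nuclei_per_area", "lumen_centroid_offset_px",
                            "lumen_centroid_offset_um")

#' The default morphometric feature registry
#'
#' Enumerates every per-organoid feature (mask class x descriptor) and the
#' per-well aggregations applied to each. Expanded to well columns the
#' registry yields more than 600 features.
#'
#' @return A list with `per_organoid` (character vector of per-organoid
#'   feature names), `aggregations` (`mean`, `median`, `sd`, `sum`) and
#'   `well_columns` (fully expanded per-well column names, stable order).
#' @examples
#' length(feature_registry()$well_columns)
#' @export
feature_registry <- function() {
  per_org <- c(
    as.vector(t(outer(c("organoid", "lumen", "nucleus"),
                      c(shape_descriptors, intensity_descriptors),
                      paste, sep = "_"))),
    paste0("organoid_", relational_descriptors))
  aggregations <- c("mean", "median", "sd", "sum")
  wells <- c(as.vector(outer(per_org, aggregations,
                             function(f, a) paste0(f, "__", a))),
             "n_organoids", "n_lumens_total", "n_nuclei_total")
  list(per_organoid = per_org, aggregations = aggregations,
       well_columns = wells)
}

# region properties of one pixel set (logical mask), with intensities.
# An empty mask (absent substructure) encodes 0 for all size/shape/topology
# descriptors, while its intensity statistics read the channel background
# (frame median, sd 0): an absent compartment measures background, which
# avoids artificial cliffs in aggregated intensity features when a
# substructure disappears at high dose.
region_props <- function(mask, actin, nuclei, pixel_size, shell_width = 3,
                         bg = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  a_px <- nrow(idx)
  out <- stats::setNames(numeric(length(shape_descriptors) +
                                   length(intensity_descriptors)),
                         c(shape_descriptors, intensity_descriptors))
  if (a_px == 0) {
    if (is.null(bg)) bg <- c(actin = stats::median(actin),
                             nuclei = stats::median(nuclei))
    for (ch in c("actin", "nuclei")) for (rg in c("object", "shell"))
      out[paste0("int_", ch, "_", rg, "_",
                 c("mean", "median", "q10", "q25", "q75", "q90"))] <-
        bg[[ch]]
    return(out)
  }
  ys <- idx[, 1]; xs <- idx[, 2]
  cy <- mean(ys); cx <- mean(xs)

  out["area_px"] <- a_px
  out["area_um2"] <- a_px * pixel_size^2
  out["equiv_diameter_px"] <- 2 * sqrt(a_px / pi)
  out["equiv_diameter_um"] <- out["equiv_diameter_px"] * pixel_size

  per <- contour_perimeter(mask)
  out["perimeter_px"] <- per
  out["perimeter_um"] <- per * pixel_size

  rad <- sqrt((ys - cy)^2 + (xs - cx)^2)
  out["radius_mean_px"] <- mean(rad)
  out["radius_sd_px"] <- if (a_px > 1) stats::sd(rad) else 0

  if (a_px > 2) {
    cv <- stats::cov(cbind(xs, ys))
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    out["major_axis_px"] <- 4 * sqrt(ev[1])
    out["minor_axis_px"] <- 4 * sqrt(ev[2])
    out["aspect_ratio"] <- if (ev[2] > 0) sqrt(ev[1] / ev[2]) else 1
    out["eccentricity"] <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  } else {
    out["major_axis_px"] <- out["minor_axis_px"] <- 2 * sqrt(a_px / pi)
    out["aspect_ratio"] <- 1
  }

  out["solidity"] <- min(1, a_px / hull_area_px(ys, xs))
  bb <- (diff(range(ys)) + 1) * (diff(range(xs)) + 1)
  out["extent"] <- a_px / bb
  out["form_factor"] <- if (per > 0) min(1, 4 * pi * a_px / per^2) else 1

  # skeleton branch points on the object's bounding-box crop
  yr <- range(ys); xr <- range(xs)
  crop <- matrix(FALSE, yr[2] - yr[1] + 1, xr[2] - xr[1] + 1)
  crop[cbind(ys - yr[1] + 1, xs - xr[1] + 1)] <- TRUE
  out["branch_points"] <- count_branch_points(crop)

  # intensity statistics: whole object vs boundary shell
  shell <- shell_mask(mask, shell_width)
  stats8 <- function(v) {
    if (!length(v)) return(rep(0, 8))
    q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    c(mean(v), if (length(v) > 1) stats::sd(v) else 0, q[3],
      stats::mad(v), q[1], q[2], q[4], q[5])
  }
  st_names <- c("mean", "sd", "median", "mad", "q10", "q25", "q75", "q90")
  for (ch in c("actin", "nuclei")) {
    img <- if (ch == "actin") actin else nuclei
    for (rg in c("object", "shell")) {
      sel <- if (rg == "object") mask else shell
      v <- img[sel]
      out[paste0("int_", ch, "_", rg, "_", st_names)] <- stats8(v)
    }
  }
  out
}

# boundary band of width w (object pixels within w of the background)
shell_mask <- function(mask, w = 3) {
  er <- as.matrix(EBImage::erode(EBImage::Image(mask * 1),
                                 EBImage::makeBrush(2 * w + 1, "disc"))) > 0
  mask & !er
}

# polygon length of the object's oriented contour (8-connected chain)
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(0)
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(0)
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    sum(d)
  }, numeric(1)))
}

#' Extract per-organoid morphometric features
#'
#' Computes, for every organoid in the filtered masks, the full registry of
#' size, shape, topology, relational and intensity features for the organoid
#' mask, its pooled lumen mask and its pooled nucleus mask.
#'
#' @param masks A `label_masks` (after [filter_objects()]).
#' @param proj The `channel_projection` of the same well (defaults to
#'   `masks$projection`).
#' @param pixel_size Lateral pixel size in micrometres (default 1.7).
#' @param well_id Well identifier attached to each record.
#' @return A data.frame with one row per organoid: `well_id`, `organoid_id`
#'   and one column per per-organoid registry feature.
#' @export
extract_organoid_features <- function(masks, proj = NULL, pixel_size = 1.7,
                                      well_id = "W001") {
  stopifnot(inherits(masks, "label_masks"))
  if (is.null(proj)) proj <- masks$projection
  if (is.null(proj)) stop("projection required")
  reg <- feature_registry()
  olab <- masks$organoid_labels
  ids <- sort(unique(olab[olab > 0]))
  if (!length(ids)) {
    empty <- as.data.frame(matrix(numeric(0), 0, length(reg$per_organoid)))
    names(empty) <- reg$per_organoid
    return(cbind(data.frame(well_id = character(0),
                            organoid_id = integer(0)), empty))
  }
  bg <- c(actin = stats::median(proj$actin_2d),
          nuclei = stats::median(proj$nuclei_2d))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    oid <- ids[i]
    omask <- olab == oid
    feats <- c(organoid = region_props(omask, proj$actin_2d, proj$nuclei_2d,
                                       pixel_size, bg = bg))
    names(feats) <- paste0("organoid_",
                           c(shape_descriptors, intensity_descriptors))

    lum_ids <- as.integer(names(masks$parent_of_lumen)[
      masks$parent_of_lumen == oid])
    lmask <- masks$lumen_labels %in% lum_ids &
      masks$lumen_labels > 0
    dim(lmask) <- dim(olab)
    lfe <- region_props(lmask, proj$actin_2d, proj$nuclei_2d, pixel_size,
                        bg = bg)
    names(lfe) <- paste0("lumen_", names(lfe))

    nuc_ids <- as.integer(names(masks$parent_of_nucleus)[
      masks$parent_of_nucleus == oid])
    nmask <- masks$nucleus_labels %in% nuc_ids &
      masks$nucleus_labels > 0
    dim(nmask) <- dim(olab)
    nfe <- region_props(nmask, proj$actin_2d, proj$nuclei_2d, pixel_size,
                        bg = bg)
    names(nfe) <- paste0("nucleus_", names(nfe))

    # relational features (ratio sentinel: 0 with a presence flag)
    oarea <- feats[["organoid_area_px"]]
    lum_area <- lfe[["lumen_area_px"]]
    rel <- c(lumen_count = length(lum_ids),
             nucleus_count = length(nuc_ids),
             lumen_area_total_px = lum_area,
             lumen_area_total_um2 = lum_area * pixel_size^2,
             lumen_area_ratio = if (oarea > 0) lum_area / oarea else 0,
             has_lumen = as.numeric(length(lum_ids) > 0),
             nuclei_per_area = if (oarea > 0) length(nuc_ids) / oarea else 0,
             lumen_centroid_offset_px = 0,
             lumen_centroid_offset_um = 0)
    if (any(lmask) && any(omask)) {
      oc <- which(omask, arr.ind = TRUE); lc <- which(lmask, arr.ind = TRUE)
      off <- sqrt(sum((colMeans(oc) - colMeans(lc))^2))
      rel["lumen_centroid_offset_px"] <- off
      rel["lumen_centroid_offset_um"] <- off * pixel_size
    }
    names(rel) <- paste0("organoid_", relational_descriptors)
    rows[[i]] <- c(feats, lfe, nfe, rel)[reg$per_organoid]
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- reg$per_organoid
  cbind(data.frame(well_id = well_id, organoid_id = ids), df)
}

#' Aggregate per-organoid records into a per-well profile
#'
#' Emits, for each per-organoid feature, its mean, median, standard deviation
#' (0 for a single organoid) and sum across the organoids of the well, plus
#' the organoid, lumen and nucleus counts, and attaches the layout metadata.
#' A well with zero organoids is returned flagged degenerate (`n_organoids =
#' 0`, all features `NA`) and should be excluded downstream.
#'
#' @param records Data.frame from [extract_organoid_features()].
#' @param layout_row One-row data.frame (or list) with `well`, `compound`,
#'   `dose_nM`, `role`.
#' @return One-row data.frame: metadata columns `well`, `compound`,
#'   `dose_nM`, `role`, `n_organoids`, then the aggregated feature columns
#'   in registry order.
#' @export
aggregate_well <- function(records, layout_row) {
  reg <- feature_registry()
  meta <- data.frame(well = layout_row$well, compound = layout_row$compound,
                     dose_nM = layout_row$dose_nM, role = layout_row$role)
  n <- nrow(records)
  if (n == 0) {
    warning("well ", layout_row$well, " has no organoids; profile degenerate")
    vals <- as.data.frame(as.list(stats::setNames(
      rep(NA_real_, length(reg$well_columns)), reg$well_columns)),
      check.names = FALSE)
    vals$n_organoids <- 0
    return(cbind(meta, n_organoids = 0,
                 vals[setdiff(names(vals), "n_organoids")]))
  }
  X <- as.matrix(records[, reg$per_organoid, drop = FALSE])
  agg <- c(
    stats::setNames(colMeans(X), paste0(colnames(X), "__mean")),
    stats::setNames(apply(X, 2, stats::median),
                    paste0(colnames(X), "__median")),
    stats::setNames(if (n > 1) apply(X, 2, stats::sd) else rep(0, ncol(X)),
                    paste0(colnames(X), "__sd")),
    stats::setNames(colSums(X), paste0(colnames(X), "__sum")),
    n_organoids = n,
    n_lumens_total = sum(records$organoid_lumen_count),
    n_nuclei_total = sum(records$organoid_nucleus_count))
  agg <- agg[reg$well_columns]
  cbind(meta, n_organoids = n,
        as.data.frame(as.list(agg[setdiff(names(agg), "n_organoids")]),
                      check.names = FALSE))
}

#' Names of the feature columns of a profile table
#'
#' @param profiles A profile data.frame (rows = wells).
#' @return Character vector of feature column names (everything except the
#'   metadata columns).
#' @export
profile_feature_columns <- function(profiles) {
  setdiff(names(profiles), c("well", "compound", "dose_nM", "role",
                             "replicate", "theta", "seed", "n_organoids"))
}
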