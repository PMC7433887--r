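#' Maximum-intensity projection of a two-channel stack
#'
#' Collapses each channel to a 2D frame by taking the per-pixel maximum over
#' z, and records the arg-max plane of the actin channel as a focus map used
#' later by the out-of-focus filter.
#'
#' @param stack An `image_stack`.
#' @return A list of class `channel_projection` with `nuclei_2d`, `actin_2d`
#'   and `focus_map` (1-based plane index of the actin maximum).
#' @export
project_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(dim(stack$nuclei), dim(stack$actin)))
    stop("channel shapes differ")
  nz <- dim(stack$actin)[3]
  if (nz < 1) stop("empty stack")
  actin_2d <- stack$actin[, , 1]
  nuclei_2d <- stack$nuclei[, , 1]
  focus_map <- array(1L, dim = dim(actin_2d))
  if (nz > 1) for (z in 2:nz) {
    pl <- stack$actin[, , z]
    upd <- pl > actin_2d
    focus_map[upd] <- z
    actin_2d[upd] <- pl[upd]
    nuclei_2d <- pmax(nuclei_2d, stack$nuclei[, , z])
  }
  structure(list(nuclei_2d = nuclei_2d, actin_2d = actin_2d,
                 focus_map = focus_map),
            class = "channel_projection")
}

#' Segment organoids from a two-channel projection
#'
#' Foreground is detected by Otsu thresholding of a blurred weighted sum of
#' the two channels, hole-filled, and cleaned of small objects. Touching
#' organoids are split by seeded region growing: seeds are local maxima of
#' the heavily smoothed nuclei-channel density, and any connected component
#' holding two or more seeds is partitioned with [EBImage::propagate()].
#' Labels are consecutive positive integers in deterministic (row-major)
#' order; background is 0.
#'
#' @param proj A `channel_projection`.
#' @param min_area Minimum organoid area in pixels (default 250, i.e. a
#'   27 um-diameter object at 1.7 um/px — below the smallest organoid of
#'   interest, so drug-shrunken organoids are not censored).
#' @param weights Channel weights `c(actin, nuclei)` for the combined image.
#' @param blur_sigma Gaussian blur applied before thresholding, in pixels.
#' @param seed_sigma Gaussian blur of the nuclei channel used for the seed
#'   density map, in pixels; about the organoid radius (default 20).
#' @param min_seed_dist Minimum seed separation in pixels; closer seeds are
#'   merged. Roughly one organoid diameter at the working magnification
#'   (default 36).
#' @return Integer label matrix.
#' @export
segment_organoids <- function(proj, min_area = 250, weights = c(0.7, 0.3),
                              blur_sigma = 2, seed_sigma = 20,
                              min_seed_dist = 36) {
  stopifnot(inherits(proj, "channel_projection"))
  norm01 <- function(m) {
    rg <- range(m)
    if (diff(rg) == 0) return(m * 0)
    (m - rg[1]) / diff(rg)
  }
  combined <- weights[1] * norm01(proj$actin_2d) +
    weights[2] * norm01(proj$nuclei_2d)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(combined),
                                 sigma = blur_sigma))
  sm <- norm01(sm)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  # Otsu splits even a unimodal noise histogram; require the threshold to
  # clear the background by a robust margin so blank frames stay empty
  th <- max(th, stats::median(sm) + 6 * stats::mad(sm))
  fg <- sm > th
  if (!any(fg)) return(array(0L, dim = dim(sm)))
  fg <- as.matrix(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(fg)))
  # drop small objects
  tab <- tabulate(lab[lab > 0])
  small <- which(tab < min_area)
  if (length(small)) {
    lab[lab %in% small] <- 0
    fg <- lab > 0
  }
  if (!any(fg)) return(array(0L, dim = dim(sm)))

  # watershed-style split of touching organoids, seeded from smoothed
  # nuclei density maxima
  dens <- as.matrix(EBImage::gblur(EBImage::Image(proj$nuclei_2d),
                                   sigma = seed_sigma))
  seeds <- find_seeds(dens, fg, min_seed_dist)
  if (nrow(seeds) >= 2) {
    seed_img <- array(0L, dim = dim(sm))
    for (k in seq_len(nrow(seeds)))
      seed_img[round(seeds[k, 1]), round(seeds[k, 2])] <- k
    comp_of_seed <- lab[cbind(round(seeds[, 1]), round(seeds[, 2]))]
    multi <- names(which(table(comp_of_seed[comp_of_seed > 0]) >= 2))
    if (length(multi)) {
      prop <- EBImage::propagate(EBImage::Image(sm),
                                 seeds = EBImage::Image(seed_img),
                                 mask = EBImage::Image(fg * 1))
      prop <- as.matrix(prop)
      mx <- max(lab)
      for (cid in as.integer(multi)) {
        sel <- lab == cid
        lab[sel] <- prop[sel] + mx
      }
    }
  }
  relabel_consecutive(lab)$labels
}

#' Segment lumens inside organoids
#'
#' Within each organoid, pixels whose actin intensity falls below a fraction
#' of that organoid's median actin intensity are lumen candidates. Candidate
#' components touching the organoid boundary or smaller than `min_area` are
#' discarded; each retained lumen is assigned its enclosing organoid.
#'
#' @param organoid_labels Integer label matrix from [segment_organoids()].
#' @param proj A `channel_projection`.
#' @param frac Threshold as a fraction of the per-organoid median actin
#'   intensity (default 0.4).
#' @param min_area Minimum lumen area in pixels (default 25).
#' @return A list with `labels` (lumen label matrix) and `parent` (named
#'   integer vector, lumen id -> organoid id).
#' @export
segment_lumens <- function(organoid_labels, proj, frac = 0.4, min_area = 25) {
  out <- array(0L, dim = dim(organoid_labels))
  parent <- integer(0)
  ids <- sort(unique(organoid_labels[organoid_labels > 0]))
  if (!length(ids)) return(list(labels = out, parent = parent))
  next_id <- 0L
  h <- nrow(organoid_labels); w <- ncol(organoid_labels)
  for (oid in ids) {
    obj <- organoid_labels == oid
    med <- stats::median(proj$actin_2d[obj])
    cand <- obj & proj$actin_2d < frac * med
    if (!any(cand)) next
    clab <- as.matrix(EBImage::bwlabel(EBImage::Image(cand)))
    # boundary of the organoid: organoid pixels 8-adjacent to non-organoid
    pad <- matrix(FALSE, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- !obj
    touches_out <- matrix(FALSE, h, w)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      touches_out <- touches_out |
        pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    }
    border_ids <- unique(clab[clab > 0 & touches_out])
    areas <- tabulate(clab[clab > 0])
    for (ci in seq_along(areas)) {
      if (areas[ci] < min_area || ci %in% border_ids) next
      next_id <- next_id + 1L
      out[clab == ci] <- next_id
      parent[as.character(next_id)] <- oid
    }
  }
  list(labels = out, parent = parent)
}

#' Segment nuclei and assign them to organoids
#'
#' The nuclei projection is lightly smoothed and thresholded against the
#' image background (median + `k` robust SDs); touching nuclei are split by
#' watershed on the distance transform. Nuclei whose centroid falls outside
#' every organoid are discarded.
#'
#' @param proj A `channel_projection`.
#' @param organoid_labels Label matrix from [segment_organoids()].
#' @param blur_sigma Smoothing sigma in pixels (default 1).
#' @param k Robust threshold multiplier (default 8).
#' @param amp_frac Fraction of the bright-tail amplitude (99.9th percentile
#'   above background) that the threshold must also clear (default 0.3);
#'   prevents neighbouring nuclei from merging at a purely robust threshold.
#' @param min_area Minimum nucleus area in pixels (default 4).
#' @return A list with `labels` (nucleus label matrix) and `parent` (named
#'   integer vector, nucleus id -> organoid id).
#' @export
segment_nuclei <- function(proj, organoid_labels, blur_sigma = 1,
                           k = 8, amp_frac = 0.3, min_area = 4) {
  sm <- as.matrix(EBImage::gblur(EBImage::Image(proj$nuclei_2d),
                                 sigma = blur_sigma))
  bg <- stats::median(sm)
  spread <- stats::mad(sm)
  if (spread == 0) spread <- max(stats::sd(sm), 1e-6)
  # adaptive threshold: robust floor, raised towards the blob amplitude
  # (upper intensity tail) so neighbouring nuclei do not merge
  amp <- stats::quantile(sm, 0.999, names = FALSE) - bg
  thr <- bg + max(k * spread, amp_frac * amp)
  mask <- sm > thr
  out <- array(0L, dim = dim(sm))
  if (!any(mask)) return(list(labels = out, parent = integer(0)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- as.matrix(EBImage::watershed(dm, tolerance = 0.5))
  areas <- tabulate(ws[ws > 0])
  keep <- which(areas >= min_area)
  parent <- integer(0)
  next_id <- 0L
  for (ni in keep) {
    idx <- which(ws == ni, arr.ind = TRUE)
    cy <- round(mean(idx[, 1])); cx <- round(mean(idx[, 2]))
    oid <- organoid_labels[cy, cx]
    if (oid == 0) next
    next_id <- next_id + 1L
    out[ws == ni] <- next_id
    parent[as.character(next_id)] <- oid
  }
  list(labels = out, parent = parent)
}

#' Remove out-of-focus and border-touching organoids
#'
#' Each organoid gets a focus score: the variance of the
#' Laplacian-of-Gaussian of its modal focus plane over the object's pixels,
#' normalised by the squared mean intensity. Organoids scoring more than
#' `focus_mad` robust SDs below the median log-score, and organoids touching
#' the frame border, are removed with their lumens and nuclei. The removal is
#' iterated to a fixed point so the operation is idempotent.
#'
#' @param masks A `label_masks` object (see [segment_well()]).
#' @param stack The originating `image_stack`.
#' @param focus_mad Robust-deviation multiplier (default 3).
#' @param min_keep Objects are never filtered by focus when fewer than this
#'   many organoids are present (default 3; the robust statistics are
#'   meaningless for tiny samples).
#' @return Filtered `label_masks`.
#' @export
filter_objects <- function(masks, stack, focus_mad = 3, min_keep = 3) {
  stopifnot(inherits(masks, "label_masks"))
  lab <- masks$organoid_labels
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(masks)
  h <- nrow(lab); w <- ncol(lab)

  # border rule
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  drop <- intersect(ids, border[border > 0])
  keep <- setdiff(ids, drop)

  # focus scores at each object's modal focus plane; Laplacian planes are
  # computed once per distinct plane
  zmode <- vapply(keep, function(oid)
    mode_int(masks$focus_map[lab == oid]), numeric(1))
  # Laplacian of Gaussian: smoothing first suppresses the shot-noise floor
  # so the score reflects structural sharpness, not photon noise
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  laps <- lapply(unique(zmode), function(z) {
    pl <- EBImage::gblur(EBImage::Image(stack$actin[, , z]), sigma = 1.5)
    as.matrix(EBImage::filter2(pl, kern))
  })
  names(laps) <- unique(zmode)
  score <- vapply(seq_along(keep), function(i) {
    sel <- lab == keep[i]
    plane <- stack$actin[, , zmode[i]]
    mu <- mean(plane[sel])
    if (mu <= 0) return(0)
    stats::var(laps[[as.character(zmode[i])]][sel]) / mu^2
  }, numeric(1))
  names(score) <- keep

  if (length(keep) >= min_keep) {
    # focus scores are ratio-scale, so the robust cut is multiplicative:
    # remove organoids more than focus_mad robust SDs below the median on
    # the log scale, iterating to a fixed point (idempotent)
    lsc <- log10(score + 1e-12)
    repeat {
      med <- stats::median(lsc)
      dev <- stats::mad(lsc)
      # floor: with a handful of organoids the MAD is unstable, so removal
      # additionally requires the score to sit at least ~5x below median
      thr <- med - max(focus_mad * dev, 0.7)
      bad <- names(lsc)[lsc < thr]
      if (!length(bad) || length(lsc) - length(bad) < 1) break
      lsc <- lsc[!names(lsc) %in% bad]
    }
    keep <- as.integer(names(lsc))
  }

  subset_masks(masks, keep)
}

# keep only the given organoid ids and relabel everything consecutively
subset_masks <- function(masks, keep_ids) {
  lab <- masks$organoid_labels
  lab[!(lab %in% keep_ids)] <- 0L
  rl <- relabel_consecutive(lab)
  omap <- rl$map   # old id -> new id

  remap_child <- function(clab, parent) {
    keep_child <- names(parent)[parent %in% keep_ids]
    clab[!(clab %in% as.integer(keep_child))] <- 0L
    crl <- relabel_consecutive(clab)
    new_parent <- integer(0)
    for (old in names(crl$map)) {
      new_parent[as.character(crl$map[[old]])] <-
        as.integer(omap[[as.character(parent[[old]])]])
    }
    list(labels = crl$labels, parent = new_parent)
  }
  lum <- remap_child(masks$lumen_labels, masks$parent_of_lumen)
  nuc <- remap_child(masks$nucleus_labels, masks$parent_of_nucleus)
  structure(list(organoid_labels = rl$labels,
                 lumen_labels = lum$labels, parent_of_lumen = lum$parent,
                 nucleus_labels = nuc$labels, parent_of_nucleus = nuc$parent,
                 focus_map = masks$focus_map),
            class = "label_masks")
}

#' Full segmentation of one well
#'
#' Projects the stack, segments organoids, lumens and nuclei, and applies the
#' out-of-focus / border filter.
#'
#' @param stack An `image_stack`.
#' @param min_area Minimum organoid area in pixels (default 250).
#' @param lumen_frac,lumen_min_area Lumen threshold fraction and minimum area
#'   (defaults 0.4 and 25; see [segment_lumens()]).
#' @param focus_mad Out-of-focus threshold in robust SDs (default 3).
#' @param filter Apply [filter_objects()] (default `TRUE`).
#' @return A list of class `label_masks` with the three label matrices, the
#'   two parent maps, the focus map and the projection (`$projection`).
#' @export
segment_well <- function(stack, min_area = 250, lumen_frac = 0.4,
                         lumen_min_area = 25, focus_mad = 3, filter = TRUE) {
  proj <- project_stack(stack)
  olab <- segment_organoids(proj, min_area = min_area)
  lum <- segment_lumens(olab, proj, frac = lumen_frac,
                        min_area = lumen_min_area)
  nuc <- segment_nuclei(proj, olab)
  masks <- structure(list(organoid_labels = olab,
                          lumen_labels = lum$labels,
                          parent_of_lumen = lum$parent,
                          nucleus_labels = nuc$labels,
                          parent_of_nucleus = nuc$parent,
                          focus_map = proj$focus_map),
                     class = "label_masks")
  if (filter) masks <- filter_objects(masks, stack, focus_mad = focus_mad)
  masks$projection <- proj
  masks
}

#' Write label masks as 16-bit TIFFs plus a parent-map CSV
#'
#' @param masks A `label_masks`.
#' @param dir Output directory.
#' @param well_id Well identifier used in file names.
#' @return Invisibly, the parent-map data.frame.
#' @export
write_masks <- function(masks, dir, well_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in c("organoid", "lumen", "nucleus")) {
    lab <- masks[[paste0(cls, "_labels")]]
    tiff::writeTIFF(lab / 65535,
                    file.path(dir, sprintf("%s_%s.tif", well_id, cls)),
                    bits.per.sample = 16, compression = "none")
  }
  pm <- rbind(
    data.frame(well = well_id, child_type = "lumen",
               child_id = as.integer(names(masks$parent_of_lumen)),
               organoid_id = unname(masks$parent_of_lumen)),
    data.frame(well = well_id, child_type = "nucleus",
               child_id = as.integer(names(masks$parent_of_nucleus)),
               organoid_id = unname(masks$parent_of_nucleus)))
  utils::write.csv(pm, file.path(dir, sprintf("%s_parents.csv", well_id)),
                   row.names = FALSE)
  invisible(pm)
}
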