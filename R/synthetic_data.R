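#' Dose series for a dilution-plate design
#'
#' Returns the descending concentration series defined by a [plate_design()]:
#' `n_doses` points starting at `top_dose`, each the previous divided by
#' `dilution_factor`. The default design yields the 9-point 2-fold series
#' 50, 25, ..., 0.195 nM.
#'
#' @param design A [plate_design()] object.
#' @return Numeric vector of doses in nM, descending.
#' @examples
#' dose_series(plate_design(top_dose = 100, n_doses = 3, dilution_factor = 10))
#' @export
dose_series <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  design$top_dose / design$dilution_factor^(seq_len(design$n_doses) - 1)
}

#' Hill dose-to-phenotype map
#'
#' Maps a dose to the phenotype severity `theta` via the Hill equation
#' `theta = max_effect * d^n / (d^n + ec50^n)`, giving the synthetic screen a
#' monotone dose-response with a known EC50 so that curve-fit recovery is
#' well-posed.
#'
#' @param dose Dose in nM (scalar or vector), must be non-negative.
#' @param compound A [compound_model()].
#' @return Phenotype severity in \[0, max_effect\].
#' @examples
#' hill_phenotype(2, compound_model("C1", ec50 = 2))  # 0.5
#' @export
hill_phenotype <- function(dose, compound) {
  stopifnot(inherits(compound, "compound_model"))
  if (any(dose < 0)) stop("dose must be non-negative")
  dn <- dose^compound$hill
  out <- compound$max_effect * dn / (dn + compound$ec50^compound$hill)
  out[dose == 0] <- 0
  out
}

# deterministic per-well seed derived from the master seed (Lehmer-style mix,
# kept below 2^31 so it is a valid R integer seed)
well_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(index) * 104729) %% m)
}

# effective phenotype parameters at severity theta: radius shrinks up to
# 40%, lumens collapse up to 50% of their fraction (so an average organoid's
# lumen shrinks about 4-fold in area but stays detectable at full severity:
# every phenotype axis responds gradedly across the dose range rather than
# switching off at a detection threshold), nucleus counts drop up to 50%,
# debris increases
theta_effects <- function(pheno) {
  th <- pheno$theta
  list(radius_mean = pheno$organoid_radius_mean * (1 - 0.4 * th),
       lumen_fraction = pheno$lumen_fraction * (1 - 0.5 * th),
       nuclei_mean = pheno$nuclei_per_organoid_mean * (1 - 0.5 * th),
       debris = min(1, pheno$debris_fraction + 0.5 * th))
}

#' Generate one synthetic two-channel organoid z-stack
#'
#' Renders `n_organoids` spherical organoids into a two-channel z-stack:
#' the F-actin channel is bright on the epithelial shell and dim inside the
#' lumen; the nuclei channel holds small Gaussian blobs placed on the shell.
#' The phenotype severity `theta` shrinks the mean radius, collapses lumens,
#' reduces nucleus counts and adds dead-cell debris blobs. Poisson shot noise
#' and Gaussian background/read noise are applied per voxel. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param pheno A [phenotype_params()].
#' @param acq An [acquisition_params()].
#' @param seed Integer seed; the same seed always yields the identical stack.
#' @param well_id Well identifier stored with the stack.
#' @param nuclei_placement `"shell"` (random positions on the spherical shell,
#'   default) or `"ring"` (equally spaced on the equatorial circle, guaranteeing
#'   non-touching nuclei in projection).
#' @return A list with `stack` (class `image_stack`: `nuclei` and `actin`
#'   arrays of dimension `c(height, width, n_z_planes)`, plus `acquisition`
#'   and `well_id`) and `truth` (ground-truth data.frame with one row per
#'   organoid: `well, organoid_id, x, y, z, radius_um, lumen_radius_um,
#'   n_nuclei, in_focus, theta`).
#' @export
generate_well_stack <- function(pheno, acq, seed, well_id = "W001",
                                nuclei_placement = c("shell", "ring")) {
  stopifnot(inherits(pheno, "phenotype_params"),
            inherits(acq, "acquisition_params"))
  nuclei_placement <- match.arg(nuclei_placement)
  set.seed(as.integer(seed))

  h <- acq$frame_shape[1]; w <- acq$frame_shape[2]; nz <- acq$n_z_planes
  px <- acq$pixel_size
  depth_um <- nz * acq$z_step
  eff <- theta_effects(pheno)

  actin <- array(0, dim = c(h, w, nz))
  nuc <- array(0, dim = c(h, w, nz))

  n <- pheno$n_organoids
  truth <- data.frame(well = character(0), organoid_id = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      radius_um = numeric(0), lumen_radius_um = numeric(0),
                      n_nuclei = integer(0), in_focus = logical(0),
                      theta = numeric(0))

  if (n > 0) {
    radii_um <- pmax(eff$radius_mean * 0.3,
                     stats::rnorm(n, eff$radius_mean, pheno$organoid_radius_sd))
    radii_px <- radii_um / px
    margin <- 4
    if (max(radii_px) + margin >= min(h, w) / 2)
      stop("frame too small to hold an organoid of the requested radius")

    # rejection-sample non-overlapping centres away from the frame border,
    # restarting the whole layout when a dead end is reached
    cx <- numeric(n); cy <- numeric(n)
    layout_ok <- FALSE
    for (restart in 1:50) {
      ok <- TRUE
      for (i in seq_len(n)) {
        placed <- FALSE
        for (attempt in 1:500) {
          x0 <- stats::runif(1, radii_px[i] + margin,
                             w - radii_px[i] - margin)
          y0 <- stats::runif(1, radii_px[i] + margin,
                             h - radii_px[i] - margin)
          if (i == 1 || all(sqrt((cx[seq_len(i - 1)] - x0)^2 +
                                 (cy[seq_len(i - 1)] - y0)^2) >
                            radii_px[seq_len(i - 1)] + radii_px[i] + 6)) {
            cx[i] <- x0; cy[i] <- y0; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { layout_ok <- TRUE; break }
    }
    if (!layout_ok) stop("could not place organoids without overlap; ",
                         "reduce n_organoids or enlarge the frame")

    n_oof <- round(pheno$oof_fraction * n)
    in_focus <- rep(TRUE, n)
    if (n_oof > 0) in_focus[sample.int(n, n_oof)] <- FALSE

    lumen_r_um <- radii_um * eff$lumen_fraction
    # "ring" placement is a calibration fixture: deterministic counts,
    # guaranteed non-touching in projection
    n_nuc <- if (nuclei_placement == "ring") rep(round(eff$nuclei_mean), n)
    else stats::rpois(n, eff$nuclei_mean)
    cz_um <- vapply(radii_um, function(r) {
      lo <- min(r + acq$z_step, depth_um / 2)
      stats::runif(1, lo, depth_um - lo)
    }, numeric(1))

    A_ACTIN <- 800; A_LUMEN <- 0.12 * A_ACTIN; A_NUC <- 1000
    nuc_sigma_um <- 3.5

    for (i in seq_len(n)) {
      r_um <- radii_um[i]; lr_um <- lumen_r_um[i]
      rpxi <- radii_px[i]
      xs <- max(1, floor(cx[i] - rpxi - 1)):min(w, ceiling(cx[i] + rpxi + 1))
      ys <- max(1, floor(cy[i] - rpxi - 1)):min(h, ceiling(cy[i] + rpxi + 1))

      if (in_focus[i]) {
        # per plane z the organoid cross-section is an annulus of outer
        # radius r_z with a lateral lumen hole of radius lr, so the lumen
        # stays actin-poor in the maximum-intensity projection (as lumens
        # appear in projected confocal stacks of epithelial organoids)
        zlo <- max(1, floor((cz_um[i] - r_um) / acq$z_step))
        zhi <- min(nz, ceiling((cz_um[i] + r_um) / acq$z_step) + 1)
        zs <- zlo:zhi
        dy2 <- ((ys - cy[i]) * px)^2
        dx2 <- ((xs - cx[i]) * px)^2
        rho <- sqrt(outer(dy2, dx2, "+"))
        for (z in zs) {
          dz2 <- ((z - 0.5) * acq$z_step - cz_um[i])^2
          if (dz2 >= r_um^2) next
          r_z <- sqrt(r_um^2 - dz2)
          shell <- rho <= r_z & rho > lr_um
          lum <- rho <= pmin(lr_um, r_z)
          plane <- actin[ys, xs, z]
          plane[shell] <- plane[shell] + A_ACTIN
          plane[lum] <- plane[lum] + A_LUMEN
          actin[ys, xs, z] <- plane
        }
      } else {
        # out-of-focus organoid: smooth featureless disc (wide logistic
        # edge stands in for defocus blur) confined to an outer plane
        z <- if (stats::runif(1) < 0.5) 1L else nz
        dy2 <- ((ys - cy[i]) * px)^2
        dx2 <- ((xs - cx[i]) * px)^2
        d <- sqrt(outer(dy2, dx2, "+"))
        disc <- A_ACTIN * 0.8 * stats::plogis((r_um - d) / (0.35 * r_um))
        actin[ys, xs, z] <- actin[ys, xs, z] + disc
      }

      # nuclei in the epithelial layer: lateral position inside the actin
      # annulus so each nucleus projects between lumen and organoid boundary
      if (n_nuc[i] > 0) {
        lo_um <- max(lr_um + 3, 0.35 * r_um)
        hi_um <- max(lo_um + 1, 0.92 * r_um)
        if (nuclei_placement == "ring" || !in_focus[i]) {
          ring_r <- (lo_um + hi_um) / 2
          ang <- 2 * pi * (seq_len(n_nuc[i]) - 1) / n_nuc[i] +
            stats::runif(1, 0, 2 * pi)
          nx_um <- cx[i] * px + ring_r * cos(ang)
          ny_um <- cy[i] * px + ring_r * sin(ang)
          nz_um <- rep(cz_um[i], n_nuc[i])
        } else {
          rho_n <- stats::runif(n_nuc[i], lo_um, hi_um)
          phi <- stats::runif(n_nuc[i], 0, 2 * pi)
          nx_um <- cx[i] * px + rho_n * cos(phi)
          ny_um <- cy[i] * px + rho_n * sin(phi)
          zmax <- sqrt(pmax(0, r_um^2 - rho_n^2))
          nz_um <- cz_um[i] + stats::runif(n_nuc[i], -0.7, 0.7) * zmax
        }
        if (!in_focus[i]) {
          zpl <- rep(if (cz_um[i] < depth_um / 2) 1L else nz, n_nuc[i])
        } else {
          zpl <- pmin(nz, pmax(1, round(nz_um / acq$z_step + 0.5)))
        }
        for (k in seq_len(n_nuc[i])) {
          nuc <- add_blob(nuc, nx_um[k] / px, ny_um[k] / px, zpl[k],
                          nuc_sigma_um / px, A_NUC,
                          blur = !in_focus[i])
        }
      }
    }

    truth <- data.frame(well = well_id, organoid_id = seq_len(n),
                        x = cx, y = cy, z = cz_um / acq$z_step,
                        radius_um = radii_um, lumen_radius_um = lumen_r_um,
                        n_nuclei = n_nuc, in_focus = in_focus,
                        theta = pheno$theta)
  }

  # dead-cell debris: small bright specks in both channels
  n_debris <- if (n > 0) round(eff$debris * n * 3) else 0
  if (n_debris > 0) {
    dx <- stats::runif(n_debris, 6, w - 6)
    dy <- stats::runif(n_debris, 6, h - 6)
    dz <- sample.int(nz, n_debris, replace = TRUE)
    for (k in seq_len(n_debris)) {
      actin <- add_blob(actin, dx[k], dy[k], dz[k], 2.5 / px, 600)
      nuc <- add_blob(nuc, dx[k], dy[k], dz[k], 2 / px, 500)
    }
  }

  # detector model: Poisson shot noise on signal (only where signal is
  # present), Gaussian background + read noise everywhere
  ps <- acq$photon_scaling
  apply_noise <- function(vol) {
    out <- acq$background_level +
      array(stats::rnorm(length(vol), 0, acq$noise_sd), dim = dim(vol))
    idx <- which(vol > 0)
    if (length(idx))
      out[idx] <- out[idx] + stats::rpois(length(idx), vol[idx] * ps) / ps
    array(pmin(65535, pmax(0, out)), dim = dim(vol))
  }
  actin <- apply_noise(actin)
  nuc <- apply_noise(nuc)

  stack <- structure(list(nuclei = nuc, actin = actin, acquisition = acq,
                          well_id = well_id),
                     class = "image_stack")
  list(stack = stack, truth = truth)
}

# add an isotropic Gaussian blob centred at (x, y) px in plane z
add_blob <- function(vol, x, y, z, sigma_px, amp, blur = FALSE) {
  h <- dim(vol)[1]; w <- dim(vol)[2]
  if (blur) sigma_px <- sigma_px * 2.5
  r <- ceiling(3 * sigma_px)
  xs <- max(1, floor(x - r)):min(w, ceiling(x + r))
  ys <- max(1, floor(y - r)):min(h, ceiling(y + r))
  if (!length(xs) || !length(ys)) return(vol)
  g <- outer((ys - y)^2, (xs - x)^2, "+")
  vol[ys, xs, z] <- vol[ys, xs, z] +
    amp * (if (blur) 0.4 else 1) * exp(-g / (2 * sigma_px^2))
  vol
}

#' Simulate a full screening plate
#'
#' Builds the plate layout from a [plate_design()] and a list of
#' [compound_model()]s (control wells at `theta = 0`, treated wells at the
#' severity given by [hill_phenotype()]), then renders one two-channel stack
#' per well with a per-well seed derived deterministically from `seed`.
#'
#' @param design A [plate_design()].
#' @param compounds List of [compound_model()] objects.
#' @param base_pheno A [phenotype_params()] describing the untreated (control)
#'   well; `theta` is overridden per well.
#' @param acq An [acquisition_params()].
#' @param seed Master integer seed.
#' @param out_dir If non-`NULL`, stacks are written as 16-bit multi-page TIFFs
#'   (`<well>_dapi.tif`, `<well>_actin.tif`) together with `layout.csv` and
#'   `ground_truth.csv`, and stacks are not kept in memory.
#' @param plate_capacity Maximum number of wells (default 384).
#' @return An object of class `organoid_screen`: a list with `layout`
#'   (data.frame `well, compound, dose_nM, role, replicate, theta, seed`),
#'   `truth` (row-bound ground truth), `stacks` (named list of `image_stack`,
#'   or `NULL` when written to disk) and `dir`.
#' @export
generate_screen <- function(design, compounds, base_pheno = phenotype_params(),
                            acq = acquisition_params(), seed = 1,
                            out_dir = NULL, plate_capacity = 384) {
  stopifnot(inherits(design, "plate_design"))
  if (inherits(compounds, "compound_model")) compounds <- list(compounds)
  stopifnot(all(vapply(compounds, inherits, logical(1), "compound_model")))

  layout <- screen_layout(design, compounds)
  if (nrow(layout) > plate_capacity)
    stop("plate capacity exceeded: ", nrow(layout), " wells > ",
         plate_capacity)

  layout$theta <- 0
  cmp_by_name <- stats::setNames(compounds,
                                 vapply(compounds, `[[`, "", "name"))
  trt <- layout$role == "treated"
  layout$theta[trt] <- mapply(function(cn, d)
    hill_phenotype(d, cmp_by_name[[cn]]),
    layout$compound[trt], layout$dose_nM[trt])
  layout$seed <- well_seed(seed, seq_len(nrow(layout)))

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stacks <- if (is.null(out_dir)) vector("list", nrow(layout)) else NULL
  truths <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    ph <- base_pheno
    ph$theta <- layout$theta[i]
    res <- generate_well_stack(ph, acq, layout$seed[i],
                               well_id = layout$well[i])
    truths[[i]] <- res$truth
    if (is.null(out_dir)) {
      stacks[[i]] <- res$stack
    } else {
      write_stack_tiff(res$stack, out_dir)
    }
  }
  truth <- do.call(rbind, truths)
  if (!is.null(out_dir)) {
    utils::write.csv(layout, file.path(out_dir, "layout.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    names(stacks) <- layout$well
  }
  structure(list(layout = layout, truth = truth, stacks = stacks,
                 dir = out_dir, acquisition = acq),
            class = "organoid_screen")
}

#' @export
print.organoid_screen <- function(x, ...) {
  cat(sprintf("organoid screen: %d wells (%d control), %d organoids\n",
              nrow(x$layout), sum(x$layout$role == "control"),
              nrow(x$truth)))
  invisible(x)
}

# plate layout table: control wells first, then compound x dose x replicate
screen_layout <- function(design, compounds) {
  doses <- dose_series(design)
  rows <- list()
  if (design$n_control_wells > 0)
    rows[[1]] <- data.frame(compound = design$control_label, dose_nM = 0,
                            role = "control",
                            replicate = seq_len(design$n_control_wells))
  for (cmp in compounds)
    for (d in doses)
      rows[[length(rows) + 1]] <- data.frame(compound = cmp$name, dose_nM = d,
                                             role = "treated",
                                             replicate =
                                               seq_len(design$n_replicates))
  layout <- do.call(rbind, rows)
  layout <- cbind(well = sprintf("W%03d", seq_len(nrow(layout))), layout)
  layout
}
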