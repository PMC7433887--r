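#' Acquisition parameters for a two-channel confocal z-stack
#'
#' Describes how a single well is imaged: number of z-planes, physical step
#' between planes, lateral pixel size, frame shape and the camera noise model.
#' Defaults mirror a 4x high-content confocal acquisition: 25 planes at
#' 10 micrometre steps.
#'
#' @param n_z_planes Number of z-planes per channel (default 25).
#' @param z_step Axial step between planes in micrometres (default 10).
#' @param pixel_size Lateral pixel size in micrometres per pixel (default 1.7,
#'   typical of a 4x objective on a high-content confocal).
#' @param frame_shape Integer vector `c(height, width)` in pixels; both
#'   dimensions must be at least 64 (default `c(256, 256)`).
#' @param background_level Additive background intensity in detector units
#'   (default 120).
#' @param noise_sd Standard deviation of the Gaussian read noise (default 8).
#' @param photon_scaling Photons per detector unit used by the Poisson shot
#'   noise model; larger values mean less relative shot noise (default 0.05).
#'
#' @return An object of class `acquisition_params`.
#' @examples
#' acq <- acquisition_params()
#' acq$n_z_planes
#' @export
acquisition_params <- function(n_z_planes = 25, z_step = 10, pixel_size = 1.7,
                               frame_shape = c(256L, 256L),
                               background_level = 120, noise_sd = 8,
                               photon_scaling = 0.05) {
  stopifnot(length(n_z_planes) == 1, length(z_step) == 1,
            length(pixel_size) == 1, length(frame_shape) == 2)
  if (n_z_planes < 1) stop("n_z_planes must be >= 1")
  if (z_step <= 0) stop("z_step must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (any(frame_shape < 64)) stop("frame_shape dimensions must be >= 64")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (photon_scaling <= 0) stop("photon_scaling must be positive")
  structure(list(n_z_planes = as.integer(n_z_planes), z_step = z_step,
                 pixel_size = pixel_size,
                 frame_shape = as.integer(frame_shape),
                 background_level = background_level, noise_sd = noise_sd,
                 photon_scaling = photon_scaling),
            class = "acquisition_params")
}

#' Pharmacological model of one compound
#'
#' A Hill (dose-occupancy) model used by the synthetic screen generator to map
#' dose to phenotype severity.
#'
#' @param name Compound name.
#' @param ec50 Half-maximal concentration in nM; must be positive.
#' @param hill Hill slope, must be positive (default 1).
#' @param max_effect Maximal phenotype severity reached at saturating dose,
#'   a fraction in \[0, 1\] (default 1).
#'
#' @return An object of class `compound_model`.
#' @examples
#' cmp <- compound_model("C1", ec50 = 2)
#' @export
compound_model <- function(name, ec50, hill = 1, max_effect = 1) {
  if (!is.character(name) || length(name) != 1) stop("name must be a string")
  if (ec50 <= 0) stop("ec50 must be positive")
  if (hill <= 0) stop("hill must be positive")
  if (max_effect < 0 || max_effect > 1) stop("max_effect must be in [0, 1]")
  structure(list(name = name, ec50 = ec50, hill = hill,
                 max_effect = max_effect),
            class = "compound_model")
}

#' Phenotype parameters for one synthetic well
#'
#' `theta` is the severity of the drug-induced phenotype in \[0, 1\]: it shrinks
#' the mean organoid radius (up to 40 percent), collapses lumens, reduces the
#' nucleus count (up to 50 percent) and adds dead-cell debris. `theta = 0` is
#' the vehicle-control morphology.
#'
#' @param theta Phenotype severity in \[0, 1\] (default 0).
#' @param n_organoids Number of organoids rendered in the well (default 8).
#' @param organoid_radius_mean Mean organoid radius in micrometres at
#'   `theta = 0` (default 40).
#' @param organoid_radius_sd Between-organoid SD of the radius in micrometres
#'   (default 6).
#' @param lumen_fraction Lumen radius as a fraction of the organoid radius at
#'   `theta = 0` (default 0.5).
#' @param nuclei_per_organoid_mean Mean nucleus count per organoid at
#'   `theta = 0` (default 12).
#' @param debris_fraction Baseline density of dead-cell debris blobs as a
#'   fraction in \[0, 1\] (default 0); `theta` adds to it.
#' @param oof_fraction Fraction of organoids rendered out of focus (blurred,
#'   confined to the outermost planes), giving the focus filter true positives
#'   (default 0).
#'
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(theta = 0, n_organoids = 8,
                             organoid_radius_mean = 40,
                             organoid_radius_sd = 6,
                             lumen_fraction = 0.5,
                             nuclei_per_organoid_mean = 12,
                             debris_fraction = 0,
                             oof_fraction = 0) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (n_organoids < 0) stop("n_organoids must be >= 0")
  if (organoid_radius_mean <= 0 || organoid_radius_sd < 0)
    stop("organoid radii must be positive")
  if (lumen_fraction < 0 || lumen_fraction >= 1)
    stop("lumen_fraction must be in [0, 1)")
  if (nuclei_per_organoid_mean < 0) stop("nuclei count must be >= 0")
  if (debris_fraction < 0 || debris_fraction > 1)
    stop("debris_fraction must be in [0, 1]")
  if (oof_fraction < 0 || oof_fraction > 1)
    stop("oof_fraction must be in [0, 1]")
  structure(list(theta = theta, n_organoids = as.integer(n_organoids),
                 organoid_radius_mean = organoid_radius_mean,
                 organoid_radius_sd = organoid_radius_sd,
                 lumen_fraction = lumen_fraction,
                 nuclei_per_organoid_mean = nuclei_per_organoid_mean,
                 debris_fraction = debris_fraction,
                 oof_fraction = oof_fraction),
            class = "phenotype_params")
}

#' Plate design for a dose-response screen
#'
#' Defaults describe the screening layout used throughout: a 9-point 2-fold
#' dilution series, 8 replicate wells per condition and DMSO vehicle controls.
#'
#' @param n_doses Number of dose points (default 9, must be >= 2 unless a
#'   single-dose series is explicitly requested via [dose_series()]).
#' @param dilution_factor Fold-dilution between consecutive doses (default 2,
#'   must be > 1).
#' @param top_dose Highest dose in nM (default 50).
#' @param n_replicates Replicate wells per (compound, dose) (default 8).
#' @param n_control_wells Number of vehicle-control wells (default 8).
#' @param control_label Label of the control condition (default `"DMSO"`).
#'
#' @return An object of class `plate_design`.
#' @examples
#' dose_series(plate_design())
#' @export
plate_design <- function(n_doses = 9, dilution_factor = 2, top_dose = 50,
                         n_replicates = 8, n_control_wells = 8,
                         control_label = "DMSO") {
  if (n_doses < 1) stop("n_doses must be >= 1")
  if (n_doses > 1 && dilution_factor <= 1)
    stop("dilution_factor must be > 1")
  if (top_dose <= 0) stop("top_dose must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (n_control_wells < 0) stop("n_control_wells must be >= 0")
  structure(list(n_doses = as.integer(n_doses),
                 dilution_factor = dilution_factor, top_dose = top_dose,
                 n_replicates = as.integer(n_replicates),
                 n_control_wells = as.integer(n_control_wells),
                 control_label = control_label),
            class = "plate_design")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("acquisition: %d z-planes x %g um, %dx%d px @ %g um/px\n",
              x$n_z_planes, x$z_step, x$frame_shape[1], x$frame_shape[2],
              x$pixel_size))
  invisible(x)
}

#' @export
print.compound_model <- function(x, ...) {
  cat(sprintf("compound %s: EC50 = %g nM, hill = %g, max effect = %g\n",
              x$name, x$ec50, x$hill, x$max_effect))
  invisible(x)
}
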