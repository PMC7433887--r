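#' Write a two-channel stack as 16-bit multi-page TIFFs
#'
#' One file per channel, `<well>_dapi.tif` (nuclei) and `<well>_actin.tif`,
#' z-planes as TIFF pages. Intensities are stored as 16-bit unsigned values.
#'
#' @param stack An `image_stack` (see [generate_well_stack()]).
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_stack_tiff <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  paths <- c(dapi = file.path(dir, paste0(stack$well_id, "_dapi.tif")),
             actin = file.path(dir, paste0(stack$well_id, "_actin.tif")))
  for (ch in c("dapi", "actin")) {
    vol <- if (ch == "dapi") stack$nuclei else stack$actin
    pages <- lapply(seq_len(dim(vol)[3]),
                    function(z) round(vol[, , z]) / 65535)
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16,
                    compression = "none")
  }
  invisible(paths)
}

#' Read a two-channel stack written by [write_stack_tiff()]
#'
#' @param dir Directory holding `<well>_dapi.tif` and `<well>_actin.tif`.
#' @param well_id Well identifier.
#' @param acq The [acquisition_params()] used at acquisition time; validated
#'   against the number of TIFF pages.
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(dir, well_id, acq = acquisition_params()) {
  read_vol <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) * 65535
  }
  nuc <- read_vol(file.path(dir, paste0(well_id, "_dapi.tif")))
  act <- read_vol(file.path(dir, paste0(well_id, "_actin.tif")))
  if (dim(nuc)[3] != acq$n_z_planes)
    warning("plane count (", dim(nuc)[3], ") differs from acquisition (",
            acq$n_z_planes, ")")
  structure(list(nuclei = nuc, actin = act, acquisition = acq,
                 well_id = well_id),
            class = "image_stack")
}

#' Read a plate-layout table
#'
#' @param path CSV with at least the columns `well, compound, dose_nM, role,
#'   replicate` (as written by [generate_screen()]).
#' @return A data.frame.
#' @export
read_layout <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "compound", "dose_nM", "role", "replicate")
  miss <- setdiff(need, names(layout))
  if (length(miss)) stop("layout is missing columns: ",
                         paste(miss, collapse = ", "))
  layout
}
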