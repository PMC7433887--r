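#' Read simulation/analysis parameters from a config file
#'
#' Reads a YAML or JSON file with any of the top-level keys `acquisition`,
#' `phenotype`, `plate`, `compounds` (a list of compound entries) and
#' `segmentation` (passed to [segment_well()]), and returns constructed
#' parameter objects with package defaults filling everything the file does
#' not set.
#'
#' @param path Config file; `.json` is parsed with jsonlite, anything else
#'   with yaml (requires the yaml package).
#' @return A list with `acquisition`, `phenotype`, `plate`, `compounds`
#'   (list of [compound_model()], possibly empty) and `segmentation` (plain
#'   list of overrides).
#' @export
read_screen_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  }
  build <- function(ctor, args) do.call(ctor, as.list(args))
  cmps <- lapply(cfg$compounds, function(cm)
    build(compound_model, cm))
  list(acquisition = build(acquisition_params, cfg$acquisition),
       phenotype = build(phenotype_params, cfg$phenotype),
       plate = build(plate_design, cfg$plate),
       compounds = cmps,
       segmentation = if (is.null(cfg$segmentation)) list()
       else as.list(cfg$segmentation))
}

#' Write the feature-registry manifest as JSON
#'
#' Records the exact per-organoid feature names, aggregations and expanded
#' per-well columns of the default registry, for provenance alongside
#' exported feature tables.
#'
#' @param path Output JSON file.
#' @return Invisibly, the registry.
#' @export
write_registry_manifest <- function(path) {
  reg <- feature_registry()
  jsonlite::write_json(reg, path, auto_unbox = FALSE)
  invisible(reg)
}
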