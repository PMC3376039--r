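#' Study configuration defaults
#'
#' Collects every tunable constant of the toolkit in one serialisable
#' structure: shrinkage fractions, the detection cutoff (diameter, and
#' whether it is expressed on the in-vivo or the on-slide scale), the
#' needle gauge table, CKD stage bands and the log-rank design
#' parameters. Round-trips unchanged through [write_study_config()] /
#' [read_study_config()].
#'
#' @param shrinkage_tissue,shrinkage_glomerulus volume shrinkage fractions.
#' @param cutoff_diameter_um detection cutoff as an observed profile
#'   diameter, micrometres.
#' @param cutoff_space `"in_vivo"` (default) or `"on_slide"`; on-slide
#'   cutoffs are corrected by the glomerular linear factor before use.
#' @param gauge_table named list, gauge number to internal diameter (mm).
#' @param ckd_bands four decreasing eGFR stage cutoffs.
#' @param design a [design_spec()] (stored as plain fields).
#' @return object of class `study_config`.
#' @export
study_config <- function(shrinkage_tissue = 0.31,
                         shrinkage_glomerulus = 0.43,
                         cutoff_diameter_um = 5,
                         cutoff_space = c("in_vivo", "on_slide"),
                         gauge_table = as.list(default_gauge_table()),
                         ckd_bands = c(90, 60, 30, 15),
                         design = design_spec()) {
  structure(
    list(schema_version = "1.0",
         shrinkage = list(tissue = shrinkage_tissue,
                          glomerulus = shrinkage_glomerulus),
         cutoff_diameter_um = cutoff_diameter_um,
         cutoff_space = match.arg(cutoff_space),
         gauge_table = gauge_table,
         ckd_bands = as.numeric(ckd_bands),
         design = unclass(design)),
    class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_config(
    shrinkage_tissue = raw$shrinkage$tissue,
    shrinkage_glomerulus = raw$shrinkage$glomerulus,
    cutoff_diameter_um = raw$cutoff_diameter_um,
    cutoff_space = raw$cutoff_space,
    gauge_table = raw$gauge_table,
    ckd_bands = unlist(raw$ckd_bands),
    design = do.call(design_spec, raw$design[
      setdiff(names(raw$design), character())])
  )
  cfg
}

#' Derived model objects from a study configuration
#'
#' `shrinkage_from_config` builds the [shrinkage_model()];
#' `geometry_from_config` builds the [glomerular_geometry()] for a cohort
#' mean radius, applying the cutoff-space convention (an on-slide cutoff
#' is divided by the glomerular linear factor to reach in-vivo scale).
#'
#' @param config a [study_config()].
#' @param r cohort mean glomerular radius, micrometres, in-vivo.
#' @export
geometry_from_config <- function(config, r) {
  sh <- shrinkage_from_config(config)
  r_o <- config$cutoff_diameter_um / 2
  if (config$cutoff_space == "on_slide")
    r_o <- r_o / sh$linear_factor_glomerulus
  glomerular_geometry(r, r_o)
}

#' @rdname geometry_from_config
#' @export
shrinkage_from_config <- function(config) {
  shrinkage_model(tissue = config$shrinkage$tissue,
                  glomerulus = config$shrinkage$glomerulus)
}

#' @rdname geometry_from_config
#' @export
gauge_table_from_config <- function(config) {
  unlist(config$gauge_table)
}
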