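#' Flatten a nephron estimate into an audit payload
#'
#' Every intermediate of the stereological chain, as plain named values
#' suitable for a JSON report: shrinkage factors, geometry, mean profile
#' area, cortex area, profile counts, volume fraction, totals and the
#' adequacy flag.
#'
#' @param est a `nephron_estimate` from [estimate_nephrons()].
#' @return named list.
#' @export
estimate_report <- function(est) {
  if (!inherits(est, "nephron_estimate"))
    stop_domain("est must be a nephron_estimate")
  list(
    linear_factor_tissue = est$shrinkage$linear_factor_tissue,
    linear_factor_glomerulus = est$shrinkage$linear_factor_glomerulus,
    r_um = est$geometry$r,
    r_o_um = est$geometry$r_o,
    mean_profile_area_um2 = est$mean_profile_area,
    cortex_area_um2 = est$cortex_area,
    n_profiles_used = est$n_profiles_used,
    n_sclerotic = est$n_sclerotic,
    sections_ignored = est$sections_ignored,
    volume_fraction = est$volume_fraction,
    v_cortex = est$v_cortex,
    v_cortex_unit = est$v_cortex_unit,
    total_number = est$total_number,
    total_number_nonsclerotic = est$total_number_nonsclerotic,
    adequacy = est$adequacy
  )
}

# canonical JSON for hashing/serialisation: stable key order, no NAs lost
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canonical_json(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write an audit-ready JSON report
#'
#' The report echoes the results, the configuration (with its MD5 hash),
#' the seed and the package version. Output is byte-stable: identical
#' inputs give identical bytes (no timestamps).
#'
#' @param results named list of results (e.g. [estimate_report()] output).
#' @param path output path.
#' @param config optional [study_config()] to embed and hash.
#' @param seed optional seed to record.
#' @param inputs optional named list echoing the input files/parameters.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path, config = NULL, seed = NULL,
                         inputs = NULL) {
  payload <- list(
    tool = "nephest",
    version = as.character(utils::packageVersion("nephest")),
    seed = seed,
    inputs = inputs,
    config = if (!is.null(config)) unclass(config),
    config_hash = if (!is.null(config)) config_hash(config),
    results = results
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop("cannot write report to '", path, "': ",
                         conditionMessage(e)))
  on.exit(close(con))
  writeLines(canonical_json(payload), con)
  invisible(path)
}
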