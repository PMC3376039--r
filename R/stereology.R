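#' Glomerular volume fraction of the cortex
#'
#' By the Delesse principle the volume fraction of glomeruli in the cortex
#' equals the area fraction seen on random sections:
#' `VF = N_s * A_h / A_cortex`. Values above 1 are physically impossible;
#' they are clipped to 1 with a warning and marked with a `clipped`
#' attribute so the caller can filter.
#'
#' @param n_s number of observed glomerular profiles (over usable sections).
#' @param a_h mean observed profile area, square micrometres
#'   ([mean_profile_area()]).
#' @param a_cortex in-vivo cortex area of the specimen, square micrometres
#'   ([cortex_section_area()]).
#' @return the volume fraction, dimensionless, with attribute `clipped`.
#' @export
volume_fraction <- function(n_s, a_h, a_cortex) {
  check_number(n_s, "n_s", lower = 0)
  check_number(a_h, "a_h", lower = 0)
  if (!is.numeric(a_cortex) || length(a_cortex) != 1L || !is.finite(a_cortex) ||
      a_cortex <= 0)
    stop_domain("a_cortex must be > 0")
  vf <- n_s * a_h / a_cortex
  clipped <- vf > 1
  if (clipped) {
    warning("volume fraction ", format(vf, digits = 4),
            " exceeds 1; clipped (check inputs and units)")
    vf <- 1
  }
  structure(vf, clipped = clipped)
}

#' Total glomerular number from volume fraction and cortex volume
#'
#' The total glomerular volume in the cortex is `VF * V_cortex`; dividing
#' by the mean single-glomerular volume `(4/3) pi r^3` gives the total
#' number of glomeruli. Cortex volumes carry an explicit unit tag; there is
#' no silent unit inference.
#'
#' @param vf glomerular volume fraction in `[0, 1]`.
#' @param v_cortex cortex volume (both kidneys for a whole-body count).
#' @param geometry a [glomerular_geometry()] giving the cohort mean radius.
#' @param unit unit of `v_cortex`: `"cm3"`, `"mm3"` or `"um3"`.
#' @return total glomerular number (not rounded).
#' @examples
#' g <- glomerular_geometry(100, 2.5)
#' total_glomerular_number(0.03, 100, g, unit = "cm3")
#' @export
total_glomerular_number <- function(vf, v_cortex, geometry,
                                    unit = c("cm3", "mm3", "um3")) {
  check_number(as.numeric(vf), "vf", lower = 0, upper = 1)
  check_number(v_cortex, "v_cortex", lower = 0, strict_lower = TRUE)
  if (!inherits(geometry, "glomerular_geometry"))
    stop_domain("geometry must be a glomerular_geometry object")
  unit <- match.arg(unit)
  v_um3 <- volume_to_um3(v_cortex, unit)
  as.numeric(vf) * v_um3 / mean_glomerular_volume(geometry)
}

#' Cohort mean glomerular radius from a random patient subsample
#'
#' The common radius entering the estimator is fixed once for the cohort:
#' a fraction of patients (default 5%) is sampled without replacement and
#' the mean of their shrinkage-corrected mean profile-equivalent radii is
#' taken. The sample size is the ceiling of `fraction * n`, so at least one
#' patient is always drawn; the draw is deterministic given `seed`.
#'
#' How a patient's own mean radius is measured on sections (maximum Feret,
#' equivalent-circle, ...) is a lab convention; the function accepts the
#' precomputed per-patient values as measured on the slide and corrects
#' them by the glomerular linear shrinkage factor (pass a zero-shrinkage
#' model if the inputs are already in-vivo).
#'
#' @param radii numeric vector of per-patient mean radii, micrometres,
#'   on-slide scale.
#' @param sample_fraction fraction of patients to sample, in `(0, 1]`
#'   (default 0.05).
#' @param seed integer seed for the subsample draw (optional).
#' @param shrinkage a [shrinkage_model()]; its glomerular linear factor
#'   corrects the radii to in-vivo scale.
#' @return the cohort mean radius `r`, micrometres, in-vivo scale.
#' @export
cohort_mean_radius <- function(radii, sample_fraction = 0.05, seed = NULL,
                               shrinkage = shrinkage_model()) {
  if (!is.numeric(radii) || length(radii) == 0L || any(!is.finite(radii)) ||
      any(radii <= 0))
    stop_domain("radii must be a non-empty vector of positive values")
  check_number(sample_fraction, "sample_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (!inherits(shrinkage, "shrinkage_model"))
    stop_domain("shrinkage must be a shrinkage_model")
  n <- length(radii)
  m <- ceiling(sample_fraction * n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  picked <- sample.int(n, m)
  mean(correct_to_in_vivo(radii[picked], shrinkage$linear_factor_glomerulus))
}

#' Estimate the total nephron number from a biopsy specimen
#'
#' Runs the full stereological chain: usability/adequacy rules, in-vivo
#' cortex area, mean observed profile area under the detection cutoff,
#' glomerular volume fraction (Delesse), and finally the total glomerular
#' number `VF * V_cortex / ((4/3) pi r^3)`. A secondary count excluding
#' globally sclerotic glomeruli is reported alongside. The adequacy flag is
#' carried through without suppressing the numeric estimate, so downstream
#' filtering stays explicit.
#'
#' @param specimen a [biopsy_specimen()].
#' @param v_cortex cortex volume, in `unit`.
#' @param geometry a [glomerular_geometry()] with the cohort mean radius.
#' @param shrinkage a [shrinkage_model()].
#' @param table gauge table ([default_gauge_table()]).
#' @param unit unit of `v_cortex` (`"cm3"`, `"mm3"`, `"um3"`).
#' @return an object of class `nephron_estimate`: a list with
#'   `mean_profile_area`, `cortex_area`, `n_profiles_used`,
#'   `n_sclerotic`, `volume_fraction`, `total_number`,
#'   `total_number_nonsclerotic`, `adequacy` (`"adequate"` or
#'   `"insufficient"`), `sections_ignored`, plus the inputs' shrinkage
#'   factors for audit.
#' @examples
#' sp <- biopsy_specimen(biopsy_section(10, 10), needle_gauge = 16)
#' g <- glomerular_geometry(100, 2.5)
#' estimate_nephrons(sp, v_cortex = 100, geometry = g)
#' @export
estimate_nephrons <- function(specimen, v_cortex, geometry,
                              shrinkage = shrinkage_model(),
                              table = default_gauge_table(),
                              unit = c("cm3", "mm3", "um3")) {
  unit <- match.arg(unit)
  if (!inherits(specimen, "biopsy_specimen"))
    stop_domain("estimate_nephrons [specimen]: not a biopsy_specimen")
  adeq <- assess_adequacy(specimen)
  a_h <- mean_profile_area(geometry)
  if (adeq$n_s == 0L) {
    # all sections dropped or empty: report a zero estimate with the flag
    est <- list(
      mean_profile_area = a_h, cortex_area = NA_real_,
      n_profiles_used = 0L, n_sclerotic = 0L,
      volume_fraction = 0, total_number = 0,
      total_number_nonsclerotic = 0,
      adequacy = "insufficient",
      sections_ignored = adeq$sections_ignored,
      shrinkage = shrinkage, geometry = geometry,
      v_cortex = v_cortex, v_cortex_unit = unit
    )
    return(structure(est, class = "nephron_estimate"))
  }
  a_cortex <- tryCatch(
    cortex_section_area(specimen, shrinkage, table),
    error = function(e) stop_domain("estimate_nephrons [cortex area]: ",
                                    conditionMessage(e)))
  vf <- volume_fraction(adeq$n_s, a_h, a_cortex)
  n_total <- total_glomerular_number(vf, v_cortex, geometry, unit)
  n_nonscl <- adeq$n_s - adeq$n_sclerotic
  vf_ns <- volume_fraction(n_nonscl, a_h, a_cortex)
  est <- list(
    mean_profile_area = a_h,
    cortex_area = a_cortex,
    n_profiles_used = adeq$n_s,
    n_sclerotic = adeq$n_sclerotic,
    volume_fraction = as.numeric(vf),
    total_number = n_total,
    total_number_nonsclerotic =
      total_glomerular_number(vf_ns, v_cortex, geometry, unit),
    adequacy = if (adeq$adequate) "adequate" else "insufficient",
    sections_ignored = adeq$sections_ignored,
    shrinkage = shrinkage, geometry = geometry,
    v_cortex = v_cortex, v_cortex_unit = unit
  )
  structure(est, class = "nephron_estimate")
}

#' @export
print.nephron_estimate <- function(x, ...) {
  cat("Nephron number estimate\n")
  cat(sprintf("  profiles used (N_s):        %d (%d sclerotic, %d section(s) ignored)\n",
              x$n_profiles_used, x$n_sclerotic, x$sections_ignored))
  cat(sprintf("  mean profile area (A_h):    %.1f um^2\n", x$mean_profile_area))
  if (is.finite(x$cortex_area %||% NA))
    cat(sprintf("  cortex area (A_cortex_s):   %.4g um^2\n", x$cortex_area))
  cat(sprintf("  volume fraction (VF):       %.5f\n", x$volume_fraction))
  cat(sprintf("  cortex volume:              %g %s\n", x$v_cortex,
              x$v_cortex_unit))
  cat(sprintf("  total glomerular number:    %.0f\n", x$total_number))
  cat(sprintf("  non-sclerotic:              %.0f\n",
              x$total_number_nonsclerotic))
  cat(sprintf("  adequacy:                   %s\n", x$adequacy))
  invisible(x)
}
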