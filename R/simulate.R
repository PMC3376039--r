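#' A virtual kidney with known ground truth
#'
#' The generative counterpart of the nephron-number estimator: glomeruli
#' are spheres of one common radius, placed homogeneously (Poisson) in a
#' cortex of known volume. The implied glomerular volume fraction must
#' stay physiological (<= 0.2), which guards against accidentally
#' simulating a cortex packed solid with glomeruli.
#'
#' @param n_glomeruli true total number of glomeruli.
#' @param radius glomerular radius, micrometres (in-vivo).
#' @param cortex_volume_cm3 cortex volume, cm^3.
#' @param sclerotic_fraction fraction of glomeruli with global sclerosis.
#' @return object of class `virtual_kidney`.
#' @examples
#' virtual_kidney()  # the default 7e5-glomerulus, 100-cm3 kidney
#' @export
virtual_kidney <- function(n_glomeruli = 7e5, radius = 100,
                           cortex_volume_cm3 = 100,
                           sclerotic_fraction = 0) {
  check_number(n_glomeruli, "n_glomeruli", lower = 0)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(cortex_volume_cm3, "cortex_volume_cm3", lower = 0,
               strict_lower = TRUE)
  check_number(sclerotic_fraction, "sclerotic_fraction", 0, 1)
  vf <- n_glomeruli * 4 / 3 * pi * radius^3 /
    volume_to_um3(cortex_volume_cm3, "cm3")
  if (vf > 0.2)
    stop_domain("implied glomerular volume fraction ", round(vf, 3),
                " exceeds the physiological guard of 0.2")
  structure(
    list(n_glomeruli_true = n_glomeruli, glomerular_radius = radius,
         cortex_volume_cm3 = cortex_volume_cm3,
         sclerotic_fraction = sclerotic_fraction,
         volume_fraction_true = vf),
    class = "virtual_kidney")
}

#' @export
print.virtual_kidney <- function(x, ...) {
  cat(sprintf(
    "Virtual kidney: %g glomeruli, r = %g um, cortex %g cm3 (VF %.4f)\n",
    x$n_glomeruli_true, x$glomerular_radius, x$cortex_volume_cm3,
    x$volume_fraction_true))
  invisible(x)
}

#' Simulate a needle biopsy of a virtual kidney
#'
#' Implements the sampling model behind the estimator. Glomerular centres
#' follow a homogeneous Poisson process of intensity
#' `n_true / V_cortex`; a sphere yields a countable profile iff its centre
#' lies within the truncation half-height `h` of the section plane (so the
#' profile diameter exceeds the detection cutoff), with the plane offset
#' uniform in `(-h, h)`. The expected profile count per section is
#' therefore `intensity * L * d_b * 2h`. Profile radii are
#' `sqrt(r^2 - x^2)`. Forward shrinkage is applied so the returned
#' specimen is in on-slide units, exactly as a real slide would be
#' measured; simulating inside a cortex buffered by `r` on all sides makes
#' the sampling unbiased (no edge effects).
#'
#' @param kidney a [virtual_kidney()].
#' @param needle_gauge needle gauge (looked up in `table`; default 16).
#' @param n_sections number of sections (cores) taken.
#' @param section_length_mm in-vivo cortex length of each section, mm.
#' @param r_o detection cutoff radius, micrometres (default 2.5).
#' @param shrinkage a [shrinkage_model()] applied forward.
#' @param table gauge table ([default_gauge_table()]).
#' @param seed optional seed.
#' @return a list with `specimen` (a [biopsy_specimen()], on-slide units),
#'   `profile_radii_um` (list per section, on-slide), `geometry` (the
#'   [glomerular_geometry()] used) and `kidney`.
#' @export
sample_biopsy <- function(kidney, needle_gauge = 16, n_sections = 3,
                          section_length_mm = 10, r_o = 2.5,
                          shrinkage = shrinkage_model(),
                          table = default_gauge_table(), seed = NULL) {
  if (!inherits(kidney, "virtual_kidney"))
    stop_domain("kidney must be a virtual_kidney")
  check_number(section_length_mm, "section_length_mm", lower = 0,
               strict_lower = TRUE)
  if (n_sections < 1) stop_domain("need at least one section")
  geom <- glomerular_geometry(kidney$glomerular_radius, r_o)
  d_b_um <- needle_internal_diameter(needle_gauge, table) * 1e3
  l_um <- section_length_mm * 1e3
  intensity <- kidney$n_glomeruli_true /
    volume_to_um3(kidney$cortex_volume_cm3, "cm3")
  mu <- intensity * l_um * d_b_um * 2 * geom$h
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  f_t <- shrinkage$linear_factor_tissue
  f_g <- shrinkage$linear_factor_glomerulus
  sections <- vector("list", n_sections)
  radii <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    k <- stats::rpois(1, mu)
    x <- stats::runif(k, -geom$h, geom$h)
    r_prof <- sqrt(kidney$glomerular_radius^2 - x^2)
    n_scl <- stats::rbinom(1, k, kidney$sclerotic_fraction)
    sections[[i]] <- biopsy_section(
      cortex_segment_lengths = section_length_mm * f_t,  # on-slide mm
      n_glomeruli = k, n_global_sclerosis = n_scl)
    radii[[i]] <- r_prof * f_g                           # on-slide um
  }
  list(specimen = biopsy_specimen(sections, needle_gauge),
       profile_radii_um = radii, geometry = geom, kidney = kidney,
       expected_profiles_per_section = mu)
}

#' Ellipsoid tomography phantom
#'
#' An analytic organ phantom for validating slice-summation volumetry: an
#' outer ellipsoid (the whole kidney) with a concentric inner ellipsoid
#' (the medulla) scaled by `cortex_shell_fraction`; the cortex is the
#' shell between them, so the true cortex volume is
#' `(1 - s^3)` of the whole. Slices are taken perpendicular to the third
#' semi-axis at the given spacing, with areas evaluated at slice centres
#' -- the same plain area-times-spacing model the volumetry uses.
#'
#' @param semi_axes_cm numeric length-3, ellipsoid semi-axes (a, b, c) in
#'   cm; slicing is along the `c` axis.
#' @param cortex_shell_fraction linear scale `s` of the inner ellipsoid,
#'   in (0, 1).
#' @param spacing_cm slice spacing, cm; must be smaller than `2c`.
#' @return list with `slices` (data frame `slice_index`, `kidney_area_cm2`,
#'   `cortex_area_cm2`, `spacing_cm`) and `true` (analytic
#'   `whole_kidney_cm3`, `cortex_cm3`).
#' @examples
#' ph <- mri_phantom(c(1, 1, 1), 0.5, 0.05)  # unit sphere
#' volume_from_slices(ph$slices)
#' ph$true$whole_kidney_cm3  # 4/3*pi
#' @export
mri_phantom <- function(semi_axes_cm = c(3, 2, 5),
                        cortex_shell_fraction = 0.5, spacing_cm = 0.1) {
  if (length(semi_axes_cm) != 3L || any(!is.finite(semi_axes_cm)) ||
      any(semi_axes_cm <= 0))
    stop_domain("semi_axes_cm must be three positive numbers")
  check_number(cortex_shell_fraction, "cortex_shell_fraction", 0, 1,
               TRUE, TRUE)
  a <- semi_axes_cm[1]; b <- semi_axes_cm[2]; cc <- semi_axes_cm[3]
  check_number(spacing_cm, "spacing_cm", lower = 0, upper = 2 * cc,
               strict_lower = TRUE, strict_upper = TRUE)
  s <- cortex_shell_fraction
  n <- ceiling(2 * cc / spacing_cm)
  z <- -cc + (seq_len(n) - 0.5) * spacing_cm
  ellipse_area <- function(z, a, b, c) {
    ifelse(abs(z) < c, pi * a * b * (1 - z^2 / c^2), 0)
  }
  outer_a <- ellipse_area(z, a, b, cc)
  inner_a <- ellipse_area(z, s * a, s * b, s * cc)
  whole <- 4 / 3 * pi * a * b * cc
  list(
    slices = data.frame(slice_index = seq_len(n),
                        kidney_area_cm2 = outer_a,
                        cortex_area_cm2 = outer_a - inner_a,
                        spacing_cm = spacing_cm),
    true = list(whole_kidney_cm3 = whole,
                cortex_cm3 = whole * (1 - s^3))
  )
}
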