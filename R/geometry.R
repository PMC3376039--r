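#' Glomerular sphere geometry with a detection cutoff
#'
#' Glomeruli are modelled as spheres of a common in-vivo radius `r`. On a
#' random planar section, profiles with diameter below the microscopic
#' detection limit (5 micrometres, i.e. cutoff radius `r_o` = 2.5) cannot be
#' counted. A sphere yields a countable profile only when the cutting plane
#' passes within the truncation half-height `h = sqrt(r^2 - r_o^2)` of its
#' centre (Pythagoras), so `h^2 + r_o^2 = r^2` exactly.
#'
#' @param r cohort mean glomerular radius, micrometres, in-vivo scale.
#' @param r_o observation cutoff radius, micrometres (default 2.5,
#'   corresponding to the 5-micrometre observed-diameter limit).
#' @return an object of class `glomerular_geometry` with elements `r`,
#'   `r_o` and the derived `h`.
#' @seealso [mean_profile_area()]
#' @export
glomerular_geometry <- function(r, r_o = 2.5) {
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  check_number(r_o, "r_o", lower = 0)
  if (r <= r_o)
    stop_domain("r must exceed r_o: no observable profiles when r <= r_o ",
                "(r = ", r, ", r_o = ", r_o, ")")
  structure(
    list(r = r, r_o = r_o, h = sqrt(r^2 - r_o^2)),
    class = "glomerular_geometry"
  )
}

#' @export
print.glomerular_geometry <- function(x, ...) {
  cat(sprintf(
    "Glomerular geometry: r = %.4g um, cutoff r_o = %.4g um, h = %.6g um\n",
    x$r, x$r_o, x$h))
  invisible(x)
}

#' Mean observed profile area of a sphere under a detection cutoff
#'
#' When a sphere of radius `r` is cut by a plane at a uniformly random
#' offset `x` within the observable band `|x| <= h`, the profile is a circle
#' of area `pi * (r^2 - x^2)`. Averaging over the band gives
#' \deqn{A_h = \pi (r^2 - h^2/3) = \pi (2 r^2/3 + r_o^2/3).}
#' Without a cutoff (`r_o = 0`) this reduces to the classical mean section
#' area `(2/3) pi r^2`; as `r_o` approaches `r` only equatorial circles
#' remain and `A_h` tends to `pi r_o^2`.
#'
#' @param geometry a [glomerular_geometry()] object.
#' @return mean observed profile area, square micrometres.
#' @examples
#' mean_profile_area(glomerular_geometry(100, 0))    # (2/3)*pi*100^2
#' mean_profile_area(glomerular_geometry(100, 2.5))
#' @export
mean_profile_area <- function(geometry) {
  if (!inherits(geometry, "glomerular_geometry"))
    stop_domain("geometry must be a glomerular_geometry object")
  pi * (2 * geometry$r^2 / 3 + geometry$r_o^2 / 3)
}

#' Mean single-glomerular volume
#'
#' `(4/3) pi r^3` for the cohort mean radius, cubic micrometres.
#'
#' @param geometry a [glomerular_geometry()] object.
#' @export
mean_glomerular_volume <- function(geometry) {
  if (!inherits(geometry, "glomerular_geometry"))
    stop_domain("geometry must be a glomerular_geometry object")
  4 / 3 * pi * geometry$r^3
}
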