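#' Linear shrinkage factor from a volume shrinkage fraction
#'
#' Fixation in formalin and paraffin embedding shrink tissue volumes; a
#' volume shrinkage fraction \eqn{s} corresponds to an isotropic linear
#' factor \eqn{(1-s)^{1/3}}. Multiplying an in-vivo length by the factor
#' gives the on-slide (shrunken) length; dividing an on-slide measurement by
#' it recovers the in-vivo length (see [correct_to_in_vivo()]).
#'
#' With the conventional 31% tissue volume shrinkage the linear factor is
#' 0.883; with 43% glomerular volume shrinkage (loss of arterial pressure
#' plus embedding) it is 0.829.
#'
#' @param volume_shrinkage volume shrinkage fraction in `[0, 1)`.
#' @return the linear shrinkage factor, in `(0, 1]`.
#' @examples
#' linear_shrinkage_factor(0.31)  # 0.883
#' linear_shrinkage_factor(0.43)  # 0.829
#' @export
linear_shrinkage_factor <- function(volume_shrinkage) {
  if (!is.numeric(volume_shrinkage) || any(!is.finite(volume_shrinkage)))
    stop_domain("volume_shrinkage must be finite numeric")
  if (any(volume_shrinkage < 0) || any(volume_shrinkage >= 1))
    stop_domain("volume_shrinkage must lie in [0, 1)")
  (1 - volume_shrinkage)^(1 / 3)
}

#' Correct an on-slide measurement to in-vivo scale
#'
#' @param measured measured length or radius (on-slide scale), `>= 0`.
#' @param factor linear shrinkage factor in `(0, 1]`, usually from
#'   [linear_shrinkage_factor()].
#' @return `measured / factor`, the in-vivo value. Round-trips exactly with
#'   the forward multiplication `in_vivo * factor`.
#' @examples
#' correct_to_in_vivo(8.29, 0.829)  # 10
#' @export
correct_to_in_vivo <- function(measured, factor) {
  if (!is.numeric(measured) || any(!is.finite(measured)) || any(measured < 0))
    stop_domain("measured must be finite and >= 0")
  if (!is.numeric(factor) || any(!is.finite(factor)) || any(factor <= 0) ||
      any(factor > 1))
    stop_domain("factor must lie in (0, 1]")
  measured / factor
}

#' Tissue and glomerular shrinkage model
#'
#' Bundles the two volume-shrinkage fractions used throughout the
#' stereological chain: one for the tissue block (applied to cortex
#' lengths), one for glomeruli (applied to profile radii and diameters).
#' Linear factors are derived, never hard-coded.
#'
#' @param tissue volume shrinkage fraction of the paraffin-embedded tissue
#'   (default 0.31).
#' @param glomerulus volume shrinkage fraction of glomeruli (default 0.43).
#' @return an object of class `shrinkage_model` with elements
#'   `volume_shrinkage_tissue`, `volume_shrinkage_glomerulus`,
#'   `linear_factor_tissue`, `linear_factor_glomerulus`.
#' @examples
#' shrinkage_model()
#' shrinkage_model(tissue = 0, glomerulus = 0)  # no correction
#' @export
shrinkage_model <- function(tissue = 0.31, glomerulus = 0.43) {
  check_number(tissue, "tissue", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(glomerulus, "glomerulus", lower = 0, upper = 1,
               strict_upper = TRUE)
  structure(
    list(
      volume_shrinkage_tissue = tissue,
      volume_shrinkage_glomerulus = glomerulus,
      linear_factor_tissue = linear_shrinkage_factor(tissue),
      linear_factor_glomerulus = linear_shrinkage_factor(glomerulus)
    ),
    class = "shrinkage_model"
  )
}

#' @export
print.shrinkage_model <- function(x, ...) {
  cat("Shrinkage model\n")
  cat(sprintf("  tissue:     volume %.3f -> linear factor %.4f\n",
              x$volume_shrinkage_tissue, x$linear_factor_tissue))
  cat(sprintf("  glomerulus: volume %.3f -> linear factor %.4f\n",
              x$volume_shrinkage_glomerulus, x$linear_factor_glomerulus))
  invisible(x)
}
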