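#' Whole-kidney and cortex volume from tomographic slice areas
#'
#' The organ volume is the plain Riemann sum of per-slice cross-sectional
#' areas times the slice spacing (thickness or reconstruction interval),
#' with no end-cap or trapezoid correction -- matching how the volumes are
#' read off an axial tomogram. Spacing may be uniform (scalar) or
#' per-slice.
#'
#' @param slices a data frame with columns `kidney_area_cm2`,
#'   `cortex_area_cm2` and either a `spacing_cm` column or the `spacing_cm`
#'   argument; one row per slice.
#' @param spacing_cm uniform slice spacing in cm, used when `slices` has no
#'   `spacing_cm` column.
#' @return a list with `whole_kidney_cm3` and `cortex_cm3`.
#' @examples
#' sl <- data.frame(kidney_area_cm2 = c(2, 4, 4, 2),
#'                  cortex_area_cm2 = c(1, 2, 2, 1))
#' volume_from_slices(sl, spacing_cm = 0.5)
#' @export
volume_from_slices <- function(slices, spacing_cm = NULL) {
  if (!is.data.frame(slices) || nrow(slices) == 0L)
    stop_domain("slices must be a non-empty data frame")
  for (col in c("kidney_area_cm2", "cortex_area_cm2"))
    if (!col %in% names(slices))
      stop_domain("slices is missing column '", col, "'")
  sp <- slices$spacing_cm %||% spacing_cm
  if (is.null(sp)) stop_domain("slice spacing not given")
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop_domain("slice spacing must be > 0")
  ka <- slices$kidney_area_cm2
  ca <- slices$cortex_area_cm2
  if (any(!is.finite(ka)) || any(ka < 0) || any(!is.finite(ca)) || any(ca < 0))
    stop_domain("slice areas must be finite and >= 0")
  bad <- which(ca > ka)
  if (length(bad))
    stop_domain("cortex_area_cm2 exceeds kidney_area_cm2 on slice(s) ",
                paste(bad, collapse = ", "))
  list(whole_kidney_cm3 = sum(ka * sp), cortex_cm3 = sum(ca * sp))
}

#' Fit a linear estimating equation for the cortex volume
#'
#' In routine practice the cortex volume cannot be imaged for every
#' patient; a sub-cohort with tomographic volumes is used to fit an
#' ordinary least-squares linear predictor from clinically available
#' features (ultrasound kidney axes, sex, eGFR, birth weight, body weight,
#' ...). The feature set is free; there is no automatic variable
#' selection. A rank-deficient design is refused with the offending
#' columns named.
#'
#' @param data data frame containing the features and the response.
#' @param response name of the response column (tomographic cortex volume,
#'   cm^3).
#' @param features character vector of feature column names.
#' @return an object of class `cortex_volume_model` wrapping the `lm` fit,
#'   with `feature_names`, `coefficients` and `fit_diagnostics`
#'   (`n`, `sigma`, `r_squared`, coefficient standard errors).
#' @export
fit_cortex_volume_model <- function(data, response = "cortex_volume_cm3",
                                    features) {
  if (!is.data.frame(data)) stop_domain("data must be a data frame")
  missing_cols <- setdiff(c(response, features), names(data))
  if (length(missing_cols))
    stop_domain("data is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  used <- data[, c(response, features), drop = FALSE]
  if (anyNA(used))
    stop_domain("missing values in used columns: ",
                paste(names(used)[vapply(used, anyNA, logical(1))],
                      collapse = ", "))
  if (nrow(used) < length(features) + 2L)
    stop_domain("need at least ", length(features) + 2L,
                " rows to fit ", length(features), " features")
  fml <- stats::reformulate(features, response = response)
  fit <- stats::lm(fml, data = used)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_domain("collinear design; aliased term(s): ",
                paste(aliased, collapse = ", "))
  }
  # noiseless calibration data trip summary.lm's perfect-fit warning;
  # the diagnostics are still what we want to store
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(
    list(
      feature_names = features,
      coefficients = stats::coef(fit),
      fit_diagnostics = list(
        n = nrow(used),
        sigma = sm$sigma,
        r_squared = sm$r.squared,
        coef_se = sm$coefficients[, "Std. Error"]
      ),
      response = response,
      lm = fit
    ),
    class = "cortex_volume_model"
  )
}

#' @export
print.cortex_volume_model <- function(x, ...) {
  cat("Cortex volume estimating equation (OLS)\n")
  cat("  ", x$response, " ~ ", paste(x$feature_names, collapse = " + "),
      "\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("  n = %d, residual sigma = %.3f, R^2 = %.3f\n",
              x$fit_diagnostics$n, x$fit_diagnostics$sigma,
              x$fit_diagnostics$r_squared))
  invisible(x)
}

#' Predict a cortex volume from the estimating equation
#'
#' Linear prediction from a fitted [fit_cortex_volume_model()]. Negative
#' predictions are physically impossible: they are floored at 0, warned
#' about, and flagged in the `flagged` attribute.
#'
#' @param model a `cortex_volume_model`.
#' @param newdata data frame with the model's feature columns.
#' @param interval if `"prediction"`, also return prediction-interval
#'   bounds as attributes `lower`/`upper` (95%).
#' @return predicted cortex volumes, cm^3, with attribute `flagged`
#'   (logical, TRUE where floored).
#' @export
predict_cortex_volume <- function(model, newdata,
                                  interval = c("none", "prediction")) {
  if (!inherits(model, "cortex_volume_model"))
    stop_domain("model must be a cortex_volume_model")
  interval <- match.arg(interval)
  missing_cols <- setdiff(model$feature_names, names(newdata))
  if (length(missing_cols))
    stop_domain("newdata is missing feature(s): ",
                paste(missing_cols, collapse = ", "))
  if (interval == "prediction") {
    pr <- stats::predict(model$lm, newdata = newdata,
                         interval = "prediction", level = 0.95)
    pred <- pr[, "fit"]
  } else {
    pred <- stats::predict(model$lm, newdata = newdata)
  }
  flagged <- pred < 0
  if (any(flagged)) {
    warning(sum(flagged), " negative prediction(s) floored at 0")
    pred[flagged] <- 0
  }
  out <- structure(as.numeric(pred), flagged = unname(flagged))
  if (interval == "prediction") {
    attr(out, "lower") <- unname(pr[, "lwr"])
    attr(out, "upper") <- unname(pr[, "upr"])
  }
  out
}
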