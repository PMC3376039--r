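# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("nephest_domain_error", "error")))
}

stop_unit <- function(...) {
  stop(errorCondition(paste0(...), class = c("nephest_unit_error", "error")))
}

stop_lookup <- function(...) {
  stop(errorCondition(paste0(...), class = c("nephest_lookup_error", "error")))
}

# scalar finite numeric check
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_domain(name, " must be > ", lower, " (got ", x, ")")
  if (!strict_lower && x < lower)
    stop_domain(name, " must be >= ", lower, " (got ", x, ")")
  if (strict_upper && x >= upper)
    stop_domain(name, " must be < ", upper, " (got ", x, ")")
  if (!strict_upper && x > upper)
    stop_domain(name, " must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

# years between two dates, ACT/365.25
years_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / 365.25
}

# cubic-metre style unit tags for cortex volumes; everything internal is um^3
volume_to_um3 <- function(value, unit) {
  if (length(unit) != 1L || !unit %in% c("cm3", "mm3", "um3"))
    stop_unit("unknown volume unit '", paste(unit, collapse = ","),
              "'; use one of 'cm3', 'mm3', 'um3'")
  value * switch(unit, cm3 = 1e12, mm3 = 1e9, um3 = 1)
}
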