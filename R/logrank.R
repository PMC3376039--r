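# vectorised two-group log-rank core: O(n log n), ties by the standard
# hypergeometric variance. g1 is logical membership of group 1.
logrank_core <- function(time, status, g1) {
  o <- order(time)
  t <- time[o]; s <- status[o] != 0; g <- g1[o]
  n <- length(t)
  block <- cumsum(!duplicated(t))
  nb <- block[n]
  d  <- tabulate(block[s], nb)          # events at each unique time
  d1 <- tabulate(block[s & g], nb)
  c_all <- tabulate(block, nb)          # leaving risk set at each time
  c1 <- tabulate(block[g], nb)
  n_at  <- n - c(0, cumsum(c_all)[-nb])
  n1_at <- sum(g) - c(0, cumsum(c1)[-nb])
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]
  nn <- n_at[keep]; n1 <- n1_at[keep]
  e1 <- d * n1 / nn
  v <- d * (n1 / nn) * (1 - n1 / nn) * (nn - d) / pmax(nn - 1, 1)
  c(U = sum(d1 - e1), V = sum(v), O1 = sum(d1), E1 = sum(e1))
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank test from the observed-minus-expected form:
#' at every distinct event time the events in group 1 are compared with
#' their hypergeometric expectation given the risk sets, ties handled by
#' the hypergeometric variance. The statistic `U^2/V` is chi-squared with
#' 1 degree of freedom under the null.
#'
#' @param time follow-up times.
#' @param status event indicator, 1 = event, 0 = censored.
#' @param group two-level group labels.
#' @return object of class `logrank_test`: `statistic`, `p_value`,
#'   `observed`, `expected` (both for the first factor level), `n`,
#'   `n_events`.
#' @export
logrank_test <- function(time, status, group) {
  if (length(time) != length(status) || length(time) != length(group))
    stop_domain("time, status and group must have equal length")
  if (any(!is.finite(time)) || any(time < 0))
    stop_domain("times must be finite and >= 0")
  f <- factor(group)
  if (nlevels(f) != 2L)
    stop_domain("exactly two groups are required (got ", nlevels(f), ")")
  status <- as.integer(status != 0)
  if (sum(status) < 1L) stop_domain("at least one event is required")
  core <- logrank_core(time, status, f == levels(f)[1])
  stat <- if (core[["V"]] > 0) core[["U"]]^2 / core[["V"]] else 0
  structure(
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         observed = core[["O1"]], expected = core[["E1"]],
         group1 = levels(f)[1],
         n = length(time), n_events = sum(status)),
    class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  group '%s': observed %d, expected %.2f\n",
              x$group1, x$observed, x$expected))
  cat(sprintf("  chi-square = %.4f (1 df), two-sided p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}
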