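#' Classify readings as active, resting or transitional
#'
#' The core splitting rule: readings strictly above the evaluated 55th
#' quantile curve are `ACTIVE`, readings strictly below the 45th quantile
#' curve are `REST`, and everything between the two curves — including
#' readings exactly equal to either curve — is `TRANSITIONAL`. Comparisons
#' are made against the curve value at each reading's own timestamp, so the
#' rule follows slow changes in the level of the cycle and never references
#' clock time or absolute temperature.
#'
#' @param trace A [tb_trace()].
#' @param q45 Evaluated lower (45th) quantile series aligned to the trace.
#' @param q55 Evaluated upper (55th) quantile series aligned to the trace;
#'   must satisfy `q45 <= q55` pointwise (see [rearrange_noncrossing()]).
#' @return An object of class `tb_phases` with `labels` (character vector)
#'   and counts `n_active`, `n_rest`, `n_transitional`.
#' @export
classify_phases <- function(trace, q45, q55) {
  validate_tb_trace(trace)
  n <- length(trace$tb_c)
  if (length(q45) != n || length(q55) != n) {
    stop_tbwave("quantile series must align with the trace",
                class = "tbwave_validation_error")
  }
  if (any(q45 > q55)) {
    stop_tbwave("q45 exceeds q55 at ", sum(q45 > q55),
                " point(s); rearrange the curves first",
                class = "tbwave_validation_error")
  }
  labels <- rep("TRANSITIONAL", n)
  labels[trace$tb_c > q55] <- "ACTIVE"
  labels[trace$tb_c < q45] <- "REST"
  structure(list(labels = labels,
                 n_active = sum(labels == "ACTIVE"),
                 n_rest = sum(labels == "REST"),
                 n_transitional = sum(labels == "TRANSITIONAL")),
            class = "tb_phases")
}

#' @export
print.tb_phases <- function(x, ...) {
  cat(sprintf("<tb_phases> active %d | rest %d | transitional %d\n",
              x$n_active, x$n_rest, x$n_transitional))
  invisible(x)
}

#' Extract per-phase temperature readings
#'
#' Returns the active-phase readings, rest-phase readings and the overall
#' set. Transitional readings are excluded from the active and rest sets
#' but kept in the overall set: the overall marginal distribution is an
#' object of study in its own right.
#'
#' @param trace A [tb_trace()].
#' @param partition A [classify_phases()] result aligned to `trace`.
#' @return List with numeric vectors `active`, `rest`, `overall`.
#' @export
phase_subsets <- function(trace, partition) {
  validate_tb_trace(trace)
  if (!inherits(partition, "tb_phases") ||
      length(partition$labels) != length(trace$tb_c)) {
    stop_tbwave("partition not aligned to trace",
                class = "tbwave_validation_error")
  }
  list(active = trace$tb_c[partition$labels == "ACTIVE"],
       rest = trace$tb_c[partition$labels == "REST"],
       overall = trace$tb_c)
}

#' Fit both phase-splitting quantile curves and classify a trace
#'
#' Convenience wrapper running the full partition step: fit the lower and
#' upper quantile curves (default 45th and 55th), rearrange them so they
#' never cross, and classify every reading.
#'
#' @param trace A [tb_trace()] segment long enough to fit.
#' @param taus Length-2 increasing vector of quantile levels.
#' @param ... Passed to [fit_quantile_curve()].
#' @return List with `partition` (`tb_phases`), `q45`, `q55` (evaluated,
#'   rearranged series), `curves` (the two fits) and `n_rearranged`.
#' @export
partition_trace <- function(trace, taus = c(0.45, 0.55), ...) {
  if (length(taus) != 2L || taus[1] >= taus[2]) {
    stop_tbwave("`taus` must be two increasing quantile levels",
                class = "tbwave_validation_error")
  }
  lo <- fit_quantile_curve(trace, taus[1], ...)
  up <- fit_quantile_curve(trace, taus[2], ...)
  rc <- rearrange_noncrossing(lo, up, trace$time_h)
  part <- classify_phases(trace, rc$lower, rc$upper)
  list(partition = part, q45 = rc$lower, q55 = rc$upper,
       curves = list(lower = lo, upper = up),
       n_rearranged = rc$n_rearranged)
}
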