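#' Body temperature trace objects
#'
#' A `tb_trace` holds a single continuous core body-temperature recording:
#' time in decimal hours since the first reading (strictly increasing) and
#' one temperature per time point, plus identifying metadata. Synthetic
#' traces may carry ground-truth phase labels used to score classification.
#'
#' @param time_h Numeric vector of decimal hours since record start,
#'   strictly increasing.
#' @param tb_c Numeric vector of core body temperatures in degrees Celsius,
#'   same length as `time_h`; all values must be finite and within
#'   \[0, 50\] degrees C.
#' @param individual_id Opaque individual label.
#' @param species Opaque species label.
#' @param sample_interval_min Nominal sampling interval in minutes
#'   (metadata; inferred from the median time step when `NULL`).
#' @param truth_labels Optional character vector of per-reading phase labels
#'   (`"ACTIVE"`, `"REST"`, `"TRANSITIONAL"`), synthetic traces only.
#'
#' @return An object of class `tb_trace`.
#' @export
tb_trace <- function(time_h, tb_c, individual_id = "ind1", species = "sp1",
                     sample_interval_min = NULL, truth_labels = NULL) {
  time_h <- as.numeric(time_h)
  tb_c <- as.numeric(tb_c)
  if (is.null(sample_interval_min)) {
    sample_interval_min <- if (length(time_h) > 1L)
      stats::median(diff(time_h)) * 60 else NA_real_
  }
  x <- structure(
    list(time_h = time_h, tb_c = tb_c,
         individual_id = as.character(individual_id),
         species = as.character(species),
         sample_interval_min = sample_interval_min,
         truth_labels = truth_labels),
    class = "tb_trace")
  validate_tb_trace(x)
}

#' Validate a body temperature trace
#'
#' Checks the `tb_trace` invariants: equal-length time and temperature
#' vectors, strictly increasing time, finite temperatures within
#' \[0, 50\] degrees C, and (when present) truth labels aligned to readings.
#'
#' @param x A `tb_trace`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error of class
#'   `tbwave_validation_error`.
#' @export
validate_tb_trace <- function(x) {
  if (!inherits(x, "tb_trace")) {
    stop_tbwave("not a tb_trace object", class = "tbwave_validation_error")
  }
  n <- length(x$time_h)
  if (length(x$tb_c) != n) {
    stop_tbwave("time_h and tb_c must have equal length",
                class = "tbwave_validation_error")
  }
  if (n == 0L) {
    stop_tbwave("trace is empty", class = "tbwave_validation_error")
  }
  if (anyNA(x$time_h) || any(!is.finite(x$time_h))) {
    stop_tbwave("time_h contains non-finite values",
                class = "tbwave_validation_error")
  }
  if (n > 1L && any(diff(x$time_h) <= 0)) {
    i <- which(diff(x$time_h) <= 0)[1L] + 1L
    stop_tbwave("time_h must be strictly increasing (violation at row ", i, ")",
                class = "tbwave_validation_error")
  }
  bad <- which(!is.finite(x$tb_c) | x$tb_c < 0 | x$tb_c > 50)
  if (length(bad)) {
    stop_tbwave(sprintf(
      "tb_c outside [0, 50] degC or non-finite at row %d (value %s)",
      bad[1L], format(x$tb_c[bad[1L]])),
      class = "tbwave_validation_error")
  }
  if (!is.null(x$truth_labels)) {
    if (length(x$truth_labels) != n) {
      stop_tbwave("truth_labels must match the number of readings",
                  class = "tbwave_validation_error")
    }
    ok <- x$truth_labels %in% c("ACTIVE", "REST", "TRANSITIONAL")
    if (!all(ok)) {
      stop_tbwave("truth_labels must be ACTIVE/REST/TRANSITIONAL",
                  class = "tbwave_validation_error")
    }
  }
  invisible(x)
}

#' @export
print.tb_trace <- function(x, ...) {
  n <- length(x$time_h)
  cat(sprintf("<tb_trace> %s / %s: %d readings over %.1f h (interval %.1f min)\n",
              x$species, x$individual_id, n,
              if (n > 1) diff(range(x$time_h)) else 0,
              x$sample_interval_min))
  cat(sprintf("  tb_c: %.2f-%.2f degC%s\n", min(x$tb_c), max(x$tb_c),
              if (!is.null(x$truth_labels)) " (truth labels present)" else ""))
  invisible(x)
}

#' @export
length.tb_trace <- function(x) length(x$time_h)

#' @export
as.data.frame.tb_trace <- function(x, ...) {
  d <- data.frame(time_h = x$time_h, tb_c = x$tb_c)
  if (!is.null(x$truth_labels)) d$truth_label <- x$truth_labels
  d
}
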