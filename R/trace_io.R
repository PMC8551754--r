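#' Read a body temperature trace from CSV
#'
#' Reads a long-form logger file with one timestamp column and one
#' temperature column, converts timestamps to decimal hours since the first
#' reading, drops rows with missing temperature (their count is reported via
#' a message), and returns a validated [tb_trace()].
#'
#' Timestamps may be ISO-8601 date-times (`"2021-03-01 14:00:00"` or with a
#' `T` separator) or already-numeric decimal hours. Absolute calendar time is
#' never used by any downstream statistic; only elapsed hours are retained.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param column_spec Named character vector mapping the roles `time` and
#'   `temp` to column names in the file, or `NULL` (default) to auto-detect
#'   among the common names `time_h`/`time`/`timestamp`/`datetime` and
#'   `tb_c`/`temp`/`temperature`/`tb`.
#' @param timestamp_format One of `"auto"` (default), `"iso8601"`, `"hours"`.
#' @param individual_id,species Metadata labels attached to the trace.
#' @return A [tb_trace()].
#' @export
read_trace <- function(path, column_spec = NULL,
                       timestamp_format = c("auto", "iso8601", "hours"),
                       individual_id = "ind1", species = "sp1") {
  timestamp_format <- match.arg(timestamp_format)
  if (!file.exists(path)) {
    stop_tbwave("file not found: ", path, class = "tbwave_io_error")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column_spec)) {
    pick <- function(cands, role) {
      hit <- cands[cands %in% names(d)]
      if (length(hit) == 0L) {
        stop_tbwave(sprintf("no %s column found in %s (looked for %s)",
                            role, path, paste(cands, collapse = ", ")),
                    class = "tbwave_format_error")
      }
      hit[1L]
    }
    column_spec <- c(
      time = pick(c("time_h", "time", "timestamp", "datetime"), "time"),
      temp = pick(c("tb_c", "temp", "temperature", "tb"), "temperature"))
  }
  for (role in c("time", "temp")) {
    if (!column_spec[[role]] %in% names(d)) {
      stop_tbwave(sprintf("column '%s' (role %s) not found in %s",
                          column_spec[[role]], role, path),
                  class = "tbwave_format_error")
    }
  }
  traw <- d[[column_spec[["time"]]]]
  temp <- suppressWarnings(as.numeric(d[[column_spec[["temp"]]]]))

  time_h <- parse_timestamps(traw, timestamp_format)

  drop <- is.na(temp)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing temperature dropped")
    time_h <- time_h[!drop]
    temp <- temp[!drop]
  }
  if (length(time_h) > 1L && any(diff(time_h) <= 0)) {
    i <- which(diff(time_h) <= 0)[1L] + 1L
    stop_tbwave("timestamps not strictly increasing at data row ", i,
                class = "tbwave_validation_error")
  }
  tb_trace(time_h - time_h[1L], temp,
           individual_id = individual_id, species = species)
}

parse_timestamps <- function(traw, timestamp_format) {
  if (timestamp_format == "auto") {
    timestamp_format <- if (is.numeric(traw) ||
                            !anyNA(suppressWarnings(as.numeric(traw))))
      "hours" else "iso8601"
  }
  if (timestamp_format == "hours") {
    th <- suppressWarnings(as.numeric(traw))
    if (anyNA(th)) {
      stop_tbwave("unparseable numeric timestamp at row ",
                  which(is.na(th))[1L], class = "tbwave_format_error")
    }
    return(th)
  }
  # bare clock times HH:MM[:SS] (logger dumps without dates)
  s <- as.character(traw)
  if (all(grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", s))) {
    parts <- strsplit(s, ":", fixed = TRUE)
    return(vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] + p[2] / 60 + if (length(p) > 2) p[3] / 3600 else 0
    }, numeric(1)))
  }
  # ISO-8601; accept date-only, space or 'T' separator
  s <- gsub("T", " ", s, fixed = TRUE)
  tt <- rep(as.POSIXct(NA), length(s))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(tt)
    if (!any(miss)) break
    tt[miss] <- as.POSIXct(strptime(s[miss], fmt, tz = "UTC"))
  }
  if (anyNA(tt)) {
    stop_tbwave("unparseable timestamp at row ", which(is.na(tt))[1L],
                class = "tbwave_format_error")
  }
  as.numeric(difftime(tt, tt[1L], units = "hours"))
}

#' Split a trace at recording gaps
#'
#' Field loggers fail and are redeployed; quantile smooths must not bridge
#' long gaps. `segment_trace` splits a trace wherever the step between
#' consecutive readings exceeds `max_gap_h`. Each segment keeps its original
#' timestamps. Segments spanning less than `min_duration_h` are flagged
#' unusable for curve fitting via the attribute `usable`.
#'
#' @param trace A [tb_trace()].
#' @param max_gap_h Maximum tolerated gap between readings, hours (> 0).
#' @param min_duration_h Minimum segment span required for fitting, hours.
#'   The default, 72 h, guarantees at least three daily cycles.
#' @return A list of `tb_trace` segments in time order; each has attribute
#'   `usable` (logical).
#' @export
segment_trace <- function(trace, max_gap_h = 6, min_duration_h = 72) {
  validate_tb_trace(trace)
  assert_scalar_num(max_gap_h, "max_gap_h", lower = 1e-9)
  n <- length(trace$time_h)
  cuts <- if (n > 1L) which(diff(trace$time_h) > max_gap_h) else integer()
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    seg <- trace
    seg$time_h <- trace$time_h[idx]
    seg$tb_c <- trace$tb_c[idx]
    if (!is.null(trace$truth_labels)) seg$truth_labels <- trace$truth_labels[idx]
    span <- if (length(idx) > 1L) diff(range(seg$time_h)) else 0
    attr(seg, "usable") <- span >= min_duration_h
    seg
  })
}

#' Write a trace to CSV
#'
#' Writes `time_h`, `tb_c` and, when present, `truth_label` columns. The
#' written file round-trips through [read_trace()] to 1e-6.
#'
#' @param trace A [tb_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_tb_trace(trace)
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write per-reading phase labels
#'
#' Emits the label file of the classification stage: one row per reading
#' with `time_h`, `tb_c`, the evaluated 45th/55th quantile curves, and the
#' assigned phase.
#'
#' @param trace A [tb_trace()].
#' @param partition A [classify_phases()] result aligned to `trace`.
#' @param q45,q55 Evaluated lower/upper quantile curve values at the trace
#'   timestamps.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(trace, partition, q45, q55, path) {
  validate_tb_trace(trace)
  d <- data.frame(time_h = trace$time_h, tb_c = trace$tb_c,
                  q45 = q45, q55 = q55, phase = partition$labels)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

report_fields <- function() {
  per_phase <- c("n", "mode_c", "q10_c", "q90_c", "skew", "skew_class",
                 "dip_stat", "dip_p", "bimodal")
  c("species", "individual_id",
    paste0("active_", per_phase), paste0("rest_", per_phase),
    paste0("overall_", per_phase), "amplitude_c")
}

flatten_summary <- function(s) {
  row <- list(species = s$species, individual_id = s$individual_id)
  for (phase in c("active", "rest", "overall")) {
    st <- s[[phase]]
    for (f in c("n", "mode_c", "q10_c", "q90_c", "skew", "skew_class",
                "dip_stat", "dip_p", "bimodal")) {
      v <- st[[f]]
      row[[paste0(phase, "_", f)]] <- if (is.null(v)) NA else v
    }
  }
  row$amplitude_c <- s$amplitude_c
  row
}

unflatten_summary <- function(row) {
  gets <- function(phase) {
    st <- list(
      n = as.integer(row[[paste0(phase, "_n")]]),
      mode_c = as.numeric(row[[paste0(phase, "_mode_c")]]),
      q10_c = as.numeric(row[[paste0(phase, "_q10_c")]]),
      q90_c = as.numeric(row[[paste0(phase, "_q90_c")]]),
      skew = as.numeric(row[[paste0(phase, "_skew")]]),
      skew_class = as.character(row[[paste0(phase, "_skew_class")]]),
      dip_stat = as.numeric(row[[paste0(phase, "_dip_stat")]]),
      dip_p = as.numeric(row[[paste0(phase, "_dip_p")]]),
      bimodal = as.logical(row[[paste0(phase, "_bimodal")]]))
    class(st) <- "tb_shape_stats"
    st
  }
  out <- list(species = as.character(row$species),
              individual_id = as.character(row$individual_id),
              active = gets("active"), rest = gets("rest"),
              overall = gets("overall"),
              amplitude_c = as.numeric(row$amplitude_c))
  class(out) <- "tb_individual_summary"
  out
}

#' Write per-individual summary reports
#'
#' Serializes a list of individual summaries (see [summarize_individual()])
#' to CSV (one row per individual) or JSON (one object per individual).
#' Numeric fields survive a write/read round trip to at least four decimal
#' places.
#'
#' @param summaries Non-empty list of `tb_individual_summary` objects.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(summaries, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (length(summaries) == 0L) {
    stop_tbwave("`summaries` must be non-empty",
                class = "tbwave_validation_error")
  }
  rows <- lapply(summaries, flatten_summary)
  if (format == "csv") {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_tbwave("cannot write report to ", path,
                         class = "tbwave_io_error")
  } else {
    ok <- tryCatch({
      jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                           na = "null")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_tbwave("cannot write report to ", path,
                         class = "tbwave_io_error")
  }
  invisible(path)
}

#' Read back a summary report
#'
#' Inverse of [write_report()]; reconstructs the list of individual
#' summaries from a CSV or JSON report file.
#'
#' @param path Report file path.
#' @param format `"csv"` or `"json"`.
#' @return List of `tb_individual_summary` objects.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) unflatten_summary(df[i, ]))
  } else {
    rows <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(rows, function(r) {
      r[vapply(r, is.null, logical(1))] <- NA
      unflatten_summary(r)
    })
  }
}
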