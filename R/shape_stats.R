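#' Settings for distribution-shape reports
#'
#' @param n_mc Monte-Carlo null resamples for the dip test (>= 100).
#' @param n_boot Bootstrap resamples for skew-direction classification.
#' @param seed Seed for the dip test and bootstrap; `NULL` uses the current
#'   RNG stream.
#' @param skew_method `"moment"` (adjusted Fisher-Pearson standardized
#'   third moment, the default) or `"quantile"` (Kelly-type measure from
#'   the 10th/90th quantiles and the median).
#' @param grid_step_c KDE mode grid resolution, degrees C.
#' @param min_full_n Minimum readings for a full report; below this the dip
#'   test and skew classification are reported as missing.
#' @return A list of class `tb_shape_config`.
#' @export
shape_config <- function(n_mc = 999, n_boot = 1000, seed = NULL,
                         skew_method = c("moment", "quantile"),
                         grid_step_c = 0.01, min_full_n = 30) {
  skew_method <- match.arg(skew_method)
  assert_scalar_num(n_mc, "n_mc", lower = 100)
  assert_scalar_num(n_boot, "n_boot", lower = 1)
  assert_scalar_num(grid_step_c, "grid_step_c", lower = 1e-6)
  structure(list(n_mc = as.integer(n_mc), n_boot = as.integer(n_boot),
                 seed = seed, skew_method = skew_method,
                 grid_step_c = grid_step_c,
                 min_full_n = as.integer(min_full_n)),
            class = "tb_shape_config")
}

#' Kernel-density modal temperature
#'
#' The mode is the argmax over a regular grid (default step 0.01 degrees C,
#' spanning min - 1 to max + 1) of a Gaussian kernel density estimate with
#' Silverman's rule-of-thumb bandwidth. Ties are broken toward the lowest
#' temperature. A single value, or an all-equal sample, is returned
#' directly.
#'
#' @param values Numeric temperature readings, degrees C.
#' @param grid_step_c Grid resolution, degrees C.
#' @return The modal temperature, degrees C.
#' @export
kde_mode <- function(values, grid_step_c = 0.01) {
  if (length(values) == 0L || anyNA(values)) {
    stop_tbwave("`values` must be non-empty and free of NA",
                class = "tbwave_validation_error")
  }
  if (length(values) == 1L || max(values) == min(values)) return(values[1L])
  from <- min(values) - 1
  to <- max(values) + 1
  m <- max(512L, as.integer(round((to - from) / grid_step_c)) + 1L)
  d <- stats::density(values, bw = stats::bw.nrd0(values),
                      from = from, to = to, n = m)
  d$x[which.max(d$y)]   # which.max takes the first (lowest) maximizer
}

#' Empirical quantile (linear interpolation convention)
#'
#' Sample quantile with linear interpolation between order statistics
#' (type 7, the common statistical-computing default); fixed here because
#' the 10th and 90th quantiles are reported outputs.
#'
#' @param values Numeric readings.
#' @param p Quantile level(s) in (0, 1).
#' @return Quantile value(s), degrees C.
#' @export
empirical_quantile <- function(values, p) {
  if (length(values) == 0L || anyNA(values)) {
    stop_tbwave("`values` must be non-empty and free of NA",
                class = "tbwave_validation_error")
  }
  if (any(p <= 0 | p >= 1)) {
    stop_tbwave("`p` must lie strictly inside (0, 1)",
                class = "tbwave_validation_error")
  }
  unname(stats::quantile(values, probs = p, type = 7))
}

#' Sample skewness
#'
#' `method = "moment"` gives the adjusted Fisher-Pearson standardized third
#' moment `G1 = g1 * sqrt(n (n - 1)) / (n - 2)`; `method = "quantile"`
#' gives the Kelly-type measure `(q90 + q10 - 2 * median) / (q90 - q10)`.
#' Both are invariant to location and positive scale and flip sign under
#' negation.
#'
#' @param values Numeric readings, `n >= 3`.
#' @param method `"moment"` or `"quantile"`.
#' @return Dimensionless skewness.
#' @export
skewness <- function(values, method = c("moment", "quantile")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 3L || anyNA(values)) {
    stop_tbwave("skewness needs >= 3 non-missing values",
                class = "tbwave_validation_error")
  }
  if (method == "moment") {
    m <- mean(values)
    s2 <- mean((values - m)^2)
    if (s2 <= 0) {
      stop_tbwave("skewness undefined for zero-variance sample",
                  class = "tbwave_undefined_error")
    }
    g1 <- mean((values - m)^3) / s2^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  } else {
    q <- empirical_quantile(values, c(0.1, 0.5, 0.9))
    den <- q[3] - q[1]
    if (den <= 0) {
      stop_tbwave("skewness undefined: q90 equals q10",
                  class = "tbwave_undefined_error")
    }
    (q[3] + q[1] - 2 * q[2]) / den
  }
}

# vectorized moment skewness over bootstrap resamples (rows of M)
boot_skew_rows <- function(M) {
  n <- ncol(M)
  m1 <- rowMeans(M)
  D <- M - m1
  m2 <- rowMeans(D * D)
  m3 <- rowMeans(D * D * D)
  # a degenerate (zero-variance) resample has undefined skew; score it 0 so
  # it pulls the interval toward "symmetric" rather than poisoning it
  g1 <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Classify skew direction by bootstrap interval
#'
#' Direction labels (`"left"`, `"right"`, `"symmetric"`) come from the
#' bootstrap 95% percentile interval of the moment skewness: right when the
#' interval lies above zero, left when below, symmetric otherwise.
#' Deterministic given `seed`.
#'
#' @param values Numeric readings, `n >= 30`.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed.
#' @return One of `"left"`, `"right"`, `"symmetric"`.
#' @export
classify_skew <- function(values, n_boot = 1000, seed = NULL) {
  n <- length(values)
  if (n < 30L) {
    stop_tbwave("skew classification needs >= 30 readings (got ", n, ")",
                class = "tbwave_insufficient_data_error")
  }
  ci <- with_seed(seed, {
    sk <- numeric(n_boot)
    chunk <- max(1L, floor(2e6 / n))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      M <- matrix(values[sample.int(n, n * k, replace = TRUE)], nrow = k)
      sk[(done + 1):(done + k)] <- boot_skew_rows(M)
      done <- done + k
    }
    stats::quantile(sk, c(0.025, 0.975), names = FALSE)
  })
  if (ci[1] > 0) "right" else if (ci[2] < 0) "left" else "symmetric"
}

#' Hartigan's dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal CDF,
#' computed by the greatest-convex-minorant / least-concave-majorant
#' iteration. Lies in `[1/(2n), 0.25]` and is invariant under strictly
#' increasing affine transformations of the data.
#'
#' @param values Numeric readings, `n >= 4`.
#' @return The dip statistic (dimensionless).
#' @export
dip_statistic <- function(values) {
  if (length(values) < 4L || anyNA(values)) {
    stop_tbwave("dip statistic needs >= 4 non-missing values",
                class = "tbwave_insufficient_data_error")
  }
  dip_stat_cpp(as.numeric(values))
}

#' Hartigan's dip test for unimodality
#'
#' Monte-Carlo test against the uniform null (the calibration distribution
#' of the published test): `p = (1 + #\{null dips >= observed\}) /
#' (n_mc + 1)`, so `p` is never zero and the test is conservative for
#' unimodal alternatives like the normal. Deterministic given `seed`.
#'
#' @param values Numeric readings, `n >= 4`.
#' @param n_mc Null resamples (>= 100).
#' @param seed RNG seed.
#' @return List with `dip_stat`, `dip_p` and `bimodal` (`dip_p < 0.05`).
#' @export
dip_test <- function(values, n_mc = 999, seed = NULL) {
  assert_scalar_num(n_mc, "n_mc", lower = 100)
  obs <- dip_statistic(values)
  nulls <- with_seed(seed, dip_null_cpp(length(values), as.integer(n_mc)))
  p <- (1 + sum(nulls >= obs)) / (n_mc + 1)
  list(dip_stat = obs, dip_p = p, bimodal = p < 0.05)
}

#' Full distribution-shape report
#'
#' Assembles the shape descriptors for one set of readings: reading count,
#' KDE modal temperature, 10th/90th quantiles, skewness with direction
#' class, and the dip test. Sets smaller than `config$min_full_n` produce a
#' partial report: mode and quantiles when possible, `NA` for the dip test
#' and skew classification.
#'
#' @param values Numeric temperature readings.
#' @param config A [shape_config()].
#' @return An object of class `tb_shape_stats`.
#' @export
shape_report <- function(values, config = shape_config()) {
  if (length(values) == 0L) {
    stop_tbwave("`values` must be non-empty", class = "tbwave_validation_error")
  }
  n <- length(values)
  out <- list(n = n, mode_c = NA_real_, q10_c = NA_real_, q90_c = NA_real_,
              skew = NA_real_, skew_class = NA_character_,
              dip_stat = NA_real_, dip_p = NA_real_, bimodal = NA)
  out$mode_c <- kde_mode(values, config$grid_step_c)
  q <- empirical_quantile(values, c(0.1, 0.9))
  out$q10_c <- q[1]; out$q90_c <- q[2]
  if (n >= 3L && stats::sd(values) > 0) {
    out$skew <- skewness(values, config$skew_method)
  }
  if (n >= config$min_full_n) {
    dt <- dip_test(values, config$n_mc, seed = config$seed)
    out$dip_stat <- dt$dip_stat
    out$dip_p <- dt$dip_p
    out$bimodal <- dt$bimodal
    if (stats::sd(values) > 0) {
      out$skew_class <- classify_skew(values, config$n_boot,
                                      seed = config$seed)
    }
  }
  class(out) <- "tb_shape_stats"
  out
}

#' @export
print.tb_shape_stats <- function(x, ...) {
  cat(sprintf(
    "<tb_shape_stats> n=%d mode=%.2f q10=%.2f q90=%.2f skew=%.3f (%s)\n",
    x$n, x$mode_c, x$q10_c, x$q90_c,
    if (is.na(x$skew)) NA else x$skew,
    if (is.na(x$skew_class)) "?" else x$skew_class))
  if (!is.na(x$dip_stat)) {
    cat(sprintf("  dip=%.4f p=%.3f bimodal=%s\n", x$dip_stat, x$dip_p,
                x$bimodal))
  }
  invisible(x)
}
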