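#' Summarize one individual's trace
#'
#' Computes shape statistics for the active, resting and overall
#' (all readings, transitional included) distributions, plus the daily
#' amplitude: active modal temperature minus resting modal temperature.
#' Active or rest subsets smaller than `config$min_full_n` yield partial
#' shape reports; the amplitude is `NA` whenever either mode is missing.
#'
#' The amplitude is reported, not enforced, to be positive: active modes
#' are expected to exceed resting modes empirically, but nothing in the
#' method guarantees it.
#'
#' @param trace A [tb_trace()].
#' @param partition A [classify_phases()] result aligned to `trace`.
#' @param config A [shape_config()].
#' @return An object of class `tb_individual_summary` with fields
#'   `species`, `individual_id`, `active`, `rest`, `overall`
#'   (each a `tb_shape_stats`) and `amplitude_c`.
#' @export
summarize_individual <- function(trace, partition,
                                 config = shape_config()) {
  subsets <- phase_subsets(trace, partition)
  mk <- function(v) {
    if (length(v) == 0L) {
      st <- list(n = 0L, mode_c = NA_real_, q10_c = NA_real_,
                 q90_c = NA_real_, skew = NA_real_,
                 skew_class = NA_character_, dip_stat = NA_real_,
                 dip_p = NA_real_, bimodal = NA)
      class(st) <- "tb_shape_stats"
      st
    } else shape_report(v, config)
  }
  act <- mk(subsets$active)
  rst <- mk(subsets$rest)
  ovl <- mk(subsets$overall)
  amp <- if (is.na(act$mode_c) || is.na(rst$mode_c)) NA_real_ else
    act$mode_c - rst$mode_c
  structure(list(species = trace$species,
                 individual_id = trace$individual_id,
                 active = act, rest = rst, overall = ovl,
                 amplitude_c = amp),
            class = "tb_individual_summary")
}

#' @export
print.tb_individual_summary <- function(x, ...) {
  cat(sprintf("<tb_individual_summary> %s / %s\n", x$species,
              x$individual_id))
  cat(sprintf("  active mode %.2f | rest mode %.2f | amplitude %.2f degC\n",
              x$active$mode_c, x$rest$mode_c, x$amplitude_c))
  invisible(x)
}

#' Cross-individual panel summary
#'
#' Aggregates per-individual summaries into panel statistics: for each of
#' active mode, rest mode and daily amplitude, the cross-individual KDE
#' mode (same estimator as within traces), mean, sample (n - 1) standard
#' deviation and min-max range; plus counts of individuals whose overall
#' distribution is right-skewed, left-skewed or bimodal and whose active
#' distribution is right-skewed.
#'
#' When several individuals share a species label they are averaged per
#' species first if `by_species = TRUE`.
#'
#' @param summaries List of `tb_individual_summary` objects, at least two
#'   with complete active and rest modes.
#' @param by_species Average multiple individuals per species before
#'   computing panel statistics.
#' @param grid_step_c Grid step for the cross-individual KDE modes.
#' @return An object of class `tb_panel_summary`.
#' @export
summarize_panel <- function(summaries, by_species = FALSE,
                            grid_step_c = 0.01) {
  if (length(summaries) < 2L) {
    stop_tbwave("panel summary needs >= 2 individual summaries",
                class = "tbwave_validation_error")
  }
  take <- function(s, field, phase) s[[phase]][[field]]
  df <- data.frame(
    species = vapply(summaries, `[[`, "", "species"),
    active_mode = vapply(summaries, take, 0, "mode_c", "active"),
    rest_mode = vapply(summaries, take, 0, "mode_c", "rest"),
    amplitude = vapply(summaries, `[[`, 0, "amplitude_c"),
    right_overall = vapply(summaries, function(s)
      identical(take(s, "skew_class", "overall"), "right"), NA),
    left_overall = vapply(summaries, function(s)
      identical(take(s, "skew_class", "overall"), "left"), NA),
    bimodal_overall = vapply(summaries, function(s)
      isTRUE(take(s, "bimodal", "overall")), NA),
    right_active = vapply(summaries, function(s)
      identical(take(s, "skew_class", "active"), "right"), NA))
  ok <- stats::complete.cases(df[, c("active_mode", "rest_mode",
                                     "amplitude")])
  df <- df[ok, , drop = FALSE]
  if (nrow(df) < 2L) {
    stop_tbwave("fewer than 2 usable summaries (complete mode fields)",
                class = "tbwave_validation_error")
  }
  if (by_species) {
    num <- c("active_mode", "rest_mode", "amplitude")
    agg <- stats::aggregate(df[num], by = list(species = df$species), mean)
    flags <- stats::aggregate(
      df[c("right_overall", "left_overall", "bimodal_overall",
           "right_active")],
      by = list(species = df$species), function(v) mean(v) >= 0.5)
    df <- merge(agg, flags, by = "species")
  }
  metric <- function(v) {
    list(mode_c = kde_mode(v, grid_step_c), mean_c = mean(v),
         sd_c = stats::sd(v), range_c = range(v))
  }
  structure(list(
    n_individuals = nrow(df),
    active_mode = metric(df$active_mode),
    rest_mode = metric(df$rest_mode),
    amplitude = metric(df$amplitude),
    n_right_skewed_overall = sum(df$right_overall),
    n_left_skewed_overall = sum(df$left_overall),
    n_bimodal_overall = sum(df$bimodal_overall),
    n_right_skewed_active = sum(df$right_active)),
    class = "tb_panel_summary")
}

#' @export
print.tb_panel_summary <- function(x, ...) {
  cat(sprintf("<tb_panel_summary> %d individuals\n", x$n_individuals))
  f <- function(nm, m) cat(sprintf(
    "  %-12s mode %.2f mean %.2f sd %.2f range %.2f-%.2f degC\n",
    nm, m$mode_c, m$mean_c, m$sd_c, m$range_c[1], m$range_c[2]))
  f("active mode", x$active_mode)
  f("rest mode", x$rest_mode)
  f("amplitude", x$amplitude)
  cat(sprintf(
    "  overall: %d right-skewed, %d left-skewed, %d bimodal; active: %d right-skewed\n",
    x$n_right_skewed_overall, x$n_left_skewed_overall,
    x$n_bimodal_overall, x$n_right_skewed_active))
  invisible(x)
}
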