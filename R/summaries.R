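#' Per-level, per-scenario regime summaries
#'
#' Aggregates a fire-record table into per-(scenario, level) statistics:
#' mean burned area per ignition (zero-area fires count as zeros),
#' area-weighted mean CBI, area-weighted proportion of burned area at high
#' severity, and area-weighted mean absolute deviation of CBI (diversity of
#' fire effects). Zero-area fires carry no severity and are excluded from the
#' severity aggregates. Statistics are computed per replicate and then
#' averaged, with t-based 95% confidence intervals across replicates.
#'
#' @param records Fire-record tibble from [run_experiment()].
#' @return A tibble with one row per (scenario, level): `level_value`,
#'   `level_years`, per-replicate means of `mean_area`, `mean_cbi`,
#'   `prop_high_severity`, `cbi_mad`, and `*_lo` / `*_hi` 95% CI bounds (NA
#'   with a single replicate).
#' @export
summarize_levels <- function(records) {
  check_record_columns(records)
  per_rep <- records |>
    dplyr::group_by(.data$scenario, .data$level, .data$level_value,
                    .data$level_years, .data$replicate) |>
    dplyr::summarise(
      mean_area = mean(.data$final_area),
      mean_cbi = weighted_or_na(.data$mean_cbi, .data$final_area),
      prop_high_severity = weighted_or_na(.data$prop_high_severity,
                                          .data$final_area),
      cbi_mad = weighted_or_na(.data$cbi_mad, .data$final_area),
      .groups = "drop")
  per_rep |>
    dplyr::group_by(.data$scenario, .data$level, .data$level_value,
                    .data$level_years) |>
    dplyr::summarise(
      dplyr::across(c("mean_area", "mean_cbi", "prop_high_severity",
                      "cbi_mad"),
                    list(ci = ~ list(replicate_ci(.x)))),
      .groups = "drop") |>
    tidyr::unnest_wider(dplyr::ends_with("_ci"), names_sep = "_") |>
    dplyr::rename_with(~ sub("_ci_mean$", "", .x)) |>
    dplyr::rename_with(~ sub("_ci_lo$", "_lo", .x)) |>
    dplyr::rename_with(~ sub("_ci_hi$", "_hi", .x)) |>
    dplyr::select(-dplyr::ends_with("_ci_n"))
}

weighted_or_na <- function(x, w) {
  keep <- !is.na(x) & w > 0
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

check_record_columns <- function(records) {
  needed <- c("scenario", "level", "level_value", "level_years", "replicate",
              "final_area", "mean_cbi", "prop_high_severity", "cbi_mad")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0)
    stop("fire-record table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0) stop("fire-record table is empty", call. = FALSE)
  invisible(records)
}

#' Mean and 95% confidence interval over replicates
#'
#' t-based interval over per-replicate values; with a single replicate only
#' the mean is reported.
#'
#' @param x Per-replicate values.
#' @return List with `mean`, `lo`, `hi`, `n`.
#' @export
replicate_ci <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(list(mean = NA_real_, lo = NA_real_, hi = NA_real_, n = 0L))
  m <- mean(x)
  if (n < 2) return(list(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  hw <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  list(mean = m, lo = m - hw, hi = m + hw, n = n)
}

#' Multiplicative yearly growth rate of burned area
#'
#' Fits `ln(mean area)` on year-equivalents by least squares, per replicate
#' when a `replicate` column is present, and reports the average
#' multiplicative yearly rate of increase `delta = exp(slope) - 1` and the
#' doubling time `ln(2) / ln(1 + delta)` (infinite when `delta <= 0`).
#'
#' @param level_means A tibble with columns `level_years`, `mean_area`, and
#'   optionally `replicate` (e.g. a filtered [summarize_levels()] output or
#'   per-replicate level means).
#' @return An object of class `growth_fit` with elements `delta` (per yr),
#'   `doubling_time` (yr), `per_replicate` (per-replicate deltas), `n_levels`.
#' @export
growth_rate <- function(level_means) {
  stopifnot(all(c("level_years", "mean_area") %in% names(level_means)))
  if (any(level_means$mean_area <= 0, na.rm = TRUE))
    stop("`mean_area` must be positive to fit a log-linear growth rate",
         call. = FALSE)
  fit1 <- function(d) {
    if (nrow(d) < 2) stop("need >= 2 levels to fit a growth rate", call. = FALSE)
    unname(exp(stats::coef(stats::lm(log(mean_area) ~ level_years,
                                     data = d))[2]) - 1)
  }
  if ("replicate" %in% names(level_means)) {
    deltas <- level_means |>
      dplyr::group_by(.data$replicate) |>
      dplyr::group_map(~ fit1(.x)) |>
      unlist()
  } else {
    deltas <- fit1(level_means)
  }
  delta <- mean(deltas)
  structure(list(delta = delta,
                 doubling_time = if (delta > 0) log(2) / log1p(delta) else Inf,
                 per_replicate = deltas,
                 n_levels = length(unique(level_means$level_years))),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> delta = %.3f%%/yr, doubling time = %s yr (%d levels, %d replicate fit%s)\n",
              100 * x$delta,
              if (is.finite(x$doubling_time))
                format(round(x$doubling_time)) else "Inf",
              x$n_levels, length(x$per_replicate),
              if (length(x$per_replicate) == 1) "" else "s"))
  invisible(x)
}

#' @rdname growth_rate
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = c("delta", "doubling_time"),
                 estimate = c(x$delta, x$doubling_time),
                 std.error = c(if (length(x$per_replicate) > 1)
                   stats::sd(x$per_replicate) / sqrt(length(x$per_replicate))
                   else NA_real_, NA_real_))
}

#' @rdname growth_rate
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(delta = x$delta, doubling_time = x$doubling_time,
                 n_levels = x$n_levels,
                 n_replicates = length(x$per_replicate))
}

#' Generic tidiers
#'
#' Broom-style generics for fitted objects in this package.
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Lorenz curve of burned area across fires
#'
#' Fires are ranked by increasing area burned (zero-area fires included as
#' zeros); the curve gives the cumulative share of total burned area against
#' the cumulative share of fires.
#'
#' @param areas Per-fire final areas, ha (>= 0; at least one positive).
#' @return A tibble with `p_fires` (cumulative fire share) and `p_area`
#'   (cumulative area share), starting at (0, 0) and ending at (1, 1).
#' @export
lorenz_curve <- function(areas) {
  if (length(areas) == 0 || any(areas < 0) || sum(areas) <= 0)
    stop("`areas` must be non-negative with positive total", call. = FALSE)
  a <- sort(areas)
  tibble::tibble(p_fires = c(0, seq_along(a) / length(a)),
                 p_area = c(0, cumsum(a) / sum(a)))
}

#' Share of burned area in the largest fraction of fires
#'
#' @param areas Per-fire final areas, ha.
#' @param p Fraction of fires, e.g. 0.01 for the largest 1%.
#' @return Share of total burned area (fraction in [0, 1]) contributed by the
#'   largest `ceiling(p * n)` fires.
#' @export
top_share <- function(areas, p = 0.01) {
  if (length(areas) == 0 || any(areas < 0) || sum(areas) <= 0)
    stop("`areas` must be non-negative with positive total", call. = FALSE)
  stopifnot(p > 0, p <= 1)
  k <- ceiling(p * length(areas))
  sum(sort(areas, decreasing = TRUE)[seq_len(k)]) / sum(areas)
}

#' Years-equivalent of a suppression effect
#'
#' How many years of gradient change (climate change or fuel accumulation)
#' the no-suppression scenario would need to reach an observed metric value:
#' the (monotone span of the) no-suppression metric-vs-level curve is
#' inverted by piecewise-linear interpolation at `observed`, the level
#' difference from `baseline` is taken, and divided by the yearly `rate`.
#'
#' @param curve Tibble with columns `level_value` and `metric`: the
#'   no-suppression metric across the gradient.
#' @param observed Observed metric value (e.g. under a suppression scenario).
#' @param rate Yearly rate of change of the gradient variable (kPa/yr or
#'   Mg/ha/yr).
#' @param baseline Baseline level value (defaults to the smallest level).
#' @return Years of equivalent change (can be negative). A warning is issued
#'   and the nearest endpoint used if `observed` falls outside the monotone
#'   span of the curve.
#' @export
years_equivalent <- function(curve, observed, rate,
                             baseline = min(curve$level_value)) {
  stopifnot(all(c("level_value", "metric") %in% names(curve)), rate > 0)
  curve <- curve[order(curve$level_value), ]
  m <- curve$metric
  dm <- diff(m)
  if (all(dm >= 0) || all(dm <= 0)) {
    span <- seq_len(nrow(curve))
  } else {
    # restrict to the longest monotone run of the curve
    sgn <- sign(dm); sgn[sgn == 0] <- 1
    runs <- rle(sgn)
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    k <- which.max(runs$lengths)
    span <- starts[k]:(ends[k] + 1)
    warning("no-suppression metric curve is not monotone; using its longest monotone span",
            call. = FALSE)
  }
  x <- m[span]; y <- curve$level_value[span]
  if (observed < min(x) || observed > max(x))
    warning("observed metric outside the curve's range; result extrapolated to the nearest endpoint",
            call. = FALSE)
  lvl <- stats::approx(x, y, xout = observed, rule = 2, ties = mean)$y
  (lvl - baseline) / rate
}
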