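#' Define a suppression scenario
#'
#' A scenario couples an initial-attack engagement delay with a daily
#' containment-response curve mapping local fireline intensity to the
#' proportion of spread suppressed. Regressive curves suppress low-intensity
#' fire most; the progressive curve suppresses higher-intensity fire most.
#' Every curve drops to zero at intensities at or above `impossible_above`,
#' where suppression is taken to be impossible.
#'
#' @param name One of `"none"`, `"moderate"`, `"high"`, `"maximum"`,
#'   `"progressive"`.
#' @param engagement_delay Hours after spread start at which initial attack
#'   engages, or `NA` for scenarios without initial attack (`none`,
#'   `progressive`).
#' @param ceiling Maximum proportion of spread suppressed, in [0, 1].
#' @param mid Log10 fireline intensity (kW/m) at the curve midpoint.
#' @param slope Logistic steepness per log10 intensity unit.
#' @param direction `"regressive"` (non-increasing in intensity),
#'   `"progressive"` (non-decreasing up to the impossibility cutoff), or
#'   `"none"`.
#' @param impossible_above Fireline intensity (kW/m) above which suppression
#'   is impossible (default 10000).
#' @return A list of class `suppression_scenario`.
#' @export
suppression_scenario <- function(name, engagement_delay = NA,
                                 ceiling = 0, mid = 3, slope = 3,
                                 direction = c("regressive", "progressive", "none"),
                                 impossible_above = 10000) {
  direction <- match.arg(direction)
  stopifnot(ceiling >= 0, ceiling <= 1, impossible_above > 0)
  structure(list(name = name, engagement_delay = engagement_delay,
                 ceiling = ceiling, mid = mid, slope = slope,
                 direction = direction, impossible_above = impossible_above),
            class = "suppression_scenario")
}

#' The five study suppression scenarios
#'
#' `none` (control, no suppression), three regressive scenarios with
#' increasing aggressiveness and decreasing engagement delay (`moderate` 4 h,
#' `high` 2 h, `maximum` 1 h), and `progressive` (no initial attack; daily
#' containment that targets higher-intensity fire). Containment curves are
#' logistic in log10 fireline intensity and pointwise ordered
#' maximum >= high >= moderate; all drop to zero above `impossible_above`.
#'
#' @param impossible_above Intensity (kW/m) above which suppression is
#'   impossible for every scenario.
#' @return Named list of [suppression_scenario()] objects.
#' @export
default_scenarios <- function(impossible_above = 10000) {
  list(
    none = suppression_scenario("none", NA, ceiling = 0, direction = "none",
                                impossible_above = impossible_above),
    moderate = suppression_scenario("moderate", 4, ceiling = 0.97,
                                    mid = 3.15, slope = 3.6,
                                    direction = "regressive",
                                    impossible_above = impossible_above),
    high = suppression_scenario("high", 2, ceiling = 0.975,
                                mid = 3.35, slope = 3.6,
                                direction = "regressive",
                                impossible_above = impossible_above),
    maximum = suppression_scenario("maximum", 1, ceiling = 0.98,
                                   mid = 3.55, slope = 3.6,
                                   direction = "regressive",
                                   impossible_above = impossible_above),
    progressive = suppression_scenario("progressive", NA, ceiling = 0.95,
                                       mid = 3.2, slope = 3.0,
                                       direction = "progressive",
                                       impossible_above = impossible_above)
  )
}

#' Proportion of spread suppressed at a given fireline intensity
#'
#' The daily containment curve of a scenario, evaluated at local fireline
#' intensity. Regressive curves are non-increasing in intensity; the
#' progressive curve is non-decreasing up to the impossibility cutoff; the
#' `none` scenario suppresses nothing; all curves are zero at or above
#' `impossible_above`.
#'
#' @param intensity Fireline intensity, kW/m (>= 0); vectorized.
#' @param scenario A [suppression_scenario()].
#' @return Proportion of spread suppressed, in [0, 1].
#' @export
containment_fraction <- function(intensity, scenario) {
  if (!inherits(scenario, "suppression_scenario"))
    stop("`scenario` must be a suppression_scenario", call. = FALSE)
  if (any(intensity < 0)) stop("`intensity` must be >= 0", call. = FALSE)
  x <- log10(pmax(intensity, 1e-12))
  frac <- switch(scenario$direction,
    none = rep(0, length(intensity)),
    regressive = scenario$ceiling *
      stats::plogis(scenario$slope * (scenario$mid - x)),
    progressive = scenario$ceiling *
      stats::plogis(scenario$slope * (x - scenario$mid))
  )
  frac[intensity >= scenario$impossible_above] <- 0
  frac
}

#' Initial-attack containment probability
#'
#' Probability that initial attack fully contains a fire, as a logistic in
#' log heading fireline intensity and log fire size at the time of
#' engagement (the form of empirical escape models such as Hirsch and
#' colleagues'): non-increasing in both, approaching zero for very intense
#' fires.
#'
#' @param intensity Heading fireline intensity at engagement, kW/m (>= 0).
#' @param size_ha Fire size at engagement, ha (>= 0).
#' @param coef Named numeric vector `c(b0, b_intensity, b_size)` of the
#'   logistic: `plogis(b0 - b_intensity * log(1 + I) - b_size * log(1 + A))`.
#' @return Containment probability in [0, 1].
#' @export
initial_attack_probability <- function(intensity, size_ha,
                                       coef = c(b0 = 25.2, b_intensity = 3.1,
                                                b_size = 1.5)) {
  if (any(intensity < 0) || any(size_ha < 0))
    stop("`intensity` and `size_ha` must be >= 0", call. = FALSE)
  stats::plogis(coef[["b0"]] - coef[["b_intensity"]] * log1p(intensity) -
                  coef[["b_size"]] * log1p(size_ha))
}

#' Attempt initial attack on a newly spreading fire
#'
#' Grows the day-one ellipse for the scenario's engagement delay at day-one
#' spread rates, evaluates the containment probability at the resulting size
#' and heading intensity, and compares it with a uniform draw. Only valid for
#' regressive scenarios, which have an engagement delay.
#'
#' @param ros Day-one heading spread rate, m/min.
#' @param intensity Day-one heading fireline intensity, kW/m.
#' @param lb Day-one ellipse length-to-breadth ratio.
#' @param scenario A regressive [suppression_scenario()].
#' @param u Uniform(0,1) draw deciding containment (one per ignition so that
#'   scenario contrasts stay paired); drawn internally if missing.
#' @param ia_coef Coefficients for [initial_attack_probability()].
#' @param n_angles Angular resolution for the engagement-size ellipse.
#' @return List: `contained` (logical), `size_ha` (size at engagement),
#'   `prob` (containment probability).
#' @export
attempt_initial_attack <- function(ros, intensity, lb, scenario,
                                   u = stats::runif(1),
                                   ia_coef = c(b0 = 25.2, b_intensity = 3.1,
                                               b_size = 1.5),
                                   n_angles = 360) {
  if (!inherits(scenario, "suppression_scenario") ||
      is.na(scenario$engagement_delay))
    stop("initial attack applies only to scenarios with an engagement delay",
         call. = FALSE)
  g <- ellipse_factors(lb, angle_grid(n_angles))
  head_dist <- ros * scenario$engagement_delay * 60
  size <- polar_area(head_dist * g)
  p <- initial_attack_probability(intensity, size, ia_coef)
  list(contained = u < p, size_ha = size, prob = p)
}

#' Apply daily suppression to per-angle spread increments
#'
#' Multiplies each angular bin's unsuppressed daily spread increment by the
#' proportion of fire remaining after suppression at that bin's local
#' fireline intensity.
#'
#' @param increments Unsuppressed per-angle daily spread distances, m (>= 0).
#' @param local_intensity Per-angle fireline intensity, kW/m.
#' @param scenario A [suppression_scenario()].
#' @return Suppressed per-angle spread distances, m.
#' @export
apply_suppression <- function(increments, local_intensity, scenario) {
  if (any(increments < 0)) stop("`increments` must be >= 0", call. = FALSE)
  increments * (1 - containment_fraction(local_intensity, scenario))
}
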