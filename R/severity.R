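#' Flame-length to burn-severity mapping
#'
#' Parameters of the two monotone maps linking fire behavior to ecological
#' severity: a logistic flame-length to tree-mortality curve (rescaled so
#' zero flame length gives zero mortality), and a power map from mortality to
#' Composite Burn Index (CBI), `CBI = 3 * mortality^gamma`, clipped to
#' [0, 3]. CBI at or above `high_severity_threshold` is classified high
#' severity.
#'
#' @param fl_mid Flame length (m) at the mortality-curve midpoint.
#' @param fl_scale Logistic scale of the mortality curve (m).
#' @param gamma Exponent of the mortality-to-CBI power map.
#' @param high_severity_threshold CBI threshold for high severity
#'   (default 2.25).
#' @return A list of class `severity_mapping`.
#' @export
severity_mapping <- function(fl_mid = 0.9, fl_scale = 0.55, gamma = 0.40,
                             high_severity_threshold = 2.25) {
  stopifnot(fl_scale > 0, gamma > 0,
            high_severity_threshold >= 0, high_severity_threshold <= 3)
  structure(list(fl_mid = fl_mid, fl_scale = fl_scale, gamma = gamma,
                 high_severity_threshold = high_severity_threshold),
            class = "severity_mapping")
}

#' Flame length to tree mortality
#'
#' Logistic in flame length, rescaled so that mortality is exactly 0 at zero
#' flame length and approaches 1 for tall flames; monotone non-decreasing.
#'
#' @param flame_length Flame length, m (>= 0).
#' @param mapping A [severity_mapping()].
#' @return Mortality fraction in [0, 1].
#' @export
flame_length_to_mortality <- function(flame_length, mapping = severity_mapping()) {
  if (any(flame_length < 0)) stop("`flame_length` must be >= 0", call. = FALSE)
  l0 <- stats::plogis(-mapping$fl_mid / mapping$fl_scale)
  l <- stats::plogis((flame_length - mapping$fl_mid) / mapping$fl_scale)
  pmax((l - l0) / (1 - l0), 0)
}

#' Flame length to Composite Burn Index
#'
#' Composition of the flame-length-to-mortality and mortality-to-CBI maps:
#' zero flame length maps to CBI 0 (unburned) and complete mortality maps to
#' CBI 3 (maximum severity).
#'
#' @inheritParams flame_length_to_mortality
#' @return CBI in [0, 3].
#' @export
flame_length_to_cbi <- function(flame_length, mapping = severity_mapping()) {
  mort <- flame_length_to_mortality(flame_length, mapping)
  pmin(pmax(3 * mort^mapping$gamma, 0), 3)
}

#' Invert the severity mapping
#'
#' Flame length at which the mapping reaches a given CBI; used to document
#' the high-severity anchor and in calibration checks.
#'
#' @param cbi CBI value in [0, 3).
#' @param mapping A [severity_mapping()].
#' @return Flame length, m.
#' @export
cbi_to_flame_length <- function(cbi, mapping = severity_mapping()) {
  stopifnot(all(cbi >= 0), all(cbi < 3))
  mort <- (cbi / 3)^(1 / mapping$gamma)
  l0 <- stats::plogis(-mapping$fl_mid / mapping$fl_scale)
  l <- mort * (1 - l0) + l0
  mapping$fl_mid + mapping$fl_scale * stats::qlogis(l)
}

#' High-severity classification
#'
#' @param cbi CBI values in [0, 3].
#' @param threshold CBI threshold, inclusive (default 2.25).
#' @return Logical vector: `cbi >= threshold`.
#' @export
is_high_severity <- function(cbi, threshold = 2.25) {
  stopifnot(all(cbi >= 0 & cbi <= 3))
  cbi >= threshold
}
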