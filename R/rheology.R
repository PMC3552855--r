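#' @title Channel-size blood rheology: Pries in vitro relations
#' @description
#' In conduits below a few hundred micrometres, red cells migrate away from
#' the walls. Two consequences matter for microfluidic flow assays run on
#' whole blood: the tube hematocrit falls below the feed (discharge)
#' hematocrit (Fahraeus effect), and the apparent viscosity falls with tube
#' diameter (Fahraeus-Lindqvist effect). Both are described empirically by
#' the Pries in vitro correlations, parameterized by tube diameter D (µm)
#' and discharge hematocrit H_D (fraction).
#' @name pries-rheology
NULL

.check_rheology <- function(diameter, hematocrit) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0))
    stop("tube diameter must be positive (um)", call. = FALSE)
  if (!is.numeric(hematocrit) || any(!is.finite(hematocrit)) ||
      any(hematocrit <= 0) || any(hematocrit >= 1))
    stop("discharge hematocrit must lie in (0, 1)", call. = FALSE)
  invisible(NULL)
}

#' Fahraeus effect: tube-to-discharge hematocrit ratio
#'
#' Pries in vitro relation
#' \deqn{H_T/H_D = H_D + (1 - H_D)(1 + 1.7 e^{-0.415 D} - 0.6 e^{-0.011 D})}
#' with D in micrometres. For a 50 µm channel at a normal discharge
#' hematocrit of 0.45 the ratio is about 0.81, i.e. the tube hematocrit is
#' roughly 80% of the feed value.
#'
#' @param diameter Tube (or channel) diameter D in µm; vectorized.
#' @param hematocrit Discharge hematocrit H_D as a fraction in (0, 1).
#' @return The ratio H_T/H_D, in (0, 1].
#' @examples
#' fahraeus_tube_hematocrit_ratio(50, 0.45)
#' @export
fahraeus_tube_hematocrit_ratio <- function(diameter, hematocrit) {
  .check_rheology(diameter, hematocrit)
  hematocrit + (1 - hematocrit) *
    (1 + 1.7 * exp(-0.415 * diameter) - 0.6 * exp(-0.011 * diameter))
}

#' Fahraeus-Lindqvist effect: relative apparent viscosity
#'
#' Pries in vitro correlation for the apparent viscosity of blood relative to
#' the suspending medium, as a function of tube diameter D (µm) and discharge
#' hematocrit H_D:
#' \deqn{\eta_{rel} = 1 + (\eta^{*}_{0.45} - 1)
#'   \frac{(1 - H_D)^C - 1}{(1 - 0.45)^C - 1}}
#' where
#' \deqn{\eta^{*}_{0.45} = 220 e^{-1.3 D} + 3.2 - 2.44 e^{-0.06 D^{0.645}}}
#' is the relative viscosity at H_D = 0.45 and the shape exponent is
#' \deqn{C = (0.8 + e^{-0.075 D}) \left(-1 + \frac{1}{1 + 10^{-11} D^{12}}\right)
#'   + \frac{1}{1 + 10^{-11} D^{12}}.}
#'
#' @inheritParams fahraeus_tube_hematocrit_ratio
#' @return Relative apparent viscosity (dimensionless, >= 1); increasing in
#'   hematocrit at fixed diameter and increasing in diameter over 10-1000 µm
#'   at normal hematocrit.
#' @examples
#' relative_apparent_viscosity(50, 0.45)
#' relative_apparent_viscosity(1000, 0.5) # large-tube value
#' @export
relative_apparent_viscosity <- function(diameter, hematocrit) {
  .check_rheology(diameter, hematocrit)
  eta45 <- 220 * exp(-1.3 * diameter) + 3.2 -
    2.44 * exp(-0.06 * diameter^0.645)
  s <- 1 / (1 + 1e-11 * diameter^12)
  C <- (0.8 + exp(-0.075 * diameter)) * (-1 + s) + s
  1 + (eta45 - 1) * ((1 - hematocrit)^C - 1) / ((1 - 0.45)^C - 1)
}
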