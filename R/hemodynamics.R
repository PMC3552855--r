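#' Rectangular microchannel geometry
#'
#' Describes the cross-section of a rectangular flow-assay channel and its
#' derived quantities. The convention follows flow-assay practice: channels
#' are wider than tall (`w >= h`), the aspect ratio `epsilon = w/h >= 1`, and
#' the duct-flow correlations use `alpha = h/w <= 1`.
#'
#' @param height Channel height h in micrometres (the short dimension).
#' @param width Channel width w in micrometres; must satisfy `width >= height`.
#'
#' @return An object of class `channel_geometry`: a list with fields
#'   `height`, `width` (µm), `aspect_ratio` (w/h), `alpha` (h/w),
#'   `area` (µm^2) and `hydraulic_diameter` (µm, `2wh/(w+h)`).
#'
#' @examples
#' geom <- channel_geometry(height = 50, width = 500)
#' geom$hydraulic_diameter
#' @export
channel_geometry <- function(height, width) {
  stopifnot(is.numeric(height), is.numeric(width),
            length(height) == 1L, length(width) == 1L)
  if (!is.finite(height) || height <= 0)
    stop("channel height must be a positive finite number (um)", call. = FALSE)
  if (!is.finite(width) || width < height)
    stop("channel width must be finite and >= height", call. = FALSE)
  structure(
    list(
      height = height,
      width = width,
      aspect_ratio = width / height,
      alpha = height / width,
      area = width * height,
      hydraulic_diameter = 2 * width * height / (width + height)
    ),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "Rectangular channel: h = %g um, w = %g um (aspect ratio %g)\n",
    x$height, x$width, x$aspect_ratio))
  cat(sprintf("  cross-section A = %g um^2, hydraulic diameter D_h = %.4g um\n",
              x$area, x$hydraulic_diameter))
  invisible(x)
}

#' Friction factor-Reynolds number product for a rectangular duct
#'
#' Fully developed laminar flow in a rectangular duct has a geometry-only
#' product of Fanning friction factor and Reynolds number. This uses the
#' Shah-London fifth-order polynomial in the height-to-width ratio
#' `alpha = h/w`:
#' \deqn{fRe = 24 (1 - 1.3553\alpha + 1.9467\alpha^2 - 1.7012\alpha^3
#'   + 0.9564\alpha^4 - 0.2537\alpha^5)}
#' It recovers the infinite-parallel-plate value 24 as `alpha -> 0` and the
#' square-duct value (about 14.23) at `alpha = 1`.
#'
#' @param alpha Height-to-width ratio h/w, in (0, 1]. Vectorized.
#' @return f*Re (dimensionless), monotone decreasing in `alpha`.
#' @examples
#' friction_factor_re(0.1)   # the 500 x 50 um flow-assay channel
#' friction_factor_re(1)     # square duct, ~14.23
#' @export
friction_factor_re <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) == 0L || any(!is.finite(alpha)))
    stop("alpha must be finite numeric", call. = FALSE)
  if (any(alpha <= 0 | alpha > 1))
    stop("alpha must lie in (0, 1]", call. = FALSE)
  24 * (1 - 1.3553 * alpha + 1.9467 * alpha^2 - 1.7012 * alpha^3 +
          0.9564 * alpha^4 - 0.2537 * alpha^5)
}

# uL/min -> um^3/s
.q_ul_min_to_um3_s <- function(q) q * 1e9 / 60
.q_um3_s_to_ul_min <- function(q) q * 60 / 1e9

#' Wall shear rate from volumetric flow rate
#'
#' Converts a volumetric flow rate to the wall shear rate at the long wall of
#' a rectangular microchannel,
#' \deqn{\gamma_w = \frac{fRe}{2} \frac{Q}{A D_h}}
#' with the Fanning `fRe` from [friction_factor_re()]. For wide channels
#' (aspect ratio >= 10) this is within a few percent of the parallel-plate
#' formula `6Q/(w h^2)`.
#'
#' @param flow_rate Volumetric flow rate Q in µL/min (vectorized, >= 0).
#' @param geom A [channel_geometry()].
#' @return Wall shear rate in 1/s.
#' @examples
#' geom <- channel_geometry(50, 500)
#' wall_shear_rate(2, geom)
#' @export
wall_shear_rate <- function(flow_rate, geom) {
  if (!inherits(geom, "channel_geometry"))
    stop("geom must be a channel_geometry", call. = FALSE)
  if (!is.numeric(flow_rate) || any(!is.finite(flow_rate)) || any(flow_rate < 0))
    stop("flow_rate must be nonnegative (uL/min)", call. = FALSE)
  q <- .q_ul_min_to_um3_s(flow_rate)
  fre <- friction_factor_re(geom$alpha)
  (fre / 2) * q / (geom$area * geom$hydraulic_diameter)
}

#' Volumetric flow rate needed for a target wall shear rate
#'
#' Exact inverse of [wall_shear_rate()] (the relation is linear in Q).
#'
#' @param shear_rate Target wall shear rate in 1/s (vectorized, >= 0).
#' @param geom A [channel_geometry()].
#' @return Flow rate in µL/min.
#' @examples
#' geom <- channel_geometry(50, 500)
#' flow_rate_for_shear(c(150, 300, 750, 1500), geom)
#' @export
flow_rate_for_shear <- function(shear_rate, geom) {
  if (!inherits(geom, "channel_geometry"))
    stop("geom must be a channel_geometry", call. = FALSE)
  if (!is.numeric(shear_rate) || any(!is.finite(shear_rate)) || any(shear_rate < 0))
    stop("shear_rate must be nonnegative (1/s)", call. = FALSE)
  fre <- friction_factor_re(geom$alpha)
  q <- shear_rate * geom$area * geom$hydraulic_diameter * 2 / fre
  .q_um3_s_to_ul_min(q)
}

#' Flow-rate ratios of a multi-syringe withdrawal bank
#'
#' A bank of syringes with equal stroke length mounted on one pump is driven
#' at a common plunger speed, so each syringe's flow rate is proportional to
#' its cross-sectional area, i.e. to its nominal volume. This is how a single
#' pump runs four channels at shear rates 150/300/750/1500 1/s using
#' 50/100/250/500 µL syringes (flow ratio 1:2:5:10).
#'
#' @param volumes Nominal syringe volumes (µL), all positive.
#' @return Flow-rate ratios normalized so the smallest syringe is 1.
#' @examples
#' syringe_bank_flow_ratios(c(50, 100, 250, 500))
#' @export
syringe_bank_flow_ratios <- function(volumes) {
  if (!is.numeric(volumes) || length(volumes) == 0L)
    stop("volumes must be a nonempty numeric vector", call. = FALSE)
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("all syringe volumes must be positive", call. = FALSE)
  volumes / min(volumes)
}
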