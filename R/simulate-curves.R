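#' Parameters of the platelet-deposition simulator
#'
#' The simulator is a two-phase phenomenological model of platelet
#' accumulation on collagen, designed to reproduce the statistical structure
#' of flow-assay data (shear-dependent lag, nucleation-and-growth coverage
#' kinetics, VWF coupling), not transport physics.
#'
#' Phase 1 is a surface-conditioning lag: no stable adhesion until plasma
#' proteins (chiefly VWF) have adsorbed to the collagen. Its mean is
#' \deqn{\tau(\gamma) = \tau_0 + \Delta\tau \,
#'   \mathrm{logistic}((\gamma - \gamma_{1/2}) / w) \cdot (VWF/VWF_{ref})^{-a}}
#' so lag rises steeply between venous (150-300 1/s) and arterial
#' (750-1500 1/s) shear and shortens with plasma VWF. The realized lag is a
#' gamma draw around this mean (replicate CV `lag_cv`). Plasma-pretreatment
#' mode (collagen pre-incubated with plasma) multiplies the mean lag by
#' `pretreat_tau_factor`.
#'
#' Phase 2 is nucleation and growth: adhesion events arrive as a Poisson
#' process with rate
#' \deqn{\lambda = \lambda_0(\gamma) (VWF/VWF_{ref})^{b} \cdot m_{GP6}
#'   \cdot m_{ac} \cdot m_{low}}
#' and each event seeds an aggregate that grows laterally at
#' `growth(gamma)` µm/s from one platelet radius up to `max_radius_um`.
#' Coverage is the Boolean-model union of the discs. The per-shear
#' `rate0`/`growth` tables are calibrated so that, at reference VWF, mean
#' end-point coverage is about 11.6 / 13.0 / 4.9 / 2.7 % and mean lag about
#' 47 / 58 / 153 / 195 s at 150 / 300 / 750 / 1500 1/s; values at other
#' shear rates are interpolated in log shear.
#'
#' @param shear_grid Wall shear rates (1/s) anchoring the calibration table.
#' @param rate0 Nucleation rates at `shear_grid`, events/s over the reference
#'   field (512 px at 0.3225 µm/px) at reference VWF; scaled in proportion to
#'   field area for other field sizes.
#' @param growth Lateral aggregate growth rates at `shear_grid`, µm/s.
#' @param tau_base,tau_gain,tau_mid,tau_width Lag model: baseline (s), rise
#'   (s), logistic midpoint (1/s) and width (1/s).
#' @param lag_cv Replicate coefficient of variation of the lag draw.
#' @param lag_vwf_exponent Exponent `a` of the VWF shortening of the lag.
#' @param vwf_ref Reference VWF level, IU/dL.
#' @param vwf_exponent Exponent `b` of the VWF scaling of nucleation.
#' @param gp6_ag_mult Nucleation multiplier for the GP6 AG genotype.
#' @param anticoag_cti_mult Multiplier for CTI-only anticoagulation
#'   (citrate+CTI is the reference, 1).
#' @param low_binder_mult Multiplier for latent low-binder donors.
#' @param pretreat_tau_factor Lag multiplier under plasma pretreatment.
#' @param platelet_radius_um,max_radius_um Initial and maximal aggregate
#'   radii, µm.
#' @param field_px,pixel_size Simulated field width/height (pixels) and
#'   pixel size (µm/px).
#' @param n_frames,frame_interval Frames per run and sampling interval (s);
#'   defaults give a 5-minute assay sampled every 7 s (43 frames).
#' @return A list of class `deposition_params`.
#' @export
deposition_params <- function(
    shear_grid = c(150, 300, 750, 1500),
    rate0 = c(0.48, 0.52, 0.40, 0.35),
    growth = c(0.0125, 0.014, 0.0185, 0.023),
    tau_base = 40, tau_gain = 155, tau_mid = 600, tau_width = 150,
    lag_cv = 0.2, lag_vwf_exponent = 0.5,
    vwf_ref = 87.9, vwf_exponent = 1.0,
    gp6_ag_mult = 0.7, anticoag_cti_mult = 2.0, low_binder_mult = 0.05,
    pretreat_tau_factor = 0.25,
    platelet_radius_um = 1.25, max_radius_um = 12,
    field_px = 512, pixel_size = 0.3225,
    n_frames = 43, frame_interval = 7) {
  if (any(rate0 < 0) || any(growth < 0) || tau_base < 0 || tau_gain < 0 ||
      lag_cv < 0 || gp6_ag_mult < 0 || anticoag_cti_mult < 0 ||
      low_binder_mult < 0)
    stop("all rates and multipliers must be nonnegative", call. = FALSE)
  stopifnot(length(shear_grid) == length(rate0),
            length(shear_grid) == length(growth),
            n_frames >= 1, frame_interval > 0, field_px >= 8,
            platelet_radius_um > 0, max_radius_um >= platelet_radius_um)
  structure(as.list(environment()), class = "deposition_params")
}

.interp_shear <- function(shear, grid, values) {
  if (length(grid) == 1L) return(values)
  stats::approx(log(grid), values, xout = log(shear), rule = 2)$y
}

#' Mean surface-conditioning lag at a given shear rate
#'
#' @param shear_rate Wall shear rate, 1/s.
#' @param params A [deposition_params()].
#' @return Mean lag in seconds at reference VWF.
#' @export
mean_lag_at_shear <- function(shear_rate, params = deposition_params()) {
  params$tau_base + params$tau_gain *
    plogis((shear_rate - params$tau_mid) / params$tau_width)
}

.donor_field <- function(donor, field, default) {
  v <- donor[[field]]
  if (is.null(v) || length(v) == 0L || is.na(v)) default else v[[1]]
}

#' Simulate one ground-truth platelet-accumulation curve
#'
#' Draws a surface-conditioning lag, then Poisson nucleation events with
#' uniformly random positions, each growing laterally; the coverage curve is
#' the Boolean-model overlap-corrected coverage
#' `SC(t) = 100 (1 - exp(-sum_i pi r_i(t)^2 / A))`, which is monotone
#' nondecreasing (aggregates never embolize in this model). The event list
#' (times, positions, growth) is returned so the same realization can be
#' rendered into an image stack by [render_stack()].
#'
#' @param donor One donor: a one-row data frame from [sample_cohort()] or a
#'   list with (any of) `vwf_level`, `gp6_genotype`, `anticoagulant`,
#'   `low_binder_latent`, `donor_id`. Missing fields default to the
#'   reference donor.
#' @param shear_rate Wall shear rate, 1/s (> 0).
#' @param params A [deposition_params()].
#' @param pretreatment Plasma-pretreatment mode: collagen pre-exposed to
#'   plasma, shortening the adsorption lag.
#' @param seed Optional integer seed.
#' @return An `sc_simulation`: list with `ts` (the ground-truth
#'   [sc_timeseries()]), `events` (tibble `t0_s`, `x_um`, `y_um`,
#'   `growth_um_s`), `lag_s`, `rate_events_s`, `shear_rate`, `params`.
#' @examples
#' sim <- simulate_sc_curve(list(vwf_level = 90), 300, seed = 1)
#' tail(sim$ts$sc_percent, 1)
#' @export
simulate_sc_curve <- function(donor, shear_rate,
                              params = deposition_params(),
                              pretreatment = FALSE, seed = NULL) {
  stopifnot(inherits(params, "deposition_params"))
  if (!is.numeric(shear_rate) || length(shear_rate) != 1L || shear_rate <= 0)
    stop("shear_rate must be a single positive value (1/s)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vwf <- .donor_field(donor, "vwf_level", params$vwf_ref)
  if (!is.finite(vwf) || vwf <= 0)
    stop("donor VWF level must be positive", call. = FALSE)
  gp6 <- .donor_field(donor, "gp6_genotype", "AA")
  ac <- .donor_field(donor, "anticoagulant", "citrate_cti")
  low <- isTRUE(.donor_field(donor, "low_binder_latent", FALSE))

  tau <- mean_lag_at_shear(shear_rate, params) *
    (vwf / params$vwf_ref)^(-params$lag_vwf_exponent)
  if (pretreatment) tau <- tau * params$pretreat_tau_factor
  lag <- if (params$lag_cv > 0) {
    shape <- 1 / params$lag_cv^2
    rgamma(1, shape = shape, scale = tau / shape)
  } else tau

  # rate0 is calibrated for the reference field (512 px at 0.3225 um/px);
  # nucleation is per unit area, so scale to the simulated field
  field_um <- params$field_px * params$pixel_size
  area_scale <- field_um^2 / (512 * 0.3225)^2
  rate <- area_scale *
    .interp_shear(shear_rate, params$shear_grid, params$rate0) *
    (vwf / params$vwf_ref)^params$vwf_exponent *
    (if (identical(gp6, "AG")) params$gp6_ag_mult else 1) *
    (if (identical(ac, "cti")) params$anticoag_cti_mult else 1) *
    (if (low) params$low_binder_mult else 1)
  g <- .interp_shear(shear_rate, params$shear_grid, params$growth)

  duration <- (params$n_frames - 1L) * params$frame_interval
  n_ev <- if (lag < duration) rpois(1, rate * (duration - lag)) else 0L
  events <- tibble::new_tibble(list(
    t0_s = sort(runif(n_ev, lag, duration)),
    x_um = runif(n_ev, 0, field_um),
    y_um = runif(n_ev, 0, field_um),
    growth_um_s = rep(g, n_ev)), nrow = as.integer(n_ev))

  times <- (seq_len(params$n_frames) - 1L) * params$frame_interval
  area <- field_um^2
  sc <- vapply(times, function(t) {
    act <- events$t0_s <= t
    if (!any(act)) return(0)
    r <- pmin(params$platelet_radius_um +
                events$growth_um_s[act] * (t - events$t0_s[act]),
              params$max_radius_um)
    100 * (1 - exp(-sum(pi * r^2) / area))
  }, numeric(1))

  ts <- sc_timeseries(times, sc, frame_interval = params$frame_interval,
                      metadata = list(
                        shear_rate = shear_rate,
                        donor_id = .donor_field(donor, "donor_id", NA),
                        pretreatment = pretreatment,
                        seed = seed))
  structure(list(ts = ts, events = events, lag_s = lag,
                 rate_events_s = rate, shear_rate = shear_rate,
                 pretreatment = pretreatment, params = params),
            class = "sc_simulation")
}

#' Simulate a full cohort of flow-assay runs
#'
#' Runs [simulate_sc_curve()] for every donor at every requested shear rate
#' and reduces each curve with [compute_metrics()], producing the per-donor,
#' per-shear table the cohort association stage consumes.
#'
#' @param cohort A tibble from [sample_cohort()].
#' @param shear_rates Wall shear rates, 1/s.
#' @param params A [deposition_params()].
#' @param pretreatment Passed to [simulate_sc_curve()].
#' @param seed Optional integer seed for the whole batch.
#' @return A tibble (one row per donor x shear) with the donor covariates
#'   plus `shear_rate`, `sc_end`, `lag_time_s`, `v_plt_pct_per_s`,
#'   `reached_1pct`.
#' @export
simulate_cohort_runs <- function(cohort,
                                 shear_rates = c(150, 300, 750, 1500),
                                 params = deposition_params(),
                                 pretreatment = FALSE, seed = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(row = seq_len(nrow(cohort)), shear_rate = shear_rates)
  nr <- nrow(grid)
  sc_end <- lagv <- vplt <- numeric(nr)
  reached <- logical(nr)
  for (k in seq_len(nr)) {
    donor <- cohort[grid$row[k], ]
    sim <- simulate_sc_curve(donor, grid$shear_rate[k], params = params,
                             pretreatment = pretreatment)
    m <- compute_metrics(sim$ts)
    sc_end[k] <- m$sc_end; lagv[k] <- m$lag_time_s
    vplt[k] <- m$v_plt_pct_per_s; reached[k] <- m$reached_1pct
  }
  dplyr::bind_cols(
    cohort[grid$row, , drop = FALSE],
    tibble::new_tibble(list(shear_rate = grid$shear_rate, sc_end = sc_end,
                            lag_time_s = lagv, v_plt_pct_per_s = vplt,
                            reached_1pct = reached), nrow = nr))
}
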