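#' Imaging model parameters
#'
#' Parameters of the synthetic epifluorescence renderer. The defaults mimic
#' flow-assay movies of fluorescently labeled platelets: a uniform
#' background haze from labeled platelets flowing through the field, a
#' diffraction-scale point-spread function (sigma ~0.23 µm at 0.3225 µm/px),
#' Poisson photon noise on the total signal, and additive Gaussian camera
#' read noise, quantized to 8 bits.
#'
#' @param background Mean background haze, intensity units (8-bit scale).
#' @param amplitude Platelet signal above background, intensity units.
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels.
#' @param read_noise_sd Camera read noise SD, intensity units.
#' @return A list of class `imaging_params`.
#' @export
imaging_params <- function(background = 30, amplitude = 85,
                           psf_sigma_px = 0.7, read_noise_sd = 5) {
  stopifnot(background >= 0, amplitude >= 0, psf_sigma_px >= 0,
            read_noise_sd >= 0)
  structure(list(background = background, amplitude = amplitude,
                 psf_sigma_px = psf_sigma_px, read_noise_sd = read_noise_sd),
            class = "imaging_params")
}

# rasterize the union of event discs at time t onto an n x n logical field
.rasterize_events <- function(events, t, t_radius_um, field_px, pixel_size) {
  mask <- matrix(FALSE, field_px, field_px)
  act <- which(events$t0_s <= t)
  for (k in act) {
    r_px <- t_radius_um[k] / pixel_size
    cx <- events$x_um[k] / pixel_size + 0.5
    cy <- events$y_um[k] / pixel_size + 0.5
    i0 <- max(1L, floor(cy - r_px)); i1 <- min(field_px, ceiling(cy + r_px))
    j0 <- max(1L, floor(cx - r_px)); j1 <- min(field_px, ceiling(cx + r_px))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    dy2 <- (ii - cy)^2
    dx2 <- (jj - cx)^2
    mask[ii, jj] <- mask[ii, jj] | outer(dy2, dx2, `+`) <= r_px^2
  }
  mask
}

#' Render a simulated run into a noisy image stack with ground truth
#'
#' Rasterizes the aggregate discs of an [simulate_sc_curve()] realization
#' frame by frame (these unions are the ground-truth masks), convolves the
#' platelet signal with a Gaussian PSF, adds the background haze, applies
#' Poisson photon noise and Gaussian read noise, and quantizes to 8 bits.
#' Deterministic for a fixed seed.
#'
#' Note the ground-truth mask coverage is the realized union of the placed
#' discs; it fluctuates around the overlap-corrected curve in
#' `sim$ts` by the placement randomness of a finite number of aggregates.
#'
#' @param sim An `sc_simulation` from [simulate_sc_curve()].
#' @param imaging An [imaging_params()].
#' @param seed Optional integer seed for the noise.
#' @return A `rendered_run`: list with `stack` (an [image_stack()]),
#'   `truth_masks` (list of H x W logical matrices), and `truth_sc`
#'   (percent coverage of each truth mask).
#' @export
render_stack <- function(sim, imaging = imaging_params(), seed = NULL) {
  stopifnot(inherits(sim, "sc_simulation"), inherits(imaging, "imaging_params"))
  p <- sim$params
  if (p$field_px * p$pixel_size < 2 * p$platelet_radius_um)
    stop("field smaller than a single platelet", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- p$n_frames
  fp <- p$field_px
  frames <- array(0, dim = c(fp, fp, n))
  truth_masks <- vector("list", n)
  truth_sc <- numeric(n)
  times <- (seq_len(n) - 1L) * p$frame_interval
  for (i in seq_len(n)) {
    t <- times[i]
    radii <- pmin(p$platelet_radius_um +
                    sim$events$growth_um_s * (t - sim$events$t0_s),
                  p$max_radius_um)
    mask <- .rasterize_events(sim$events, t, radii, fp, p$pixel_size)
    truth_masks[[i]] <- mask
    truth_sc[i] <- 100 * sum(mask) / length(mask)
    signal <- imaging$amplitude * mask
    if (imaging$psf_sigma_px > 0 && any(mask))
      signal <- .gaussian_blur(signal, imaging$psf_sigma_px)
    clean <- imaging$background + signal
    noisy <- rpois(length(clean), pmax(clean, 0))
    if (imaging$read_noise_sd > 0)
      noisy <- noisy + rnorm(length(clean), 0, imaging$read_noise_sd)
    frames[, , i] <- matrix(pmin(pmax(round(noisy), 0), 255), fp, fp)
  }
  stack <- image_stack(frames, frame_interval = p$frame_interval,
                       pixel_size = p$pixel_size,
                       metadata = c(attr(sim$ts, "metadata"),
                                    list(render_seed = seed)))
  structure(list(stack = stack, truth_masks = truth_masks,
                 truth_sc = truth_sc),
            class = "rendered_run")
}
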