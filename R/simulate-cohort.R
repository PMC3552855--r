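#' Parameters of the synthetic donor cohort
#'
#' Distributional parameters for [sample_cohort()], chosen to match the
#' summary statistics of a healthy-donor cohort: 58% women; plasma VWF:Ag
#' lognormal with sex-dependent location (women 97.3 +/- 30.4 IU/dL, men
#' 73.4 +/- 30.1, combined mean ~88); hematocrit normal by sex (women
#' 41.5 +/- 4.2%, men 47.8 +/- 2.9%) truncated to the observed ranges;
#' platelet count normal by sex truncated likewise. A latent "low binder"
#' subgroup (platelet accumulation below 1% coverage at venous and
#' mid-arterial shear) is assigned with probability increasing as VWF falls,
#' reflecting the observed concentration of low binders at low VWF.
#'
#' @param p_female Probability a donor is female.
#' @param vwf_mean,vwf_sd Named numeric (`F`, `M`): VWF mean and SD, IU/dL.
#' @param vwf_range Named list (`F`, `M`) of c(min, max) truncation, IU/dL.
#' @param hct_mean,hct_sd Named numeric: hematocrit mean/SD in percent.
#' @param hct_range Named list of truncation ranges, percent.
#' @param plt_mean,plt_sd Named numeric: platelet count mean/SD, per µL.
#' @param plt_range Named list of truncation ranges, per µL.
#' @param p_gp6_ag Probability of the GP6 AG genotype (vs AA).
#' @param anticoagulant Default anticoagulant label for the cohort
#'   (`"citrate_cti"` or `"cti"`).
#' @param low_binder_vwf_mid,low_binder_vwf_scale Logistic location/scale
#'   (IU/dL) of the latent low-binder probability as a function of VWF.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    p_female = 0.58,
    vwf_mean = c(F = 97.3, M = 73.4),
    vwf_sd = c(F = 30.4, M = 30.1),
    vwf_range = list(F = c(38.5, 178.2), M = c(26.3, 151.4)),
    hct_mean = c(F = 41.5, M = 47.8),
    hct_sd = c(F = 4.2, M = 2.9),
    hct_range = list(F = c(27.0, 46.9), M = c(44.0, 54.1)),
    plt_mean = c(F = 321000, M = 291000),
    plt_sd = c(F = 64000, M = 30000),
    plt_range = list(F = c(211000, 503000), M = c(255000, 370000)),
    p_gp6_ag = 0.2,
    anticoagulant = "citrate_cti",
    low_binder_vwf_mid = 55,
    low_binder_vwf_scale = 12) {
  stopifnot(p_female >= 0, p_female <= 1, p_gp6_ag >= 0, p_gp6_ag <= 1,
            all(vwf_mean > 0), all(vwf_sd > 0))
  structure(as.list(environment()), class = "cohort_params")
}

# inverse-CDF truncated normal (deterministic given runif stream)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# inverse-CDF truncated lognormal parameterized by arithmetic mean/sd
.rtrunclnorm <- function(n, mean, sd, lo, hi) {
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  sdlog <- sqrt(sdlog2)
  u <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(u, meanlog, sdlog)
}

#' Sample a synthetic donor cohort
#'
#' Draws `n` donor profiles from the distributions in [cohort_params()].
#' Deterministic for a fixed seed.
#'
#' @param n Number of donors (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param params A [cohort_params()].
#' @return A tibble with one row per donor: `donor_id`, `sex` ("F"/"M"),
#'   `vwf_level` (IU/dL), `hematocrit` (fraction), `platelet_count`
#'   (per µL), `gp6_genotype` ("AA"/"AG"), `anticoagulant`,
#'   `low_binder_latent` (logical).
#' @examples
#' cohort <- sample_cohort(5, seed = 1)
#' cohort$vwf_level
#' @export
sample_cohort <- function(n, seed = NULL, params = cohort_params()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  sex <- ifelse(runif(n) < params$p_female, "F", "M")
  draw_by_sex <- function(fun, mean, sd, range) {
    out <- numeric(n)
    for (s in c("F", "M")) {
      idx <- which(sex == s)
      if (length(idx))
        out[idx] <- fun(length(idx), mean[[s]], sd[[s]],
                        range[[s]][1], range[[s]][2])
    }
    out
  }
  vwf <- draw_by_sex(.rtrunclnorm, params$vwf_mean, params$vwf_sd,
                     params$vwf_range)
  hct <- draw_by_sex(.rtruncnorm, params$hct_mean, params$hct_sd,
                     params$hct_range) / 100
  plt <- draw_by_sex(.rtruncnorm, params$plt_mean, params$plt_sd,
                     params$plt_range)
  gp6 <- ifelse(runif(n) < params$p_gp6_ag, "AG", "AA")
  low <- runif(n) < plogis((params$low_binder_vwf_mid - vwf) /
                             params$low_binder_vwf_scale)
  tibble::tibble(
    donor_id = seq_len(n),
    sex = sex,
    vwf_level = vwf,
    hematocrit = hct,
    platelet_count = plt,
    gp6_genotype = gp6,
    anticoagulant = params$anticoagulant,
    low_binder_latent = low)
}
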