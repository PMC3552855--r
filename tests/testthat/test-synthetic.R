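test_that("cohort sampling is deterministic and matches the target moments", {
  c1 <- sample_cohort(5, seed = 3)
  c2 <- sample_cohort(5, seed = 3)
  expect_identical(c1, c2)
  expect_false(identical(sample_cohort(5, seed = 4), c1))
  expect_equal(nrow(sample_cohort(1, seed = 1)), 1L)
  expect_error(sample_cohort(0), "positive")
  big <- sample_cohort(10000, seed = 11)
  expect_lt(abs(mean(big$vwf_level) - 87.9) / 87.9, 0.05)
  expect_lt(abs(mean(big$hematocrit) - 0.439) / 0.439, 0.02)
  expect_true(all(big$vwf_level > 0))
  expect_true(all(big$hematocrit > 0.25 & big$hematocrit < 0.56))
  # women carry higher VWF and lower hematocrit, as in normal cohorts
  expect_gt(mean(big$vwf_level[big$sex == "F"]),
            mean(big$vwf_level[big$sex == "M"]))
  expect_lt(mean(big$hematocrit[big$sex == "F"]),
            mean(big$hematocrit[big$sex == "M"]))
  # the latent low-binder subgroup concentrates at low VWF
  expect_lt(mean(big$vwf_level[big$low_binder_latent]),
            mean(big$vwf_level[!big$low_binder_latent]))
})

test_that("deposition model: no adhesion events means zero coverage", {
  sim <- simulate_sc_curve(list(vwf_level = 90), 300,
                           params = deposition_params(rate0 = rep(0, 4)),
                           seed = 1)
  expect_true(all(sim$ts$sc_percent == 0))
  expect_equal(nrow(sim$events), 0L)
  expect_error(deposition_params(rate0 = c(-1, 1, 1, 1)), "nonnegative")
  expect_error(simulate_sc_curve(list(vwf_level = 90), -5), "positive")
})

test_that("ground-truth coverage is monotone nondecreasing and reproducible", {
  for (s in 1:10) {
    sim <- simulate_sc_curve(list(vwf_level = 60 + 10 * s),
                             c(150, 300, 750, 1500)[1 + s %% 4], seed = s)
    expect_true(all(diff(sim$ts$sc_percent) >= 0))
    expect_true(all(sim$ts$sc_percent >= 0 & sim$ts$sc_percent <= 100))
  }
  a <- simulate_sc_curve(list(vwf_level = 90), 300, seed = 12)
  b <- simulate_sc_curve(list(vwf_level = 90), 300, seed = 12)
  expect_identical(a$ts$sc_percent, b$ts$sc_percent)
  expect_identical(a$events, b$events)
})

test_that("doubling VWF raises the mean accumulation velocity", {
  set.seed(21)
  n <- 200
  v1 <- v2 <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- compute_metrics(simulate_sc_curve(list(vwf_level = 60), 300)$ts)
    m2 <- compute_metrics(simulate_sc_curve(list(vwf_level = 120), 300)$ts)
    v1[i] <- m1$v_plt_pct_per_s
    v2[i] <- m2$v_plt_pct_per_s
  }
  expect_gt(mean(v2, na.rm = TRUE), mean(v1, na.rm = TRUE))
})

test_that("genotype, anticoagulant and low-binder multipliers act on coverage", {
  set.seed(31)
  n <- 100
  sc_of <- function(donor) {
    mean(vapply(seq_len(n), function(i)
      tail(simulate_sc_curve(donor, 300)$ts$sc_percent, 1), numeric(1)))
  }
  base <- list(vwf_level = 90, gp6_genotype = "AA",
               anticoagulant = "citrate_cti", low_binder_latent = FALSE)
  ag <- modifyList(base, list(gp6_genotype = "AG"))
  cti <- modifyList(base, list(anticoagulant = "cti"))
  low <- modifyList(base, list(low_binder_latent = TRUE))
  sc_base <- sc_of(base)
  expect_lt(sc_of(ag), sc_base)     # AG genotype binds less
  expect_gt(sc_of(cti), sc_base)    # CTI-only blood binds about 2x more
  expect_lt(sc_of(low), 1)          # latent low binders stay under 1%
})

test_that("rendering returns noisy stacks with exact ground truth attached", {
  sim <- simulate_sc_curve(list(vwf_level = 110), 300, seed = 41)
  r1 <- render_stack(sim, seed = 42)
  r2 <- render_stack(sim, seed = 42)
  expect_identical(r1$stack$frames, r2$stack$frames)  # bit-identical
  expect_equal(length(r1$truth_masks), 43L)
  expect_equal(r1$truth_sc[1], 0)
  expect_true(all(diff(r1$truth_sc) >= -1e-12))
  expect_true(max(r1$stack$frames) <= 255 && min(r1$stack$frames) >= 0)
  # zero events: pure noise in, ~zero coverage out
  sim0 <- simulate_sc_curve(list(vwf_level = 90), 300,
                            params = deposition_params(rate0 = rep(0, 4)),
                            seed = 43)
  r0 <- render_stack(sim0, seed = 44)
  ts0 <- process_stack(r0$stack)
  expect_true(all(ts0$sc_percent < 0.5))
  expect_true(all(r0$truth_sc == 0))
})

test_that("a high-SNR render of ~15% coverage is recovered within 2% absolute", {
  set.seed(51)
  sim <- simulate_sc_curve(list(vwf_level = 135), 150)
  # crisp, bright imaging: strong signal, sub-pixel PSF, little read noise
  rr <- render_stack(sim, imaging_params(background = 20, amplitude = 150,
                                         psf_sigma_px = 0.3,
                                         read_noise_sd = 2))
  ts <- process_stack(rr$stack)
  expect_gt(tail(rr$truth_sc, 1), 10)  # a substantial end-point coverage
  expect_true(all(abs(ts$sc_percent - rr$truth_sc) < 2))
})

test_that("rendering refuses a field smaller than one platelet", {
  p <- deposition_params(field_px = 8, pixel_size = 0.1)
  sim <- simulate_sc_curve(list(vwf_level = 90), 300, params = p, seed = 6)
  expect_error(render_stack(sim), "smaller than a single platelet")
})
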