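test_that("grayscale conversion uses the standard luminance weights", {
  z <- array(0, dim = c(4, 4, 3))
  expect_equal(to_grayscale(z), matrix(0, 4, 4))
  k <- array(137, dim = c(3, 5, 3))
  expect_equal(to_grayscale(k), matrix(137, 3, 5))
  px <- array(0, dim = c(1, 1, 3))
  px[1, 1, ] <- c(100, 150, 200)
  expect_equal(to_grayscale(px)[1, 1],
               round(0.2989 * 100 + 0.5870 * 150 + 0.1140 * 200))
  g <- matrix(7, 2, 2)
  expect_identical(to_grayscale(g), g)  # pass-through on gray input
  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))), "RGB")
})

test_that("triangle threshold equals the exhaustive-search oracle", {
  # spike histogram: peak at bin 10, single far bright bin at 200
  h <- numeric(256); h[11] <- 1000; h[201] <- 5
  expect_identical(triangle_threshold(h), triangle_oracle(h))
  # two-bin histogram: threshold bounded by the bins
  h2 <- numeric(256); h2[21] <- 900; h2[121] <- 40
  th <- triangle_threshold(h2)
  expect_gte(th, 20); expect_lte(th, 120)
  # bimodal Gaussian-mixture histograms
  set.seed(101)
  for (i in 1:50) {
    h3 <- random_histogram()
    expect_identical(triangle_threshold(h3), triangle_oracle(h3))
  }
})

test_that("triangle threshold handles degenerate histograms", {
  expect_error(triangle_threshold(numeric(256)), "degenerate")
  h <- numeric(256); h[61] <- 12
  expect_identical(triangle_threshold(h), 60L)  # single-bin: that bin
  expect_warning(th <- triangle_threshold(rep(4, 256)), "peak")
  expect_identical(th, 0L)  # uniform: lowest tied peak
  expect_error(triangle_threshold(numeric(100)), "256")
})

test_that("binarize-and-filter removes sub-platelet components", {
  f <- blob_fixture()
  bm <- binarize_and_filter(f, level = 100, min_area = 47)
  expect_equal(sum(bm$mask), 60)   # only the 60-px blob survives
  expect_equal(surface_coverage(bm), 15)  # 60 / 400
  # min_area = 1 is pure thresholding
  bm1 <- binarize_and_filter(f, level = 100, min_area = 1)
  expect_equal(sum(bm1$mask), 63)
  # empty foreground stays empty
  bm0 <- binarize_and_filter(f, level = 250, min_area = 47)
  expect_equal(sum(bm0$mask), 0)
  # idempotent: filtering the filtered mask changes nothing
  again <- binarize_and_filter(bm$mask * 255, level = 100, min_area = 47)
  expect_identical(again$mask, bm$mask)
  expect_error(binarize_and_filter(f, 100, min_area = 0), "min_area")
  expect_error(binarize_and_filter(f, 100, connectivity = 6), "connectivity")
})

test_that("connectivity 4 vs 8 differ on diagonal chains", {
  f <- matrix(0, 6, 6)
  f[cbind(1:3, 1:3)] <- 255  # 3-px diagonal chain
  m8 <- binarize_and_filter(f, 100, min_area = 3, connectivity = 8)
  m4 <- binarize_and_filter(f, 100, min_area = 3, connectivity = 4)
  expect_equal(sum(m8$mask), 3)  # one 8-connected component of size 3
  expect_equal(sum(m4$mask), 0)  # three 4-connected singletons, all removed
})

test_that("coverage is anti-monotone in min_area and in threshold level", {
  set.seed(7)
  f <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  sc_by_area <- vapply(c(1, 2, 5, 10, 25, 50), function(a)
    surface_coverage(binarize_and_filter(f, 120, min_area = a)), numeric(1))
  expect_true(all(diff(sc_by_area) <= 0))
  sc_by_level <- vapply(c(0, 60, 120, 180, 240), function(l)
    surface_coverage(binarize_and_filter(f, l, min_area = 1)), numeric(1))
  expect_true(all(diff(sc_by_level) <= 0))
})

test_that("surface coverage validates input and scales to percent", {
  expect_equal(surface_coverage(matrix(TRUE, 5, 5)), 100)
  m <- matrix(FALSE, 10, 10); m[1:5, 1:5] <- TRUE
  expect_equal(surface_coverage(m), 25)
  expect_error(surface_coverage(matrix(TRUE, 0, 0)), "zero")
  expect_error(surface_coverage(1:5), "logical")
})

test_that("process_stack yields constant coverage for identical frames", {
  f <- blob_fixture()
  stk <- image_stack(array(rep(f, 5), dim = c(20, 20, 5)),
                     frame_interval = 7)
  cfg <- mfa_config(min_area = 47)
  ts <- process_stack(stk, cfg)
  expect_s3_class(ts, "sc_timeseries")
  expect_equal(ts$time_s, (0:4) * 7)
  expect_equal(length(unique(ts$sc_percent)), 1L)
  expect_equal(length(unique(ts$threshold_level)), 1L)
  # global threshold mode gives the same answer here (identical histograms)
  tsg <- process_stack(stk, mfa_config(min_area = 47,
                                       threshold_mode = "global"))
  expect_equal(tsg$sc_percent, ts$sc_percent)
})

test_that("noise-only stacks give ~0% coverage after the platelet-size filter", {
  set.seed(99)
  frames <- array(rpois(64 * 64 * 4, 30), dim = c(64, 64, 4))
  frames[frames > 255] <- 255
  ts <- process_stack(image_stack(frames), mfa_config())
  expect_true(all(ts$sc_percent < 0.5))
})

test_that("TIFF round trip and config files preserve the pipeline inputs", {
  f <- blob_fixture()
  stk <- image_stack(array(rep(f, 3), dim = c(20, 20, 3)))
  tmp <- tempfile(fileext = ".tif")
  write_image_stack(stk, tmp)
  back <- read_image_stack(tmp)
  expect_equal(back$frames, stk$frames)
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c("pixel_size: 0.5", "min_area: 20", "connectivity: 4"), cfgfile)
  cfg <- read_mfa_config(cfgfile)
  expect_equal(cfg$pixel_size, 0.5)
  expect_equal(cfg$min_area, 20L)
  expect_equal(cfg$connectivity, 4L)
  writeLines("bogus_key: 1", cfgfile)
  expect_error(read_mfa_config(cfgfile), "unknown config")
  # SC CSV round trip
  ts <- process_stack(stk, mfa_config(min_area = 47))
  csv <- tempfile(fileext = ".csv")
  write_sc_csv(ts, csv)
  back_ts <- read_sc_csv(csv)
  expect_equal(back_ts$sc_percent, ts$sc_percent)
})

test_that("default minimum area is one platelet at the default optics", {
  cfg <- mfa_config()
  expect_equal(cfg$min_area, round(pi * 1.25^2 / 0.3225^2))
  expect_equal(cfg$min_area, 47L)
})
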