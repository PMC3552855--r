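# Independent oracles used across tests. These deliberately use different
# formulations (scalar loops, series solutions, closed forms) from the
# package code they check.

# Exhaustive triangle-threshold search: scalar loop over every bin, point-to-
# line distance computed from the cross product, in the same normalized
# coordinates (counts by peak height, bins by peak-to-tail span).
triangle_oracle <- function(h) {
  nz <- which(h > 0)
  if (length(nz) == 1L) return(nz[1] - 1L)
  peak <- which.max(h)
  tb <- nz[length(nz)]
  x1 <- 0; y1 <- 1
  x2 <- 1; y2 <- h[tb] / h[peak]
  best_d <- -Inf; best <- peak
  for (b in 1:256) {
    if (b < peak || b > tb) next
    px <- (b - peak) / (tb - peak)
    py <- h[b] / h[peak]
    d <- abs((x2 - x1) * (y1 - py) - (x1 - px) * (y2 - y1)) /
      sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (d > best_d - 1e-12) { if (d > best_d) best_d <- d; best <- b }
  }
  best - 1L
}

# Exact series solution for laminar flow in a rectangular duct of
# height/width ratio alpha (Fanning f * Re based on hydraulic diameter).
fre_series_oracle <- function(alpha, n_terms = 25) {
  i <- seq(1, by = 2, length.out = n_terms)
  s <- sum(tanh(i * pi / (2 * alpha)) / i^5)
  24 / ((1 + alpha)^2 * (1 - (192 * alpha / pi^5) * s))
}

# Parallel-plate wall shear rate, Q in uL/min, dimensions in um.
parallel_plate_shear <- function(q_ul_min, width, height) {
  6 * (q_ul_min * 1e9 / 60) / (width * height^2)
}

# Independent transcription of the in vitro viscosity correlation.
pries_viscosity_oracle <- function(D, H) {
  eta_star <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  dampen <- 1 / (1 + 1e-11 * D^12)
  C <- (0.8 + exp(-0.075 * D)) * (dampen - 1) + dampen
  num <- (1 - H)^C - 1
  den <- (1 - 0.45)^C - 1
  1 + (eta_star - 1) * num / den
}

# Random fluorescence-like histogram: Poisson-ish dark peak plus a sparse
# bright tail; occasionally pathological (few bins).
random_histogram <- function() {
  h <- numeric(256)
  peak <- sample(5:80, 1)
  bg <- round(5000 * exp(-0.5 * ((1:256 - peak) / runif(1, 2, 12))^2))
  h <- h + bg
  if (runif(1) < 0.9) {
    tail_center <- sample((peak + 30):240, 1)
    tl <- round(runif(1, 5, 300) *
                  exp(-0.5 * ((1:256 - tail_center) / runif(1, 3, 25))^2))
    h <- h + tl
  }
  if (runif(1) < 0.2) {  # sparse speckle
    idx <- sample(1:256, sample(1:5, 1))
    h[idx] <- h[idx] + sample(1:50, length(idx), replace = TRUE)
  }
  h[h < 0] <- 0
  if (sum(h) == 0) h[peak] <- 1
  h
}

# 20x20 fixture: one 60-px rectangle and one 3-px speck, counted by hand.
blob_fixture <- function() {
  f <- matrix(0, 20, 20)
  f[3:8, 4:13] <- 200   # 6 x 10 = 60 px
  f[15, 15:17] <- 200   # 3 px
  f
}
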