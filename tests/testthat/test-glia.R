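# Phase-modulation interferometer simulation and GLIA demodulation.

test_that("modulation depth follows the birefringent-modulator relation", {
  cfg0 <- modulator_config(delta_i_mA = 0)
  expect_equal(modulation_depth(cfg0), 0)
  # direct evaluation with ne-no = 0.2, L = 1 cm, beta = 0.6 nm/mA,
  # lambda0 = 852 nm, delta_i = 0.369 mA
  cfg <- modulator_config(ne = 2.15, no = 1.95, L_m = 0.01,
                          beta_nm_per_mA = 0.6, lambda0_nm = 852,
                          delta_i_mA = 0.369)
  expect_equal(modulation_depth(cfg),
               2 * pi * 0.2 * 0.6 * 1e7 * 0.369 / 852^2, tolerance = 1e-12)
  expect_equal(modulation_depth(cfg), 3.83, tolerance = 2e-3)
  # linear in the modulation current amplitude
  cfg2 <- modulator_config(delta_i_mA = 2 * 0.369)
  expect_equal(modulation_depth(cfg2), 2 * modulation_depth(cfg))
  expect_error(modulator_config(L_m = -1), "positive")
})

test_that("J1-null depth is the first positive zero of J1", {
  d <- j1_null_depth()
  expect_equal(round(d, 4), 3.8317)
  expect_lt(abs(besselJ(d, 1)), 1e-10)
  expect_gt(d, 3.0); expect_lt(d, 4.5)
})

test_that("beating-signal limiting cases", {
  # m = 0: pure residual-amplitude sinusoid
  s <- simulate_beating(0.7, m = 0, mu = 0.3, I0 = 2)
  expect_equal(s$I, 2 * (1 + 0.3 * sin(s$omega * s$t)), tolerance = 1e-12)
  # mu = 0 and zero depth: constant level set by the interference term
  s2 <- simulate_beating(0.9, depth = 0, mu = 0, m = 0.4, I0 = 1.5)
  expect_equal(s2$I, rep(1.5 * (1 + 0.4 * cos(0.9)), length(s2$t)),
               tolerance = 1e-12)
  expect_true(all(simulate_beating(1.2, mu = 0.9, m = 1)$I >= 0))
  expect_error(simulate_beating(0, mu = 1.2), "\\[0, 1\\]")
  expect_error(simulate_beating(0, samples_per_period = 32), ">= 64")
})

test_that("simulated harmonics match the Jacobi-Anger expansion (FFT check)", {
  phi <- 0.8; mu <- 0.12; m <- 0.55; d <- j1_null_depth()
  sig <- simulate_beating(phi, depth = d, mu = mu, m = m,
                          n_periods = 1, samples_per_period = 512)
  wt <- sig$omega * sig$t
  # oracle: truncated Bessel series for cos/sin(d sin wt), mean-removed
  nmax <- 40
  Cser <- besselJ(d, 0) + 2 * Reduce(`+`, lapply(seq_len(nmax), function(n)
    besselJ(d, 2 * n) * cos(2 * n * wt)))
  Sser <- 2 * Reduce(`+`, lapply(seq_len(nmax), function(n)
    besselJ(d, 2 * n - 1) * sin((2 * n - 1) * wt)))
  Iser <- (1 + mu * sin(wt)) * (1 + m * (cos(phi) * Cser + sin(phi) * Sser))
  ff_sim <- stats::fft(sig$I - mean(sig$I)) / length(wt)
  ff_ser <- stats::fft(Iser - mean(Iser)) / length(wt)
  for (bin in 1:3)   # DC residual, 1w, 2w
    expect_lt(Mod(ff_sim[bin] - ff_ser[bin]), 1e-6)
})

test_that("numeric lock-in quadratures equal the closed forms", {
  grid <- expand.grid(phi = c(-2.4, -0.7, 0, 1.1, 2.9),
                      mu = c(0, 0.05, 0.2),
                      depth = c(3.0, j1_null_depth(), 4.4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sig <- simulate_beating(g$phi, depth = g$depth, mu = g$mu, m = 0.6, I0 = 1.7)
    lk <- lockin_xy(sig)
    cf <- glia_quadratures(g$phi, g$depth, I0 = 1.7, mu = g$mu, m = 0.6)
    scale <- max(abs(cf$X), abs(cf$Y))
    expect_lt(abs(lk$X - cf$X) / scale, 1e-8)
    expect_lt(abs(lk$Y - cf$Y) / scale, 1e-8)
  }
})

test_that("lock-in quadratures vanish without interference contrast", {
  lk <- lockin_xy(simulate_beating(1.3, m = 0, mu = 0.25))
  expect_lt(abs(lk$X), 1e-12)
  expect_lt(abs(lk$Y), 1e-12)
})

test_that("quadrature ratio between phases follows the closed form", {
  # X(phi = 0) / X(phi = pi/3) = 1 / cos(pi/3) = 2 at mu = 0
  x0 <- lockin_xy(simulate_beating(0, mu = 0))$X
  x3 <- lockin_xy(simulate_beating(pi / 3, mu = 0))$X
  expect_equal(x0 / x3, 2, tolerance = 1e-9)
})

test_that("non-integer period coverage is rejected", {
  sig <- simulate_beating(0.4)
  sig$t <- sig$t[1:(length(sig$t) - 10)]
  sig$I <- sig$I[1:length(sig$t)]
  expect_error(lockin_xy(sig), "integer")
})

test_that("phase extraction round-trips the simulator", {
  expect_equal(glia_roundtrip(0), 0, tolerance = 1e-9)
  phis <- seq(-pi + 0.01, pi - 0.01, length.out = 181)
  for (mu in c(0, 0.05, 0.2)) {
    err <- vapply(phis, function(p) abs(glia_roundtrip(p, mu = mu) - p), numeric(1))
    expect_lt(max(err), 1e-6)
  }
})

test_that("extraction is scale invariant and rejects degenerate input", {
  sig <- simulate_beating(1.234, mu = 0.1)
  lk <- lockin_xy(sig)
  p1 <- extract_phase(lk, mu = 0.1)
  lk2 <- lk; lk2$X <- 7.3 * lk$X; lk2$Y <- 7.3 * lk$Y
  expect_equal(extract_phase(lk2, mu = 0.1), p1, tolerance = 1e-12)
  expect_error(extract_phase(list(X = 0, Y = 0, depth = 3.8)), "degenerate")
})

test_that("J1-null depth makes extraction first-order insensitive to mu", {
  # extraction is told mu; the uncorrectable residual-amplitude term in Y
  # scales with J1(depth), which vanishes exactly at the null depth
  sens <- function(depth) {
    h <- 1e-3
    p1 <- extract_phase(lockin_xy(simulate_beating(0.9, depth = depth, mu = h)),
                        depth = depth, mu = h)
    p0 <- extract_phase(lockin_xy(simulate_beating(0.9, depth = depth, mu = 0)),
                        depth = depth, mu = 0)
    abs(p1 - p0) / h
  }
  expect_lt(sens(j1_null_depth()), 1e-6)
  expect_gt(sens(3.0), 1e-3)
})

test_that("round trip under phase noise recovers the truth without bias", {
  set.seed(7)
  phis <- seq(-2.5, 2.5, length.out = 8)
  err <- unlist(lapply(phis, function(p) vapply(1:100, function(k) {
    glia_roundtrip(p + stats::rnorm(1, sd = 0.001), mu = 0.1) - p
  }, numeric(1))))
  rms <- sqrt(mean(err^2))
  expect_gt(rms, 0.0007); expect_lt(rms, 0.0013)   # ~ the injected noise
  expect_lt(abs(mean(err)), 1e-4)                  # no bias
})
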