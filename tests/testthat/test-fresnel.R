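# Multilayer Fresnel reflectivity: single interfaces, full stacks, and the
# phase-vs-RI mapping curve.

test_that("single-interface coefficients match closed forms", {
  # identical media reflect nothing
  expect_equal(Mod(interface_rp(1.47, 1.47, 37)), 0, tolerance = 1e-14)
  expect_equal(Mod(interface_rs(2.1 + 0.3i, 2.1 + 0.3i, 61)), 0, tolerance = 1e-14)
  # normal incidence: |r| = (n2 - n1)/(n2 + n1) = 0.2 for 1 -> 1.5
  expect_equal(Mod(interface_rp(1.0, 1.5, 1e-6)), 0.2, tolerance = 1e-9)
  expect_equal(Mod(interface_rs(1.0, 1.5, 1e-6)), 0.2, tolerance = 1e-9)
  # total internal reflection beyond the critical angle (~62.1 deg)
  expect_equal(Mod(interface_rp(1.51, 1.3344, 70)), 1, tolerance = 1e-12)
  expect_equal(Mod(interface_rs(1.51, 1.3344, 70)), 1, tolerance = 1e-12)
  expect_error(interface_rp(0, 1.5, 45), "nonzero")
  expect_error(interface_rp(NaN, 1.5, 45), "non-finite")
})

test_that("stack constructor enforces layer invariants", {
  expect_error(optical_layer("x", 1.5, -1), "negative thickness")
  expect_error(optical_layer("x", 1.5 - 0.2i, 10), "Im\\(n\\)")
  good <- list(optical_layer("a", 1.5, Inf), optical_layer("b", 1.33, Inf))
  expect_s3_class(optical_stack(good), "optical_stack")
  # overlapping semi-infinite markers
  bad <- list(optical_layer("a", 1.5, Inf), optical_layer("m", 2, Inf),
              optical_layer("b", 1.33, Inf))
  expect_error(optical_stack(bad), "semi-infinite")
  expect_error(stack_reflectivity(default_chip_stack(), 95), "\\(0, 90\\)")
})

test_that("zero-thickness internal layers reduce to the bare interface", {
  st <- default_chip_stack(au_nm = 0, probe_nm = 0, cr_nm = 0)
  for (ang in c(35, 61, 66, 80)) {
    rf <- stack_reflectivity(st, ang)
    expect_equal(rf$r_p, interface_rp(1.51, 1.3344, ang), tolerance = 1e-12)
    expect_equal(rf$r_s, interface_rs(1.51, 1.3344, ang), tolerance = 1e-12)
  }
})

test_that("matrix and recursive implementations agree on random stacks", {
  set.seed(401)
  for (k in 1:100) {
    st <- random_stack()
    ang <- runif(1, 5, 85)
    a <- stack_reflectivity(st, ang)
    b <- stack_reflectivity_recursive(st, ang)
    expect_lt(Mod(a$r_p - b$r_p), 1e-10)
    expect_lt(Mod(a$r_s - b$r_s), 1e-10)
  }
})

test_that("reflectances of passive stacks respect the energy bound", {
  set.seed(402)
  for (k in 1:60) {
    rf <- stack_reflectivity(random_stack(), runif(1, 5, 85))
    expect_true(rf$R_p >= 0 && rf$R_p <= 1 + 1e-12)
    expect_true(rf$R_s >= 0 && rf$R_s <= 1 + 1e-12)
  }
})

test_that("Cr- and probe-free stack matches an independent three-layer formula", {
  st <- default_chip_stack(au_nm = 48, probe_nm = 0, cr_nm = 0)
  for (ang in c(60, 66, 70)) {
    rf <- stack_reflectivity(st, ang)
    expect_equal(rf$r_p, three_layer_r(1.51, 0.16 + 5.34i, 1.3344, 48, 850, ang, "p"),
                 tolerance = 1e-12)
    expect_equal(rf$r_s, three_layer_r(1.51, 0.16 + 5.34i, 1.3344, 48, 850, ang, "s"),
                 tolerance = 1e-12)
  }
})

test_that("default stack has a unique resonance dip with a p-phase sweep", {
  st <- default_chip_stack()    # 48 nm Au, buffer 1.3344
  ang <- seq(63, 71, by = 0.005)  # above the TIR critical angle (~62.1 deg)
  rf <- stack_reflectivity(st, ang)
  dip <- ang[which.min(rf$R_p)]
  expect_gt(dip, 65.5); expect_lt(dip, 67.5)
  # unique deep minimum: near-total absorption at the dip, and the
  # low-reflectance region is a single contiguous run around it
  i <- which.min(rf$R_p)
  expect_lt(rf$R_p[i], 0.01)
  low <- which(rf$R_p < 0.1)
  expect_true(all(diff(low) == 1))
  expect_true(i %in% low)
  # p-phase sweeps monotonically through resonance; s-phase is slowly varying
  win <- abs(ang - dip) < 0.75
  php <- rf$phi_p[win]; php <- cumsum(c(php[1], { d <- diff(php); d - 2*pi*round(d/(2*pi)) }))
  expect_true(all(diff(php) < 0) || all(diff(php) > 0))
  expect_gt(diff(range(php)), 10 * diff(range(rf$phi_s[win])))
})

test_that("phase-vs-RI curve is baseline-referenced, monotone and asymmetric", {
  st <- default_chip_stack(au_nm = 46, probe_nm = 7.5)
  for (ang in c(66.3, 66.5)) {
    curve <- phase_vs_ri(st, ang, seq(1.333, 1.340, length.out = 301),
                         baseline_ri = 1.3344)
    expect_equal(curve$dphase[which.min(abs(curve$ri - 1.3344))], 0,
                 tolerance = 1e-9)
    d <- diff(curve$dphase)
    expect_true(all(d > 0) || all(d < 0))               # monotone
    expect_lt(max(abs(d)), pi)                          # continuous
    # asymmetric sigmoid: the rise over the lower half of the RI window
    # differs from the rise over the upper half
    n <- length(curve$ri); mid <- (n + 1) %/% 2
    lo <- curve$dphase[mid] - curve$dphase[1]
    hi <- curve$dphase[n] - curve$dphase[mid]
    expect_gt(abs(lo / hi - 1), 0.05)
  }
})

test_that("near-resonance angle amplifies the phase step (angle offset ordering)", {
  st <- default_chip_stack(au_nm = 46, probe_nm = 7.5)
  step_at <- function(ang) {
    curve <- phase_vs_ri(st, ang, seq(1.333, 1.340, length.out = 601),
                         baseline_ri = 1.3344)
    abs(stats::approx(curve$ri, curve$dphase, 1.3384)$y)
  }
  expect_gt(step_at(66.4), step_at(66.1))
})

test_that("mapping-curve slope at fixed angle is monotone in Au thickness", {
  slope_at <- function(au) {
    st <- default_chip_stack(au_nm = au, probe_nm = 7.5)
    curve <- phase_vs_ri(st, 66.4, seq(1.3335, 1.3345, length.out = 101),
                         baseline_ri = 1.3340)
    i <- which.min(abs(curve$ri - 1.3340))
    (curve$dphase[i + 2] - curve$dphase[i - 2]) / (curve$ri[i + 2] - curve$ri[i - 2])
  }
  slopes <- vapply(44:48, slope_at, numeric(1))
  expect_true(all(diff(slopes) < 0) || all(diff(slopes) > 0))
})

test_that("phase grid errors are informative", {
  st <- default_chip_stack()
  expect_error(phase_vs_ri(st, 66.4, c(1.334, 1.333), 1.334), "strictly increasing")
  expect_error(phase_vs_ri(st, 66.4, seq(1.334, 1.340, length.out = 50), 1.35),
               "within the grid")
  # a two-point grid straddling a sharp resonance cannot unwrap unrefined,
  # but succeeds once automatic grid refinement is allowed
  sharp <- default_chip_stack(au_nm = 48, probe_nm = 7.5)
  expect_error(phase_vs_ri(sharp, 66.4, c(1.3340, 1.3365), 1.3340,
                           max_refine = 0L), "too coarse")
  refined <- phase_vs_ri(sharp, 66.4, c(1.3340, 1.3365), 1.3340)
  expect_gt(length(refined$ri), 2)            # the refined grid is reported
  expect_lt(max(abs(diff(refined$dphase))), pi / 2)
})
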