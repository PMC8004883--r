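# Segmented-cubic meta-model: fitting, evaluation, inversion, serialization.

test_that("an exact cubic is reproduced to machine precision", {
  ri <- seq(1.333, 1.340, length.out = 60)
  truth <- function(x) 2.1 + 350 * (x - 1.336) + 4e4 * (x - 1.336)^2 - 8e6 * (x - 1.336)^3
  curve <- mapping_curve(ri, truth(ri) - truth(1.334), baseline_ri = 1.334)
  mm <- build_metamodel(curve)
  expect_lt(mm$max_residual, 1e-10)
  expect_lt(max(abs(evaluate_phase(mm, ri) - curve$dphase)), 1e-10)
})

test_that("defaults are three cubic segments with equal-count chunks", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  expect_identical(mm$n_segments, 3L)
  expect_identical(mm$order, 3L)
  expect_length(mm$segments, 3)
  # 301-point curve (plus the inserted baseline) splits into near-equal chunks
  ri <- seq(0, 1, length.out = 301)
  sizes <- table(rep(1:3, psprmap:::.chunk_sizes(301, 3)))
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("meta-model tracks the Fresnel curve on the default chip", {
  chip <- default_chip()
  curve <- chip_mapping_curve(chip)          # 301 samples over the window
  mm <- build_metamodel(curve)
  dense <- chip_mapping_curve(chip, n = 1501L)
  err <- evaluate_phase(mm, dense$ri) - dense$dphase
  # phase-direction error is bounded by the chip's resonance sharpness;
  # the RI-direction (mapping) error stays at the micro-RIU level
  expect_lt(max(abs(err)), 2e-2)
  slope <- c(diff(dense$dphase) / diff(dense$ri), NA)
  slope[length(slope)] <- slope[length(slope) - 1]
  expect_lt(max(abs(err / slope)), 2e-5)
})

test_that("insufficient points and non-curve input are rejected", {
  ri <- seq(1.333, 1.340, length.out = 10)
  curve <- mapping_curve(ri, (ri - 1.333) * 100, baseline_ri = 1.333)
  expect_error(build_metamodel(curve), "insufficient points")
  expect_error(mapping_curve(c(1.34, 1.33), c(0, 1), 1.33), "strictly increasing")
  expect_error(mapping_curve(c(1.33, 1.34), c(0, 4), 1.33), "jump exceeds pi")
})

test_that("evaluation uses the lower segment at a boundary and stays continuous", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  for (b in mm$breaks) {
    lo <- psprmap:::.eval_segment(mm, b, psprmap:::.segment_of(mm, b))
    hi <- psprmap:::.eval_segment(mm, b, psprmap:::.segment_of(mm, b) + 1L)
    expect_identical(evaluate_phase(mm, b), lo)
    expect_lt(abs(hi - lo), 2 * mm$max_residual)   # monitored joint mismatch
  }
  expect_error(evaluate_phase(mm, mm$ri_range[2] + 0.001), "out of model domain")
})

test_that("evaluation preserves ordering on the monotone working branch", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  set.seed(11)
  for (k in 1:25) {
    tri <- sort(runif(3, mm$working_ri_range[1], mm$working_ri_range[2]))
    vals <- evaluate_phase(mm, tri)
    expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  }
})

test_that("inversion is the functional inverse of evaluation", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  set.seed(12)
  ri <- runif(100, mm$ri_range[1], mm$ri_range[2])
  back <- invert_phase(mm, evaluate_phase(mm, ri))
  expect_lt(max(abs(back - ri)), 1e-9)
  # temporal continuity: with a previous value the same branch is kept
  expect_equal(invert_phase(mm, evaluate_phase(mm, ri[1]), previous_ri = ri[1]),
               ri[1], tolerance = 1e-9)
  expect_error(invert_phase(mm, mm$phase_range[2] + 1), "outside the model")
})

test_that("meta-model JSON round-trips", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  path <- tempfile(fileext = ".json")
  write_metamodel(mm, path, provenance = list(au_nm = 46, grid = 301))
  mm2 <- read_metamodel(path)
  expect_equal(mm2$breaks, mm$breaks, tolerance = 1e-12)
  expect_equal(mm2$phase_range, mm$phase_range, tolerance = 1e-12)
  ri <- seq(mm$ri_range[1], mm$ri_range[2], length.out = 57)
  expect_equal(evaluate_phase(mm2, ri), evaluate_phase(mm, ri), tolerance = 1e-12)
  expect_equal(mm2$provenance$au_nm, 46)
  expect_error(read_metamodel(write_metamodel_bad <- {
    p <- tempfile(fileext = ".json"); jsonlite::write_json(list(a = 1), p); p
  }), "not a meta-model")
})
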