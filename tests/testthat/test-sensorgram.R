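# Phasogram -> sensorgram conversion and cross-ROI consistency.

test_that("containers validate their invariants", {
  expect_error(phasogram(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
  expect_error(phasogram(1:3, c(0, NA, 0)), "non-finite")
  pg <- phasogram(1:5, rep(0, 5), roi_id = "a")
  expect_identical(attr(pg, "units"), "rad")
  sg <- sensorgram(1:5, rep(0, 5))
  expect_identical(attr(sg, "units"), "RIU")
})

test_that("an all-zero phasogram converts to an all-zero sensorgram", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  pg <- phasogram(seq(0, 100, by = 1), rep(0, 101))
  sg <- convert_phasogram(pg, mm)
  expect_true(all(abs(sg$ri) < 1e-12))
  expect_identical(sg$time_s, pg$time_s)
})

test_that("a known RI ramp is recovered through the chip's own model", {
  time <- seq(0, 600, by = 2)
  ramp <- 1.3340 + seq(0, 1.8e-3, length.out = length(time))
  # smooth chip (44 nm): recovery at the micro-RIU level
  chip44 <- ground_truth_chip(66.4, 44)
  sg <- convert_phasogram(phasogram_from_ri(chip44, time, ramp, sigma = 0),
                          build_metamodel(chip_mapping_curve(chip44)))
  expect_lt(sqrt(mean((sg$ri - (ramp - 1.3340))^2)), 1e-6)
  # default 46 nm chip: bounded by its (sharper) meta-model floor
  chip <- default_chip()
  sg2 <- convert_phasogram(phasogram_from_ri(chip, time, ramp, sigma = 0),
                           build_metamodel(chip_mapping_curve(chip)))
  expect_lt(sqrt(mean((sg2$ri - (ramp - 1.3340))^2)), 5e-6)
})

test_that("conversion preserves sample ordering on the monotone branch", {
  chip <- default_chip()
  mm <- build_metamodel(chip_mapping_curve(chip))
  time <- seq(0, 200, by = 1)
  ri <- 1.3340 + 1.5e-3 * (1 - exp(-time / 60))
  pg <- phasogram_from_ri(chip, time, ri, sigma = 0)
  sg <- convert_phasogram(pg, mm)
  expect_true(all(diff(sg$ri)[diff(pg$phase_rad) > 0] > 0))
})

test_that("unit tags are enforced (no double conversion)", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  sg <- sensorgram(1:20, rep(0, 20))
  expect_error(convert_phasogram(sg, mm), "already a refractive-index")
})

test_that("out-of-range samples are reported with indices", {
  mm <- build_metamodel(chip_mapping_curve(default_chip()))
  pg <- phasogram(1:12, c(rep(0, 10), 50, -50))
  expect_error(convert_phasogram(pg, mm), "indices: 11, 12")
})

test_that("baseline re-referencing subtracts the baseline-window mean", {
  pg <- phasogram(seq(0, 300, by = 1), c(rep(0.25, 61), rep(1, 240)))
  rb <- rebaseline(pg, window = 60)
  expect_equal(rb$phase_rad[1:61], rep(0, 61))
  expect_equal(rb$phase_rad[100], 0.75)
})

test_that("consistency report is symmetric with zero diagonal", {
  sg1 <- sensorgram(seq(0, 100, 1), sin(seq(0, 100, 1) / 20) * 1e-4, "a")
  expect_equal(unname(consistency_report(list(sg1, sg1, sg1))),
               matrix(0, 3, 3))
  sg2 <- sensorgram(seq(0, 100, 0.5), sin(seq(0, 100, 0.5) / 20) * 1e-4 + 1e-6, "b")
  M <- consistency_report(list(sg1, sg2))
  expect_equal(M[1, 2], M[2, 1])
  expect_equal(M[1, 2], 1e-6, tolerance = 1e-3)
  expect_error(consistency_report(list(sg1, sensorgram(200:300, rep(0, 101)))),
               "overlap")
  expect_error(consistency_report(list(sg1)), "at least two")
})

test_that("neighbouring ROIs disagree in phase but agree after conversion", {
  pair <- make_roi_pair(default_chip())          # 1.2 nm Au / 0.05 deg apart
  pgs <- list(); sgs <- list()
  for (i in 1:2) {
    cal <- make_calibration(pair[[i]], sigma = 0.001, seed = 300 + i)
    fit <- calibrate_chip(cal, n_iter = 150, seed = 10 + i)
    bind <- make_binding_phasogram(pair[[i]], sigma = 0.001, seed = 400 + i,
                                   roi_id = paste0("roi", i))
    pgs[[i]] <- bind$phasogram
    sgs[[i]] <- convert_phasogram(bind$phasogram, fit$model)
  }
  phase_rms <- consistency_report(pgs)[1, 2]
  ri_rms <- consistency_report(sgs)[1, 2]
  expect_gt(phase_rms, 10 * 0.001)    # raw phasograms visibly differ
  expect_lt(ri_rms, 5e-6)             # converted sensorgrams coincide
})
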