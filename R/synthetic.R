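# Synthetic ground-truth chips, calibration tables and phasograms.
#
# The generated world mirrors the instrument's stated conditions: five-point
# calibration (four NaCl reference solutions at RI 1.3342 / 1.3346 / 1.3349 /
# 1.3364 plus the running-buffer baseline, taken here as 1.3340), phase noise
# of about 0.001 rad, chips in the 44-48 nm gold range operated at
# 66.3-66.5 degrees, and a ~7.5 nm aptamer probe layer (about 22 bp at
# 0.34 nm/bp) of effective index 1.40.  All generators are pure functions of
# (parameters, seed).

#' Reference-solution refractive indices
#'
#' The four NaCl-in-PBS reference solutions used for five-point calibration.
#' @return Numeric vector of four RIU values.
#' @export
reference_ris <- function() c(1.3342, 1.3346, 1.3349, 1.3364)

#' Create a ground-truth chip
#'
#' The latent physical parameters of a simulated sensor chip; everything a
#' calibration run tries to recover.
#'
#' @param incident_angle Operating angle, degrees (60-75).
#' @param au_nm Gold thickness, nm (35-60).
#' @param probe_nm Probe layer thickness, nm.
#' @param probe_ri Probe layer effective refractive index.
#' @return An object of class `ground_truth_chip`.
#' @export
ground_truth_chip <- function(incident_angle = 66.4, au_nm = 46,
                              probe_nm = 7.5, probe_ri = 1.40) {
  if (incident_angle < 60 || incident_angle > 75)
    stop("'incident_angle' outside the plausible window (60-75 deg)")
  if (au_nm < 35 || au_nm > 60)
    stop("'au_nm' outside the plausible window (35-60 nm)")
  structure(list(incident_angle = incident_angle, au_nm = au_nm,
                 probe_nm = probe_nm, probe_ri = probe_ri),
            class = "ground_truth_chip")
}

#' @export
print.ground_truth_chip <- function(x, ...) {
  cat(sprintf("Ground-truth chip: angle %.3f deg, Au %.2f nm, probe %.2f nm @ RI %.4f\n",
              x$incident_angle, x$au_nm, x$probe_nm, x$probe_ri))
  invisible(x)
}

#' Optical stack of a ground-truth chip
#'
#' @param chip A [ground_truth_chip()].
#' @param buffer_ri Buffer refractive index.
#' @return An [optical_stack()].
#' @export
chip_stack <- function(chip, buffer_ri = 1.3340) {
  stopifnot(inherits(chip, "ground_truth_chip"))
  default_chip_stack(au_nm = chip$au_nm, probe_nm = chip$probe_nm,
                     probe_ri = chip$probe_ri, buffer_ri = buffer_ri)
}

#' True mapping curve of a ground-truth chip
#'
#' The chip's exact Fresnel phase-vs-RI curve over a window, baseline
#' referenced.  `include` values are inserted into the grid exactly so that
#' calibration phases are Fresnel-exact, not interpolated.
#'
#' @param chip A [ground_truth_chip()].
#' @param ri_window `c(lo, hi)` RI window.
#' @param baseline_ri Baseline buffer RI.
#' @param n Grid size.
#' @param include Extra RI values sampled exactly.
#' @return A [mapping_curve()].
#' @export
chip_mapping_curve <- function(chip, ri_window = c(1.3336, 1.3368),
                               baseline_ri = 1.3340, n = 301L,
                               include = NULL) {
  stopifnot(inherits(chip, "ground_truth_chip"))
  grid <- seq(ri_window[1], ri_window[2], length.out = n)
  grid <- sort(unique(c(grid, include, baseline_ri)))
  phase_vs_ri(chip_stack(chip, baseline_ri), chip$incident_angle, grid,
              baseline_ri = baseline_ri)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate a synthetic calibration set
#'
#' Fresnel-exact differential phases of a ground-truth chip at the reference
#' refractive indices, plus i.i.d. Gaussian phase noise at the instrument's
#' noise floor.
#'
#' @param chip A [ground_truth_chip()].
#' @param refs Reference RIs (default [reference_ris()]).
#' @param baseline_ri Baseline buffer RI.
#' @param sigma Phase noise SD, rad (default 0.001; 0 gives exact phases).
#' @param seed RNG seed.
#' @return A [calibration_set()].
#' @export
make_calibration <- function(chip, refs = reference_ris(),
                             baseline_ri = 1.3340, sigma = 0.001, seed = 0L) {
  stopifnot(inherits(chip, "ground_truth_chip"))
  span <- max(c(refs, baseline_ri)) - min(c(refs, baseline_ri))
  win <- range(c(refs, baseline_ri)) + c(-0.25, 0.25) * span
  curve <- chip_mapping_curve(chip, ri_window = win, baseline_ri = baseline_ri,
                              include = refs)
  ph <- curve$dphase[match(refs, curve$ri)]
  if (anyNA(ph)) stop("internal error: reference RI not on the curve grid")
  if (sigma > 0) ph <- ph + .with_seed(seed, stats::rnorm(length(refs), sd = sigma))
  calibration_set(refs, ph, baseline_ri)
}

#' Phasogram of a chip measuring a refractive-index time course
#'
#' Pushes `ri(t)` through the chip's exact Fresnel phase map (dense monotone
#' interpolation) and adds Gaussian phase noise.
#'
#' @param chip A [ground_truth_chip()].
#' @param time Times, s.
#' @param ri Refractive-index course (same length), RIU.
#' @param baseline_ri Baseline buffer RI (phase 0).
#' @param sigma Phase noise SD, rad.
#' @param seed RNG seed.
#' @param roi_id ROI identifier.
#' @return A [phasogram()].
#' @export
phasogram_from_ri <- function(chip, time, ri, baseline_ri = 1.3340,
                              sigma = 0.001, seed = 0L, roi_id = "roi1") {
  stopifnot(inherits(chip, "ground_truth_chip"))
  pad <- 0.1 * max(diff(range(c(ri, baseline_ri))), 1e-4)
  win <- range(c(ri, baseline_ri)) + c(-pad, pad)
  curve <- chip_mapping_curve(chip, ri_window = win, baseline_ri = baseline_ri,
                              n = 2001L)
  monotone <- all(diff(curve$dphase) > 0) || all(diff(curve$dphase) < 0)
  ph <- stats::spline(curve$ri, curve$dphase, xout = ri,
                      method = if (monotone) "hyman" else "natural")$y
  if (sigma > 0) ph <- ph + .with_seed(seed, stats::rnorm(length(ph), sd = sigma))
  phasogram(time, ph, roi_id = roi_id)
}

#' Reference-solution staircase time course
#'
#' The refractive-index course of a calibration measurement: baseline, then a
#' dwell at each reference solution, returning to baseline.
#'
#' @param refs Reference RIs.
#' @param baseline_ri Baseline buffer RI.
#' @param dwell Dwell time per solution, s.
#' @param dt Sampling interval, s.
#' @return `list(time =, ri =)`.
#' @export
reference_series <- function(refs = reference_ris(), baseline_ri = 1.3340,
                             dwell = 200, dt = 1) {
  levels <- c(baseline_ri, as.vector(rbind(refs, baseline_ri)))
  ri <- rep(levels, each = round(dwell / dt))
  time <- seq_along(ri) * dt
  list(time = time, ri = ri)
}

#' Synthetic binding phasogram
#'
#' Builds a Langmuir 1:1 refractive-index time course (baseline, association,
#' dissociation) on a ground-truth chip and returns the resulting noisy
#' phasogram together with the underlying truth.
#'
#' @param chip A [ground_truth_chip()].
#' @param k_on Association rate constant, M^-1 s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param C Analyte concentration, M.
#' @param dRI_max Saturation refractive-index change, RIU.
#' @param t_baseline,t_assoc,t_dissoc Segment durations, s.
#' @param dt Sampling interval, s.
#' @param baseline_ri Baseline buffer RI.
#' @param sigma Phase noise SD, rad. @param seed RNG seed.
#' @param roi_id ROI identifier.
#' @return List with `phasogram`, `truth` (a [sensorgram()] of the noiseless
#'   delta-RI course) and the segment times `t_assoc_start`, `t_dissoc_start`.
#' @export
make_binding_phasogram <- function(chip, k_on = 4.28e4, k_off = 1.75e-4,
                                   C = 3.984e-8, dRI_max = 5e-4,
                                   t_baseline = 300, t_assoc = 3000,
                                   t_dissoc = 2000, dt = 1,
                                   baseline_ri = 1.3340, sigma = 0.001,
                                   seed = 0L, roi_id = "roi1") {
  stopifnot(inherits(chip, "ground_truth_chip"))
  tau <- k_on * C + k_off
  time <- seq(0, t_baseline + t_assoc + t_dissoc, by = dt)
  t1 <- t_baseline; t2 <- t_baseline + t_assoc
  dri <- numeric(length(time))
  assoc <- time > t1 & time <= t2
  dri[assoc] <- langmuir_association(time[assoc], tau, dRI_max, t_start = t1)
  level <- langmuir_association(t2, tau, dRI_max, t_start = t1)
  diss <- time > t2
  dri[diss] <- langmuir_dissociation(time[diss], k_off, level, t0 = t2)
  pg <- phasogram_from_ri(chip, time, baseline_ri + dri,
                          baseline_ri = baseline_ri, sigma = sigma,
                          seed = seed, roi_id = roi_id)
  list(phasogram = pg, truth = sensorgram(time, dri, roi_id = roi_id),
       t_assoc_start = t1, t_dissoc_start = t2, tau = tau)
}

#' Neighbouring-ROI chip pair
#'
#' Two chips sharing the probe layer but differing slightly in gold thickness
#' and incident angle, emulating two regions of interest of one physical chip
#' (film inhomogeneity and beam-angle variation across the field of view).
#'
#' @param chip Base [ground_truth_chip()].
#' @param d_au_nm Gold thickness offset of the second ROI, nm (default 1.2).
#' @param d_angle Incident-angle offset, degrees (default 0.05).
#' @return List of two [ground_truth_chip()]s.
#' @export
make_roi_pair <- function(chip, d_au_nm = 1.2, d_angle = 0.05) {
  stopifnot(inherits(chip, "ground_truth_chip"))
  list(chip,
       ground_truth_chip(chip$incident_angle + d_angle, chip$au_nm + d_au_nm,
                         chip$probe_nm, chip$probe_ri))
}
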