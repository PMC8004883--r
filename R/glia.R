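# Phase-modulation homodyne interferometer simulation and generalized
# lock-in (GLIA) phase demodulation.
#
# The beating signal is I(t) = I0 (1 + mu sin wt)(1 + m cos(d sin wt - phi)),
# where d is the phase-modulation depth produced by sinusoidal current
# modulation of the VCSEL through a YVO4 birefringent crystal, mu the
# residual amplitude-modulation fraction, m the interference contrast and
# phi the SPR phase to be recovered.  Demodulation multiplies the
# mean-removed signal by the Bessel-matched references cos(d sin wt) and
# sin(d sin wt) and time-averages over integer periods.
#
# The exact time-average quadratures, derived via the Jacobi-Anger
# expansion, are
#   X = (I0 m / 2) { cos(phi) [1 + J0(2d) - 2 J0(d)^2]
#                    + mu sin(phi) [J1(2d) - 2 J0(d) J1(d)] }
#   Y = I0 mu J1(d)
#       + (I0 m / 2) { sin(phi) [1 - J0(2d)] + mu cos(phi) J1(2d) }.
# The I0 mu J1(d) term in Y is the residual-amplitude-modulation error; it
# vanishes exactly when d is tuned to the first zero of J1 (3.8317 rad),
# which is why the instrument operates there.  Phase extraction inverts the
# 2x2 linear system in (cos phi, sin phi) with a two-argument arctangent;
# all common positive scale factors cancel.

#' Phase-modulator configuration
#'
#' Physical parameters of the current-modulated VCSEL + YVO4 crystal phase
#' modulator.  The modulation depth follows
#' `d = 2 pi (ne - no) beta L delta_i / lambda0^2` (magnitude).
#'
#' @param ne,no Extraordinary/ordinary indices of the YVO4 crystal.  The
#'   birefringence is an implementer-chosen fixture (0.2 by default); only
#'   the resulting depth matters.
#' @param L_m Crystal length in metres (about 1 cm).
#' @param beta_nm_per_mA Current modulation efficiency of the VCSEL, nm/mA
#'   (typically about 0.6).
#' @param lambda0_nm Centre wavelength, nm.
#' @param delta_i_mA Modulation current amplitude, mA.
#' @param omega Modulation angular frequency, rad/s.
#' @return An object of class `modulator_config`.
#' @export
modulator_config <- function(ne = 2.15, no = 1.95, L_m = 0.01,
                             beta_nm_per_mA = 0.6, lambda0_nm = 852,
                             delta_i_mA = 0.369, omega = 2 * pi * 1e3) {
  vals <- c(L_m = L_m, beta_nm_per_mA = beta_nm_per_mA,
            lambda0_nm = lambda0_nm, omega = omega)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical modulator fields must be positive and finite")
  if (!is.finite(delta_i_mA) || delta_i_mA < 0)
    stop("'delta_i_mA' must be >= 0")
  structure(list(ne = ne, no = no, L_m = L_m,
                 beta_nm_per_mA = beta_nm_per_mA, lambda0_nm = lambda0_nm,
                 delta_i_mA = delta_i_mA, omega = omega),
            class = "modulator_config")
}

#' Phase-modulation depth of a modulator configuration
#'
#' `d = 2 pi (ne - no) beta L delta_i / lambda0^2` (magnitude; the sign is a
#' convention).  Linear in the modulation current amplitude.
#'
#' @param config A [modulator_config()].
#' @return Modulation depth in rad.
#' @export
modulation_depth <- function(config) {
  stopifnot(inherits(config, "modulator_config"))
  L_nm <- config$L_m * 1e9
  abs(2 * pi * (config$ne - config$no) * config$beta_nm_per_mA * L_nm *
        config$delta_i_mA / config$lambda0_nm^2)
}

#' Modulation depth nulling the first-order Bessel term
#'
#' The smallest positive depth at which `J1` vanishes, i.e. where the
#' residual-amplitude-modulation term of the demodulated quadratures is
#' suppressed.  The instrument tunes its modulation current so the depth sits
#' here (3.8317 rad).
#'
#' @return The first positive zero of `J1`, rad, to ~1e-12.
#' @export
j1_null_depth <- function() {
  stats::uniroot(function(x) besselJ(x, 1), c(3, 4.5), tol = 1e-14)$root
}

#' Simulate the interferometric beating signal
#'
#' Deterministic sampled signal `I0 (1 + mu sin wt)(1 + m cos(d sin wt -
#' phi_spr))` over an integer number of modulation periods, with optional
#' additive Gaussian intensity noise.
#'
#' @param phi_spr SPR phase, rad.
#' @param depth Phase-modulation depth, rad.  Defaults to the depth of
#'   `config`, or to [j1_null_depth()] when no config is given.
#' @param config Optional [modulator_config()]; supplies `depth` and `omega`.
#' @param I0 Intensity scale. @param mu Residual AC/DC intensity-modulation
#'   fraction in `[0, 1]`. @param m Interference contrast in `[0, 1]`.
#' @param n_periods Integer number of modulation periods (>= 1).
#' @param samples_per_period Samples per period (>= 64).
#' @param noise_sd Additive Gaussian intensity noise SD (0 = none).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return An object of class `beating_signal`: `t`, `I`, `omega`, `depth`
#'   and the generator parameters.
#' @export
simulate_beating <- function(phi_spr, depth = NULL, config = NULL,
                             I0 = 1, mu = 0, m = 0.5,
                             n_periods = 4L, samples_per_period = 256L,
                             noise_sd = 0, seed = 0L) {
  if (mu < 0 || mu > 1 || m < 0 || m > 1)
    stop("'mu' and 'm' must lie in [0, 1]")
  if (I0 <= 0) stop("'I0' must be positive")
  if (samples_per_period < 64L) stop("'samples_per_period' must be >= 64")
  if (n_periods < 1L || n_periods != round(n_periods))
    stop("'n_periods' must be a positive integer")
  omega <- if (!is.null(config)) config$omega else 2 * pi * 1e3
  if (is.null(depth))
    depth <- if (!is.null(config)) modulation_depth(config) else j1_null_depth()
  Tper <- 2 * pi / omega
  nt <- as.integer(n_periods * samples_per_period)
  t <- seq(0, n_periods * Tper, length.out = nt + 1L)[seq_len(nt)]
  I <- I0 * (1 + mu * sin(omega * t)) *
       (1 + m * cos(depth * sin(omega * t) - phi_spr))
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    I <- I + stats::rnorm(nt, sd = noise_sd)
  }
  structure(list(t = t, I = I, omega = omega, depth = depth,
                 I0 = I0, mu = mu, m = m, phi_spr = phi_spr),
            class = "beating_signal")
}

#' GLIA lock-in quadratures of a beating signal
#'
#' Removes the mean (exact high-pass over integer periods) and time-averages
#' the signal against the Bessel-matched references `cos(depth sin wt)` and
#' `sin(depth sin wt)`.
#'
#' @param signal A [simulate_beating()] result (or a list with `t`, `I`,
#'   `omega`).
#' @param depth Demodulation reference depth, rad (defaults to the signal's
#'   own depth when present).
#' @return An object of class `lockin_result` with quadratures `X`, `Y` and
#'   the reference `depth`.
#' @export
lockin_xy <- function(signal, depth = NULL) {
  if (is.null(signal$t) || is.null(signal$I) || is.null(signal$omega))
    stop("'signal' must carry t, I and omega")
  if (is.null(depth)) depth <- signal$depth
  if (is.null(depth)) stop("'depth' is required")
  t <- signal$t
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("non-uniform sampling")
  span <- (length(t)) * dt[1] * signal$omega / (2 * pi)
  if (abs(span - round(span)) > 1e-6)
    stop(sprintf("signal covers %.4f modulation periods; integer coverage is required (averaging bias)", span))
  Itil <- signal$I - mean(signal$I)
  wt <- signal$omega * t
  X <- mean(Itil * cos(depth * sin(wt)))
  Y <- mean(Itil * sin(depth * sin(wt)))
  structure(list(X = X, Y = Y, depth = depth), class = "lockin_result")
}

#' Exact closed-form GLIA quadratures
#'
#' The analytic time averages of the mean-removed beating signal times the
#' lock-in references, used by [extract_phase()] to derive inversion
#' coefficients and available as an oracle for the numeric path.
#'
#' @param phi_spr SPR phase, rad. @param depth Modulation depth, rad.
#' @param I0,mu,m Signal parameters as in [simulate_beating()].
#' @return List with `X` and `Y`.
#' @export
glia_quadratures <- function(phi_spr, depth, I0 = 1, mu = 0, m = 0.5) {
  J0d <- besselJ(depth, 0); J1d <- besselJ(depth, 1)
  J02d <- besselJ(2 * depth, 0); J12d <- besselJ(2 * depth, 1)
  A  <- 1 + J02d - 2 * J0d^2
  BX <- J12d - 2 * J0d * J1d
  D  <- 1 - J02d
  BY <- J12d
  list(
    X = (I0 * m / 2) * (cos(phi_spr) * A + mu * sin(phi_spr) * BX),
    Y = I0 * mu * J1d +
        (I0 * m / 2) * (sin(phi_spr) * D + mu * cos(phi_spr) * BY)
  )
}

#' Extract the SPR phase from lock-in quadratures
#'
#' Inverts the closed-form quadratures for `phi_spr` with a two-argument
#' arctangent; invariant to rescaling `(X, Y)` by any positive constant.  The
#' residual-amplitude-modulation offset in `Y` is uncorrected (it requires
#' the unknown intensity scale), so accuracy requires the depth to sit near
#' the `J1` null -- which is the instrument's operating point.
#'
#' @param result A [lockin_xy()] result (or list with `X`, `Y`).
#' @param depth Modulation depth, rad (defaults to the result's own).
#' @param mu Known residual amplitude-modulation fraction (configuration
#'   constant; default 0).
#' @return Phase in `(-pi, pi]`, rad.
#' @export
extract_phase <- function(result, depth = NULL, mu = 0) {
  if (is.null(depth)) depth <- result$depth
  if (is.null(depth)) stop("'depth' is required")
  X <- result$X; Y <- result$Y
  if (X == 0 && Y == 0) stop("degenerate quadratures: X = Y = 0")
  J0d <- besselJ(depth, 0); J1d <- besselJ(depth, 1)
  J02d <- besselJ(2 * depth, 0); J12d <- besselJ(2 * depth, 1)
  A  <- 1 + J02d - 2 * J0d^2
  BX <- J12d - 2 * J0d * J1d
  D  <- 1 - J02d
  BY <- J12d
  det <- A * D - mu^2 * BX * BY
  if (det <= 0) stop("ill-conditioned inversion: A*D - mu^2*BX*BY <= 0")
  co <- D * X - mu * BX * Y
  si <- A * Y - mu * BY * X
  atan2(si, co)
}

#' Simulate-demodulate-extract round trip
#'
#' Convenience wrapper chaining [simulate_beating()], [lockin_xy()] and
#' [extract_phase()]; returns the recovered phase.
#'
#' @inheritParams simulate_beating
#' @return Recovered phase, rad.
#' @export
glia_roundtrip <- function(phi_spr, depth = NULL, mu = 0, m = 0.5,
                           I0 = 1, n_periods = 1L, samples_per_period = 256L,
                           noise_sd = 0, seed = 0L) {
  sig <- simulate_beating(phi_spr, depth = depth, I0 = I0, mu = mu, m = m,
                          n_periods = n_periods,
                          samples_per_period = samples_per_period,
                          noise_sd = noise_sd, seed = seed)
  extract_phase(lockin_xy(sig), mu = mu)
}
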