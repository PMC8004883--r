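# Langmuir 1:1 binding kinetics on sensorgram segments.
#
# Association: dS(t) = dS_max (1 - exp(-tau (t - t_start))), with observed
# rate tau = kon * C + koff.  Dissociation: dS(t) = dS0 exp(-koff (t - t0)).
# Both models are linear in their amplitude, so fitting uses variable
# projection: the amplitude is profiled out analytically and the rate found
# by a 1-D bracketed search refined by Newton steps on the projected
# gradient.  On noiseless data this recovers generating parameters to
# machine precision (stats::nls stops with an error on exactly
# zero-residual data, hence the hand-rolled solver).

.kin_xy <- function(x, t_ref, value_col) {
  if (inherits(x, "sensorgram") || (is.data.frame(x) && "ri" %in% names(x))) {
    list(t = x$time_s, y = x$ri)
  } else if (is.data.frame(x) && "phase_rad" %in% names(x)) {
    list(t = x$time_s, y = x$phase_rad)
  } else if (is.list(x) && !is.null(x$time) && !is.null(x$signal)) {
    list(t = x$time, y = x$signal)
  } else stop("'x' must be a sensorgram, a data frame, or list(time=, signal=)")
}

# variable-projection fit of y ~ a * g(theta); returns rate after Newton
# polish of the projected gradient G(theta) = sum(r * a * dg/dtheta) = 0
.varpro_fit <- function(u, y, gfun, dgfun, theta0, lower, upper) {
  amp <- function(th) { g <- gfun(u, th); sum(g * y) / sum(g * g) }
  ssr <- function(th) { g <- gfun(u, th); a <- sum(g * y) / sum(g * g); sum((y - a * g)^2) }
  opt <- stats::optimize(function(l) ssr(exp(l)), c(log(lower), log(upper)),
                         tol = 1e-12)
  th <- exp(opt$minimum)
  grad <- function(th) {
    g <- gfun(u, th); a <- sum(g * y) / sum(g * g)
    r <- y - a * g
    sum(r * dgfun(u, th)) * a
  }
  # Newton via secant on the gradient (quadratic at a zero-residual optimum)
  h <- 1e-6 * th
  for (i in 1:60) {
    g0 <- grad(th)
    dg <- (grad(th + h) - grad(th - h)) / (2 * h)
    if (!is.finite(dg) || dg == 0) break
    step <- g0 / dg
    step <- max(min(step, 0.5 * th), -0.5 * th)
    th_new <- min(max(th - step, lower), upper)
    if (abs(th_new - th) < 1e-15 * th) { th <- th_new; break }
    th <- th_new
    h <- 1e-7 * th
  }
  list(theta = th, amplitude = amp(th), ssr = ssr(th))
}

#' Fit Langmuir association kinetics
#'
#' Nonlinear least squares of `dS(t) = dS_max (1 - exp(-tau (t - t_start)))`
#' on a rising sensorgram segment.  Deterministic: the initial rate guess is
#' `1 / (time to reach 63.2% of the final level)` and the amplitude is
#' profiled out analytically.
#'
#' @param x A [sensorgram()], a data frame with `time_s` and `ri`, or
#'   `list(time =, signal =)`.
#' @param t_start Start time of the association (default: first sample).
#' @return List with `tau` (s^-1), `dS_max`, `ssr`, `fitted`, `residuals`.
#' @export
fit_association <- function(x, t_start = NULL) {
  d <- .kin_xy(x)
  if (is.null(t_start)) t_start <- d$t[1]
  sel <- d$t >= t_start
  t <- d$t[sel]; y <- d$y[sel]
  if (length(t) < 10) stop("association segment needs at least 10 points")
  u <- t - t_start
  a0 <- y[length(y)]
  if (!(a0 > y[1])) stop("segment is not rising; association fit refused")
  i63 <- which(y - y[1] >= 0.632 * (a0 - y[1]))[1]
  tau0 <- if (!is.na(i63) && u[i63] > 0) 1 / u[i63] else 1 / (max(u) / 3)
  fit <- .varpro_fit(u, y,
                     gfun = function(u, th) 1 - exp(-th * u),
                     dgfun = function(u, th) u * exp(-th * u),
                     theta0 = tau0, lower = tau0 / 1e3, upper = tau0 * 1e3)
  g <- 1 - exp(-fit$theta * u)
  list(tau = fit$theta, dS_max = fit$amplitude, ssr = fit$ssr,
       fitted = fit$amplitude * g, residuals = y - fit$amplitude * g,
       t_start = t_start)
}

#' Fit Langmuir dissociation kinetics
#'
#' Least squares of the single exponential `dS(t) = dS0 exp(-koff (t - t0))`
#' on a decaying segment.  A log-linear regression provides the start (exact
#' on noiseless data); variable-projection Newton steps refine it.  Segments
#' with no measurable decay return `k_off = 0` flagged `no_decay`.
#'
#' @param x As in [fit_association()].
#' @param t0 Dissociation start time (default: first sample).
#' @return List with `k_off` (s^-1), `dS0`, `ssr`, `fitted`, `residuals`,
#'   `no_decay` flag.
#' @export
fit_dissociation <- function(x, t0 = NULL) {
  d <- .kin_xy(x)
  if (is.null(t0)) t0 <- d$t[1]
  sel <- d$t >= t0
  t <- d$t[sel]; y <- d$y[sel]
  if (length(t) < 10) stop("dissociation segment needs at least 10 points")
  u <- t - t0
  rel_drop <- (y[1] - y[length(y)]) / max(abs(y[1]), .Machine$double.eps)
  if (rel_drop < 1e-10) {
    return(list(k_off = 0, dS0 = mean(y), ssr = sum((y - mean(y))^2),
                fitted = rep(mean(y), length(y)), residuals = y - mean(y),
                no_decay = TRUE, t0 = t0))
  }
  k0 <- if (all(y > 0)) {
    max(-stats::coef(stats::lm(log(y) ~ u))[[2]], 1e-12)
  } else 3 / max(u)
  fit <- .varpro_fit(u, y,
                     gfun = function(u, th) exp(-th * u),
                     dgfun = function(u, th) -u * exp(-th * u),
                     theta0 = k0, lower = k0 / 1e3, upper = k0 * 1e3)
  g <- exp(-fit$theta * u)
  list(k_off = fit$theta, dS0 = fit$amplitude, ssr = fit$ssr,
       fitted = fit$amplitude * g, residuals = y - fit$amplitude * g,
       no_decay = FALSE, t0 = t0)
}

#' Derive kinetic constants from fitted rates
#'
#' From the observed association rate `tau = kon C + koff`, the dissociation
#' constant `koff` and the analyte molar concentration `C`:
#' `kon = (tau - koff) / C` and `K_D = koff / kon`.
#'
#' @param tau Observed association rate, s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param C Analyte concentration, M.
#' @return List with `k_on` (M^-1 s^-1) and `K_D` (M).
#' @export
derive_constants <- function(tau, k_off, C) {
  if (C <= 0) stop("'C' must be positive")
  if (k_off < 0) stop("'k_off' must be >= 0")
  if (tau <= k_off)
    stop("tau <= k_off: the fitted rates are inconsistent with the stated concentration")
  k_on <- (tau - k_off) / C
  list(k_on = k_on, K_D = k_off / k_on)
}

#' Langmuir signal generators
#'
#' Noiseless association / dissociation time courses used by the synthetic
#' fixtures and the kinetics tests.
#'
#' @param t Times, s. @param tau Association rate, s^-1. @param dS_max
#'   Equilibrium amplitude. @param t_start Association start, s.
#' @return Signal values.
#' @export
langmuir_association <- function(t, tau, dS_max, t_start = 0) {
  dS_max * (1 - exp(-tau * pmax(t - t_start, 0)))
}

#' @rdname langmuir_association
#' @param k_off Dissociation rate, s^-1. @param dS0 Level at the start of
#'   dissociation. @param t0 Dissociation start, s.
#' @export
langmuir_dissociation <- function(t, k_off, dS0, t0 = 0) {
  dS0 * exp(-k_off * pmax(t - t0, 0))
}
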