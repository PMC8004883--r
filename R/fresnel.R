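# Multilayer Fresnel reflectivity of a Kretschmann stack.
#
# Conventions: angles are degrees at the user interface and radians
# internally; complex layer cosines are used directly (never real-valued
# refraction angles) with the branch Im(k_z) >= 0, so evanescent and
# absorbed waves decay into the stack.  The modeled observable downstream
# is the p-s differential reflected phase, baseline-referenced, so the
# global phase sign convention is immaterial.

#' Create an optical layer
#'
#' A single stratum of a planar multilayer: a complex refractive index and a
#' thickness in nanometres.  Semi-infinite bounding media (the coupling prism
#' and the sensing buffer) use `thickness_nm = Inf`.
#'
#' @param label Character name of the layer (e.g. `"gold"`).
#' @param n Complex (or real) refractive index; `Im(n) >= 0` (absorbing
#'   convention).
#' @param thickness_nm Thickness in nm (`>= 0`), or `Inf` for a semi-infinite
#'   bounding medium.
#' @return An object of class `optical_layer`.
#' @examples
#' optical_layer("gold", 0.16 + 5.34i, 48)
#' @export
optical_layer <- function(label, n, thickness_nm) {
  n <- as.complex(n)
  if (!is.character(label) || length(label) != 1L) stop("'label' must be a single string")
  if (length(n) != 1L || !is.finite(Re(n)) || !is.finite(Im(n)))
    stop("layer '", label, "': refractive index must be a finite complex scalar")
  if (Im(n) < 0) stop("layer '", label, "': Im(n) must be >= 0 (absorbing convention)")
  if (length(thickness_nm) != 1L || is.na(thickness_nm))
    stop("layer '", label, "': thickness must be a scalar")
  if (!is.infinite(thickness_nm) && thickness_nm < 0)
    stop("layer '", label, "': negative thickness")
  structure(list(label = label, n = n, thickness_nm = as.numeric(thickness_nm)),
            class = "optical_layer")
}

#' Create an optical stack
#'
#' Ordered layers from the incidence medium (prism) to the exit medium
#' (buffer).  Exactly the first and last layers must be semi-infinite.
#'
#' @param layers List of [optical_layer()] objects, prism first.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @return An object of class `optical_stack`.
#' @seealso [default_chip_stack()] for the standard five-layer sensor model.
#' @export
optical_stack <- function(layers, wavelength_nm = 850) {
  if (!is.list(layers) || length(layers) < 2L) stop("a stack needs at least 2 layers")
  if (!all(vapply(layers, inherits, logical(1), "optical_layer")))
    stop("all elements of 'layers' must be optical_layer objects")
  th <- vapply(layers, `[[`, numeric(1), "thickness_nm")
  n_inf <- sum(is.infinite(th))
  if (!is.infinite(th[1]) || !is.infinite(th[length(th)]) || n_inf != 2L)
    stop("exactly the first and last layers must be semi-infinite (thickness Inf); ",
         "found ", n_inf, " semi-infinite markers")
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L || wavelength_nm <= 0)
    stop("'wavelength_nm' must be a positive scalar")
  structure(list(layers = layers, wavelength_nm = as.numeric(wavelength_nm)),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat("Optical stack,", length(x$layers), "layers @", x$wavelength_nm, "nm\n")
  for (l in x$layers)
    cat(sprintf("  %-10s n = %.4g%+.4gi  %s\n", l$label, Re(l$n), Im(l$n),
                if (is.infinite(l$thickness_nm)) "semi-infinite"
                else paste0(format(l$thickness_nm), " nm")))
  invisible(x)
}

#' Default five-layer sensor chip stack
#'
#' The standard pSPR chip model: BK7 prism (n = 1.51), chromium adhesion
#' layer (3.24+3.49i, 2 nm), gold film (0.16+5.34i), an effective probe
#' layer, and the semi-infinite sensing buffer, at 850 nm.  A probe layer of
#' zero thickness is permitted (bare chip).
#'
#' @param au_nm Gold film thickness, nm (nominal deposition 48 nm).
#' @param probe_nm Effective probe (receptor) layer thickness, nm.
#' @param probe_ri Effective probe layer refractive index.
#' @param buffer_ri Sensing buffer refractive index.
#' @param cr_nm Chromium adhesion layer thickness, nm.
#' @param wavelength_nm Vacuum wavelength, nm.
#' @return An [optical_stack()].
#' @export
default_chip_stack <- function(au_nm = 48, probe_nm = 0, probe_ri = 1.40,
                               buffer_ri = 1.3344, cr_nm = 2, wavelength_nm = 850) {
  optical_stack(list(
    optical_layer("prism",  1.51 + 0i, Inf),
    optical_layer("chromium", 3.24 + 3.49i, cr_nm),
    optical_layer("gold",   0.16 + 5.34i, au_nm),
    optical_layer("probe",  probe_ri + 0i, probe_nm),
    optical_layer("buffer", buffer_ri + 0i, Inf)
  ), wavelength_nm = wavelength_nm)
}

# normal component of the wave vector in each layer, branch Im(kz) >= 0
.kz <- function(n, beta, k0) {
  kz <- k0 * sqrt(n^2 - beta^2 + 0i)
  flip <- Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

.check_angle <- function(theta_deg) {
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0) || any(theta_deg >= 90))
    stop("incident angle must lie in (0, 90) degrees")
  theta_deg * pi / 180
}

#' Single-interface Fresnel amplitude coefficients
#'
#' Amplitude reflection coefficient of a single interface for p- or
#' s-polarized light, with the transmitted-side cosine obtained from Snell's
#' law using complex indices (branch chosen so the transmitted wave decays).
#' Sign convention matches the characteristic-matrix formulation used by
#' [stack_reflectivity()]: at normal incidence both polarizations give
#' `(n_out - n_in) / (n_out + n_in)`.
#'
#' @param n_in,n_out Complex refractive indices of the incidence and
#'   transmission media.
#' @param theta_in_deg Incidence angle in degrees (may be complex).
#' @return Complex amplitude reflection coefficient.
#' @examples
#' Mod(interface_rp(1.0, 1.5, 0.001)) # ~0.2
#' @export
interface_rp <- function(n_in, n_out, theta_in_deg) {
  .interface_r(n_in, n_out, theta_in_deg, pol = "p")
}

#' @rdname interface_rp
#' @export
interface_rs <- function(n_in, n_out, theta_in_deg) {
  .interface_r(n_in, n_out, theta_in_deg, pol = "s")
}

.interface_r <- function(n_in, n_out, theta_in_deg, pol) {
  n_in <- as.complex(n_in); n_out <- as.complex(n_out)
  if (any(!is.finite(Re(n_in)) | !is.finite(Im(n_in)) |
          !is.finite(Re(n_out)) | !is.finite(Im(n_out))))
    stop("non-finite refractive index")
  if (any(n_in == 0) || any(n_out == 0)) stop("refractive indices must be nonzero")
  th <- as.complex(theta_in_deg) * pi / 180
  if (any(!is.finite(Re(th)) | !is.finite(Im(th)))) stop("non-finite angle")
  cos_i <- cos(th)
  # transmitted cosine via Snell, decaying branch: Im(n_out * cos_t) >= 0
  sin_t <- n_in * sin(th) / n_out
  cos_t <- sqrt(1 - sin_t^2)
  kz_out <- n_out * cos_t
  flip <- Im(kz_out) < 0 | (Im(kz_out) == 0 & Re(kz_out) < 0)
  cos_t[flip] <- -cos_t[flip]
  if (pol == "p") {
    (n_out * cos_i - n_in * cos_t) / (n_out * cos_i + n_in * cos_t)
  } else {
    (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t)
  }
}

# core scan engine: characteristic (transfer) matrix reflectivity.
# n: complex matrix [n_scan x n_layers]; d: thickness vector (nm, Inf at ends);
# theta_deg scalar or length n_scan.  Returns complex amplitude r for one
# polarization, vectorized over the scan dimension.
.tm_reflect <- function(n, d, wavelength_nm, theta_deg, pol) {
  th <- .check_angle(theta_deg)
  k0 <- 2 * pi / wavelength_nm
  nl <- ncol(n)
  beta <- n[, 1] * sin(th)
  q1 <- NULL; qN <- NULL
  m11 <- m22 <- rep(1 + 0i, nrow(n)); m12 <- m21 <- rep(0 + 0i, nrow(n))
  for (j in seq_len(nl)) {
    kz <- .kz(n[, j], beta, k0)
    q <- if (pol == "p") kz / (k0 * n[, j]^2) else kz / k0
    if (j == 1L) { q1 <- q; next }
    if (j == nl) { qN <- q; break }
    delta <- kz * (d[j] * 1)               # d in nm, kz in 1/nm
    cd <- cos(delta); sd <- sin(delta)
    a11 <- cd;            a12 <- -1i * sd / q
    a21 <- -1i * q * sd;  a22 <- cd
    t11 <- m11 * a11 + m12 * a21; t12 <- m11 * a12 + m12 * a22
    t21 <- m21 * a11 + m22 * a21; t22 <- m21 * a12 + m22 * a22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  num <- (m11 + m12 * qN) * q1 - (m21 + m22 * qN)
  den <- (m11 + m12 * qN) * q1 + (m21 + m22 * qN)
  num / den
}

# build the [scan x layers] index matrix and thickness vector from a stack;
# optionally override the exit-medium (buffer) index with a scan vector.
.stack_arrays <- function(stack, buffer_ri = NULL, n_scan = 1L) {
  n <- vapply(stack$layers, `[[`, complex(1), "n")
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness_nm")
  if (!is.null(buffer_ri)) n_scan <- length(buffer_ri)
  nm <- matrix(rep(n, each = n_scan), nrow = n_scan)
  if (!is.null(buffer_ri)) nm[, length(n)] <- as.complex(buffer_ri)
  list(n = nm, d = d)
}

#' Full-stack complex reflectivity
#'
#' Computes the complex p- and s-polarization amplitude reflection
#' coefficients of an [optical_stack()] by the characteristic-matrix method,
#' together with reflectances and reflected phases.  Vectorized over the
#' incident angle.
#'
#' @param stack An [optical_stack()].
#' @param theta_deg Incident angle(s) in the prism, degrees, in (0, 90).
#' @return A data frame of class `complex_reflectivity` with columns
#'   `theta_deg`, `r_p`, `r_s` (complex), `R_p`, `R_s` (reflectance),
#'   `phi_p`, `phi_s` (rad, in (-pi, pi]) and `phi_diff = phi_p - phi_s`.
#' @examples
#' st <- default_chip_stack()
#' rf <- stack_reflectivity(st, seq(60, 75, by = 0.5))
#' rf$theta_deg[which.min(rf$R_p)] # resonance dip
#' @export
stack_reflectivity <- function(stack, theta_deg) {
  stopifnot(inherits(stack, "optical_stack"))
  arr <- .stack_arrays(stack, n_scan = length(theta_deg))
  rp <- .tm_reflect(arr$n, arr$d, stack$wavelength_nm, theta_deg, "p")
  rs <- .tm_reflect(arr$n, arr$d, stack$wavelength_nm, theta_deg, "s")
  out <- data.frame(theta_deg = theta_deg, R_p = Mod(rp)^2, R_s = Mod(rs)^2,
                    phi_p = Arg(rp), phi_s = Arg(rs),
                    phi_diff = .wrap_pi(Arg(rp) - Arg(rs)))
  out$r_p <- rp; out$r_s <- rs
  class(out) <- c("complex_reflectivity", "data.frame")
  out
}

#' Full-stack reflectivity by recursive interface-by-interface Fresnel
#'
#' Independent route to the same quantities as [stack_reflectivity()]: the
#' stack is reduced from the exit medium upward with the recursion
#' `r_j = (rho_j + r_{j+1} e^{2 i delta_{j+1}}) / (1 + rho_j r_{j+1}
#' e^{2 i delta_{j+1}})`, where `rho_j` is the single-interface coefficient
#' and `delta` the layer phase thickness.  Used as a structural cross-check
#' of the matrix implementation; the two agree to ~1e-12.
#'
#' @inheritParams stack_reflectivity
#' @return Same shape as [stack_reflectivity()].
#' @export
stack_reflectivity_recursive <- function(stack, theta_deg) {
  stopifnot(inherits(stack, "optical_stack"))
  th <- .check_angle(theta_deg)
  k0 <- 2 * pi / stack$wavelength_nm
  n <- vapply(stack$layers, `[[`, complex(1), "n")
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness_nm")
  nl <- length(n)
  one_pol <- function(pol) {
    sapply(th, function(t1) {
      beta <- n[1] * sin(t1)
      kz <- .kz(n, rep(beta, nl), k0)
      q <- if (pol == "p") kz / (k0 * n^2) else kz / k0
      r <- (q[nl - 1] - q[nl]) / (q[nl - 1] + q[nl])
      if (nl > 2) for (j in seq(nl - 2, 1)) {
        rho <- (q[j] - q[j + 1]) / (q[j] + q[j + 1])
        ph <- exp(2i * kz[j + 1] * d[j + 1])
        r <- (rho + r * ph) / (1 + rho * r * ph)
      }
      r
    })
  }
  rp <- one_pol("p"); rs <- one_pol("s")
  out <- data.frame(theta_deg = theta_deg, R_p = Mod(rp)^2, R_s = Mod(rs)^2,
                    phi_p = Arg(rp), phi_s = Arg(rs),
                    phi_diff = .wrap_pi(Arg(rp) - Arg(rs)))
  out$r_p <- rp; out$r_s <- rs
  class(out) <- c("complex_reflectivity", "data.frame")
  out
}

.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# unwrap by nearest-branch continuation
.unwrap <- function(phi) {
  dp <- diff(phi)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(phi[1], dp))
}

#' Locate the p-polarization resonance dip
#'
#' Dense angle scan for the minimum of `R_p`; a convenience for choosing
#' operating angles and optimization bounds.
#'
#' @param stack An [optical_stack()].
#' @param range Angle search interval, degrees.
#' @param n Number of scan points.
#' @return Dip angle in degrees.
#' @export
resonance_angle <- function(stack, range = c(55, 85), n = 2001) {
  ang <- seq(range[1], range[2], length.out = n)
  rf <- stack_reflectivity(stack, ang)
  i <- which.min(rf$R_p)
  # parabolic refinement around the discrete minimum
  if (i > 1 && i < n) {
    y <- rf$R_p[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom > 0) return(ang[i] + 0.5 * (y[1] - y[3]) / denom * (ang[2] - ang[1]))
  }
  ang[i]
}

#' Differential phase versus buffer refractive index
#'
#' The sensor's phase mapping curve: the unwrapped p-s differential reflected
#' phase of the stack as a function of the buffer refractive index, referenced
#' so that `dphase(baseline_ri) = 0`.  Continuity across the grid is enforced
#' by nearest-branch unwrapping; if any adjacent step exceeds pi/2 the grid is
#' automatically refined (doubled, up to `max_refine` times).
#'
#' @param stack An [optical_stack()]; its buffer layer index is replaced by
#'   each grid value.
#' @param theta_deg Fixed incident angle, degrees.
#' @param ri_grid Strictly increasing buffer refractive indices.
#' @param baseline_ri Baseline (running buffer) refractive index; must lie
#'   within the grid range.
#' @param max_refine Maximum number of grid-doubling refinements.
#' @return A [mapping_curve()] object.
#' @export
phase_vs_ri <- function(stack, theta_deg, ri_grid, baseline_ri,
                        max_refine = 6L) {
  stopifnot(inherits(stack, "optical_stack"))
  if (is.unsorted(ri_grid, strictly = TRUE)) stop("'ri_grid' must be strictly increasing")
  if (baseline_ri < ri_grid[1] || baseline_ri > ri_grid[length(ri_grid)])
    stop("'baseline_ri' must lie within the grid range")
  grid <- ri_grid
  for (pass in 0:max_refine) {
    phi <- .phase_diff_at(stack, theta_deg, grid)
    step <- diff(phi)
    step <- step - 2 * pi * round(step / (2 * pi))
    if (max(abs(step)) <= pi / 2) {
      unwr <- cumsum(c(phi[1], step))
      # exact baseline value, branch-aligned to the nearest grid point
      phib <- .phase_diff_at(stack, theta_deg, baseline_ri)
      i0 <- which.min(abs(grid - baseline_ri))
      phib <- phib + 2 * pi * round((unwr[i0] - phib) / (2 * pi))
      dph <- unwr - phib
      # when refinement was needed, the refined grid is reported: the
      # requested points alone could not carry a continuous curve
      return(mapping_curve(grid, dph, baseline_ri))
    }
    # refine: double density, keeping original points so values can be reported
    mid <- (grid[-1] + grid[-length(grid)]) / 2
    grid <- sort(unique(c(grid, mid)))
  }
  stop("phase grid too coarse to unwrap (adjacent jump > pi/2 after ",
       max_refine, " refinements); supply a finer 'ri_grid'")
}

# p-s differential phase (wrapped) at given buffer RIs, fixed angle
.phase_diff_at <- function(stack, theta_deg, buffer_ri) {
  arr <- .stack_arrays(stack, buffer_ri = buffer_ri)
  rp <- .tm_reflect(arr$n, arr$d, stack$wavelength_nm, theta_deg, "p")
  rs <- .tm_reflect(arr$n, arr$d, stack$wavelength_nm, theta_deg, "s")
  Arg(rp) - Arg(rs)
}
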