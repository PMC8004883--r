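# Segmented-cubic meta-model of a Fresnel phase-vs-RI curve.
#
# The sampled curve is split into contiguous chunks of (near-)equal point
# count; each chunk gets an ordinary least-squares cubic in a scaled local
# coordinate u = (ri - center)/halfspan for conditioning (the raw RI axis
# spans ~1e-3 around 1.334, hopeless for a raw cubic).  No smoothness
# constraints are imposed across joints; joint mismatch is monitored instead.

#' Create a mapping curve
#'
#' A sampled, baseline-referenced, unwrapped differential-phase curve
#' `dphase(ri)`, usually produced by [phase_vs_ri()].
#'
#' @param ri Strictly increasing refractive indices (RIU).
#' @param dphase Baseline-referenced unwrapped phase shifts (rad); no adjacent
#'   jump may exceed pi.
#' @param baseline_ri Baseline refractive index (where `dphase` is 0).
#' @return An object of class `mapping_curve`.
#' @export
mapping_curve <- function(ri, dphase, baseline_ri) {
  if (length(ri) != length(dphase)) stop("'ri' and 'dphase' lengths differ")
  if (is.unsorted(ri, strictly = TRUE)) stop("'ri' must be strictly increasing")
  if (any(!is.finite(ri)) || any(!is.finite(dphase))) stop("non-finite curve values")
  if (length(ri) >= 2 && max(abs(diff(dphase))) > pi)
    stop("curve is discontinuous: adjacent phase jump exceeds pi")
  if (baseline_ri < ri[1] || baseline_ri > ri[length(ri)])
    stop("'baseline_ri' outside the curve's RI range")
  structure(list(ri = as.numeric(ri), dphase = as.numeric(dphase),
                 baseline_ri = as.numeric(baseline_ri)),
            class = "mapping_curve")
}

#' @export
print.mapping_curve <- function(x, ...) {
  cat(sprintf("Mapping curve: %d samples, RI [%.5f, %.5f], phase span %.3f rad, baseline %.5f\n",
              length(x$ri), min(x$ri), max(x$ri), diff(range(x$dphase)), x$baseline_ri))
  invisible(x)
}

# near-equal contiguous chunk sizes (differ by at most 1)
.chunk_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' Build a segmented-cubic meta-model
#'
#' Fits `n_segments` polynomial segments of degree `order` to a mapping curve
#' by least squares on contiguous chunks of (near-)equal point count.  The
#' default three cubic segments form the invertible phase-to-RI surrogate
#' used throughout calibration and conversion.
#'
#' @param curve A [mapping_curve()].
#' @param n_segments Number of segments (default 3).
#' @param order Polynomial degree per segment (default 3).
#' @return An object of class `segmented_cubic` with elements `segments`
#'   (per-segment domain, scaling and ascending-power coefficients),
#'   `breaks`, `phase_range`, `ri_range`, `working_ri_range` (largest
#'   monotone run of the sampled curve containing the baseline),
#'   `baseline_ri`, `max_residual`, `ssr_fit` and `joint_gap`.
#' @export
build_metamodel <- function(curve, n_segments = 3L, order = 3L) {
  stopifnot(inherits(curve, "mapping_curve"))
  n <- length(curve$ri)
  if (n < n_segments * (order + 1))
    stop("insufficient points: need at least ", n_segments * (order + 1),
         ", got ", n)
  monotone <- all(diff(curve$dphase) > 0) || all(diff(curve$dphase) < 0)
  sizes <- .chunk_sizes(n, n_segments)
  idx <- split(seq_len(n), rep(seq_len(n_segments), sizes))
  resid <- numeric(0)
  segments <- vector("list", n_segments)
  for (j in seq_len(n_segments)) {
    ii <- idx[[j]]
    x <- curve$ri[ii]; y <- curve$dphase[ii]
    center <- mean(range(x)); halfspan <- diff(range(x)) / 2
    u <- (x - center) / halfspan
    X <- outer(u, 0:order, `^`)
    coef <- qr.solve(X, y)
    fit <- drop(X %*% coef)
    resid <- c(resid, y - fit)
    segments[[j]] <- list(ri_lo = min(x), ri_hi = max(x),
                          center = center, halfspan = halfspan,
                          coef = as.numeric(coef))
  }
  # contiguous domains: the break between adjacent segments sits where the
  # two fitted cubics cross (searched near the chunk boundary), which makes
  # the piecewise surrogate continuous and uniquely invertible; if they do
  # not cross there, fall back to the midpoint and monitor the joint gap.
  eval_raw <- function(s, ri) {
    u <- (ri - s$center) / s$halfspan
    drop(outer(u, 0:order, `^`) %*% s$coef)
  }
  breaks <- vapply(seq_len(n_segments - 1), function(j) {
    a <- segments[[j]]; b <- segments[[j + 1]]
    lo <- a$ri_lo + 0.75 * (a$ri_hi - a$ri_lo)
    hi <- b$ri_lo + 0.25 * (b$ri_hi - b$ri_lo)
    mid <- (a$ri_hi + b$ri_lo) / 2
    gr <- seq(lo, hi, length.out = 65)
    dd <- eval_raw(a, gr) - eval_raw(b, gr)
    sc <- which(dd[-1] * dd[-length(dd)] <= 0)
    if (length(sc) == 0) return(mid)
    i <- sc[which.min(abs(gr[sc] - mid))]
    if (dd[i] == 0) return(gr[i])
    stats::uniroot(function(r) eval_raw(a, r) - eval_raw(b, r),
                   c(gr[i], gr[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  for (j in seq_len(n_segments)) {
    segments[[j]]$dom_lo <- if (j == 1) curve$ri[1] else breaks[j - 1]
    segments[[j]]$dom_hi <- if (j == n_segments) curve$ri[n] else breaks[j]
  }
  # working branch: largest monotone run containing the baseline
  working <- .monotone_run(curve)
  model <- structure(list(
    segments = segments, breaks = breaks,
    n_segments = as.integer(n_segments), order = as.integer(order),
    baseline_ri = curve$baseline_ri,
    ri_range = range(curve$ri),
    phase_range = range(curve$dphase),
    working_ri_range = working,
    monotone = monotone,
    max_residual = max(abs(resid)),
    ssr_fit = sum(resid^2)
  ), class = "segmented_cubic")
  model$joint_gap <- if (n_segments > 1)
    max(abs(vapply(breaks, function(b)
      .eval_segment(model, b, .segment_of(model, b)) -
      .eval_segment(model, b, .segment_of(model, b) + 1L), numeric(1))))
  else 0
  model
}

#' @export
print.segmented_cubic <- function(x, ...) {
  cat(sprintf("Segmented cubic meta-model: %d segments (order %d)\n",
              x$n_segments, x$order))
  cat(sprintf("  RI domain [%.5f, %.5f], phase range [%.4f, %.4f] rad\n",
              x$ri_range[1], x$ri_range[2], x$phase_range[1], x$phase_range[2]))
  cat(sprintf("  fit: max|resid| %.3g rad, SSR %.3g rad^2, joint gap %.3g rad\n",
              x$max_residual, x$ssr_fit, x$joint_gap))
  invisible(x)
}

.monotone_run <- function(curve) {
  s <- sign(diff(curve$dphase))
  s[s == 0] <- 1
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  i0 <- which.min(abs(curve$ri - curve$baseline_ri))
  for (k in seq_along(runs$lengths)) {
    lo <- starts[k]; hi <- ends[k] + 1   # run covers points lo..hi
    if (i0 >= lo && i0 <= hi) return(c(curve$ri[lo], curve$ri[hi]))
  }
  range(curve$ri)
}

# segment index for an RI value; ties at a break go to the lower segment
.segment_of <- function(model, ri) {
  findInterval(ri, model$breaks, left.open = TRUE) + 1L
}

.eval_segment <- function(model, ri, j) {
  s <- model$segments[[j]]
  u <- (ri - s$center) / s$halfspan
  drop(outer(u, seq_along(s$coef) - 1, `^`) %*% s$coef)
}

#' Evaluate a meta-model (phase at given RI)
#'
#' Piecewise-polynomial forward evaluation.  At an interior segment boundary
#' the lower segment is used.
#'
#' @param model A [build_metamodel()] result.
#' @param ri Refractive indices inside the model's RI domain.
#' @return Phase shifts in rad.
#' @export
evaluate_phase <- function(model, ri) {
  stopifnot(inherits(model, "segmented_cubic"))
  tol <- 1e-12 + 1e-9 * diff(model$ri_range)
  if (any(ri < model$ri_range[1] - tol | ri > model$ri_range[2] + tol))
    stop(sprintf("RI out of model domain [%.6f, %.6f]",
                 model$ri_range[1], model$ri_range[2]))
  ri <- pmin(pmax(ri, model$ri_range[1]), model$ri_range[2])
  si <- .segment_of(model, ri)
  out <- numeric(length(ri))
  for (j in unique(si)) out[si == j] <- .eval_segment(model, ri[si == j], j)
  out
}

#' Invert a meta-model (RI at given phase)
#'
#' Solves the per-segment cubic for the refractive index producing a given
#' baseline-referenced phase shift.  When several real roots fall inside the
#' model domain, the root nearest `previous_ri` is taken (temporal
#' continuity); with no `previous_ri`, roots on the monotone working branch
#' are preferred and ties resolved toward the baseline.
#'
#' @param model A [build_metamodel()] result.
#' @param dphase Phase shift(s), rad; must lie within the model's valid phase
#'   range (an explicit error is raised otherwise, never silent clipping).
#' @param previous_ri Optional preceding RI estimate for root selection.
#' @return Refractive index (RIU), same length as `dphase`.
#' @export
invert_phase <- function(model, dphase, previous_ri = NULL) {
  stopifnot(inherits(model, "segmented_cubic"))
  ptol <- 1e-9 * max(1, diff(model$phase_range))
  out <- numeric(length(dphase))
  prev <- previous_ri
  for (k in seq_along(dphase)) {
    out[k] <- .invert_one(model, dphase[k], prev, ptol)
    prev <- out[k]
  }
  out
}

.invert_one <- function(model, ph, prev, ptol) {
  if (!is.finite(ph)) stop("non-finite phase value")
  if (ph < model$phase_range[1] - ptol || ph > model$phase_range[2] + ptol)
    stop(sprintf(
      "phase %.6g rad outside the model's valid range [%.6g, %.6g]",
      ph, model$phase_range[1], model$phase_range[2]))
  roots <- numeric(0)
  for (j in seq_len(model$n_segments)) {
    s <- model$segments[[j]]
    cf <- s$coef; cf[1] <- cf[1] - ph
    # drop numerically-zero leading coefficients for polyroot stability
    while (length(cf) > 1 && abs(cf[length(cf)]) < 1e-14 * max(abs(cf)))
      cf <- cf[-length(cf)]
    if (length(cf) <= 1) next
    z <- polyroot(cf)
    re <- Re(z)[abs(Im(z)) < 1e-7 * (1 + Mod(z))]
    ri <- re * s$halfspan + s$center
    u_lo <- (s$dom_lo - s$center) / s$halfspan
    u_hi <- (s$dom_hi - s$center) / s$halfspan
    utol <- 1e-7 + 1e-6 * (u_hi - u_lo)
    ok <- re >= u_lo - utol & re <= u_hi + utol
    roots <- c(roots, pmin(pmax(ri[ok], model$ri_range[1]), model$ri_range[2]))
  }
  if (length(roots) == 0) {
    # the phase can fall inside a discontinuous joint gap (no segment
    # attains it); the break point is then the best in-model answer, off by
    # at most the monitored joint mismatch
    for (b in model$breaks) {
      lo_v <- .eval_segment(model, b, .segment_of(model, b))
      hi_v <- .eval_segment(model, b, .segment_of(model, b) + 1L)
      if ((ph - lo_v) * (ph - hi_v) <= 0) return(b)
    }
    stop(sprintf("no in-domain root for phase %.6g rad (valid range [%.6g, %.6g])",
                 ph, model$phase_range[1], model$phase_range[2]))
  }
  roots <- sort(unique(roots))
  if (length(roots) == 1) return(roots)
  if (!is.null(prev)) return(roots[which.min(abs(roots - prev))])
  on_branch <- roots >= model$working_ri_range[1] - 1e-12 &
               roots <= model$working_ri_range[2] + 1e-12
  cand <- if (any(on_branch)) roots[on_branch] else roots
  cand[which.min(abs(cand - model$baseline_ri))]
}

#' Serialize a meta-model to JSON
#'
#' Writes segment domains, scaled ascending-power coefficients, baseline RI,
#' valid phase range and optional provenance so a model can be stored next to
#' converted data and reloaded bit-identically.
#'
#' @param model A [build_metamodel()] result.
#' @param path Output file path.
#' @param provenance Optional named list (chip parameters, grid size, ...).
#' @return `path`, invisibly.
#' @export
write_metamodel <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "segmented_cubic"))
  obj <- unclass(model)
  obj$provenance <- provenance
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a meta-model from JSON
#'
#' @param path File written by [write_metamodel()].
#' @return A `segmented_cubic` model.
#' @export
read_metamodel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$segments)) stop("not a meta-model JSON file: ", path)
  segs <- obj$segments
  if (is.data.frame(segs)) {
    segs <- lapply(seq_len(nrow(segs)), function(i) {
      s <- as.list(segs[i, , drop = FALSE])
      s$coef <- unlist(s$coef, use.names = FALSE)
      lapply(s, unlist, use.names = FALSE)
    })
  }
  model <- structure(list(
    segments = segs, breaks = as.numeric(obj$breaks),
    n_segments = as.integer(obj$n_segments), order = as.integer(obj$order),
    baseline_ri = obj$baseline_ri, ri_range = as.numeric(obj$ri_range),
    phase_range = as.numeric(obj$phase_range),
    working_ri_range = as.numeric(obj$working_ri_range),
    monotone = isTRUE(obj$monotone),
    max_residual = obj$max_residual, ssr_fit = obj$ssr_fit,
    joint_gap = obj$joint_gap
  ), class = "segmented_cubic")
  model$provenance <- obj$provenance
  model
}
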