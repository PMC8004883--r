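# Four-parameter calibration of the five-layer sensor model.
#
# The search space is (incident angle, gold thickness, probe thickness,
# probe refractive index); all other stack constants are fixed (850 nm,
# Au 0.16+5.34i, Cr 3.24+3.49i at 2 nm, BK7 prism 1.51).  Each trial builds
# the Fresnel mapping curve over the calibration window (plus extension
# margin), meta-models it with three cubics, and scores the sum of squared
# phase residuals at the calibration points.  The optimizer is a seeded
# Gaussian-process expected-improvement search on log10(SSR) followed by a
# budget-capped Nelder-Mead polish; single-wavelength data make the
# parameters non-identifiable, so the acceptance surface is the mapping
# function, not the parameter estimates.

#' Create a calibration set
#'
#' Reference-solution refractive indices with their measured baseline-
#' referenced phase shifts, plus the baseline buffer (phase 0 by definition).
#'
#' @param ri Strictly increasing non-baseline reference refractive indices
#'   (at least 2).
#' @param dphase Measured phase shifts at `ri`, rad.
#' @param baseline_ri Baseline buffer refractive index.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(ri, dphase, baseline_ri) {
  if (length(ri) < 2) stop("need at least 2 non-baseline calibration points")
  if (length(ri) != length(dphase)) stop("'ri' and 'dphase' lengths differ")
  if (is.unsorted(ri, strictly = TRUE)) stop("'ri' must be strictly increasing")
  if (any(!is.finite(ri)) || any(!is.finite(dphase)) || !is.finite(baseline_ri))
    stop("non-finite calibration values")
  structure(list(ri = as.numeric(ri), dphase = as.numeric(dphase),
                 baseline_ri = as.numeric(baseline_ri)),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("Calibration set: baseline %.5f + %d reference points\n",
              x$baseline_ri, length(x$ri)))
  print(data.frame(ri = x$ri, dphase_rad = x$dphase), row.names = FALSE)
  invisible(x)
}

#' Parameter bounds for calibration
#'
#' Closed intervals for the four optimized chip parameters.
#'
#' @param incident_angle,au_nm,probe_nm,probe_ri Numeric `c(lo, hi)` pairs
#'   (degenerate `lo == hi` is allowed and pins the parameter).
#' @return An object of class `parameter_bounds`.
#' @export
parameter_bounds <- function(incident_angle = c(65.4, 67.4),
                             au_nm = c(40, 55),
                             probe_nm = c(5, 10),
                             probe_ri = c(1.34, 1.45)) {
  b <- list(incident_angle = incident_angle, au_nm = au_nm,
            probe_nm = probe_nm, probe_ri = probe_ri)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2])
      stop("bounds for '", nm, "' must be finite c(lo, hi) with lo <= hi")
    b[[nm]] <- as.numeric(v)
  }
  structure(b, class = "parameter_bounds")
}

#' Default bounds anchored at the nominal resonance dip
#'
#' Angle window of +/- 1 degree around the dip of the nominal chip (48 nm Au,
#' 7.5 nm probe) in the calibration baseline buffer; gold 40-55 nm, probe
#' 5-10 nm (a ~22-bp aptamer layer at 0.34 nm/bp is ~7.5 nm), probe RI
#' 1.34-1.45.
#'
#' @param calibration A [calibration_set()] (supplies the baseline buffer RI).
#' @return A [parameter_bounds()].
#' @export
default_bounds <- function(calibration) {
  stopifnot(inherits(calibration, "calibration_set"))
  nominal <- default_chip_stack(au_nm = 48, probe_nm = 7.5, probe_ri = 1.40,
                                buffer_ri = calibration$baseline_ri)
  dip <- resonance_angle(nominal, range = c(60, 75))
  parameter_bounds(incident_angle = dip + c(-1, 1))
}

# RI sampling window for the mapping curve: calibration span extended by
# `extension` on both sides so the model's phase range exceeds the data's.
.cal_window <- function(calibration, extension = 0.10) {
  ris <- c(calibration$baseline_ri, calibration$ri)
  span <- max(ris) - min(ris)
  c(min(ris) - extension * span, max(ris) + extension * span)
}

#' Calibration objective: one trial of the four chip parameters
#'
#' Builds the trial stack, computes its Fresnel mapping curve over the
#' calibration window (plus extension), meta-models it with segmented cubics,
#' and returns the sum of squared phase residuals at the calibration points
#' (baseline included with equal weight).  Trials whose curve cannot be built
#' receive a large finite penalty rather than an exception.
#'
#' @param params Named numeric vector with `incident_angle`, `au_nm`,
#'   `probe_nm`, `probe_ri`.
#' @param calibration A [calibration_set()].
#' @param extension RI window extension fraction (default 0.10).
#' @param n_grid Mapping-curve grid size (default 301).
#' @param penalty SSR assigned to degenerate trials, rad^2.
#' @param keep_model Attach the fitted `segmented_cubic` to the result.
#' @return A list (trial record): the four parameters, `ssr` (rad^2),
#'   `log10_ssr`, `penalized` flag and optionally `model`.
#' @export
spr_objective <- function(params, calibration, extension = 0.10,
                          n_grid = 301L, penalty = 1e3, keep_model = FALSE) {
  stopifnot(inherits(calibration, "calibration_set"))
  p <- params
  need <- c("incident_angle", "au_nm", "probe_nm", "probe_ri")
  if (!all(need %in% names(p))) stop("params must be named: ", paste(need, collapse = ", "))
  win <- .cal_window(calibration, extension)
  rec <- list(incident_angle = unname(p[["incident_angle"]]),
              au_nm = unname(p[["au_nm"]]),
              probe_nm = unname(p[["probe_nm"]]),
              probe_ri = unname(p[["probe_ri"]]))
  res <- tryCatch({
    stack <- default_chip_stack(au_nm = rec$au_nm, probe_nm = rec$probe_nm,
                                probe_ri = rec$probe_ri,
                                buffer_ri = calibration$baseline_ri)
    curve <- phase_vs_ri(stack, rec$incident_angle,
                         seq(win[1], win[2], length.out = n_grid),
                         baseline_ri = calibration$baseline_ri)
    model <- build_metamodel(curve)
    pred <- evaluate_phase(model, c(calibration$baseline_ri, calibration$ri))
    resid <- pred - c(0, calibration$dphase)
    list(ssr = sum(resid^2), resid = resid, model = model, penalized = FALSE)
  }, error = function(e) list(ssr = penalty, resid = NULL, model = NULL,
                              penalized = TRUE))
  rec$ssr <- res$ssr
  rec$log10_ssr <- if (res$ssr > 0) log10(res$ssr) else -Inf
  rec$penalized <- res$penalized
  rec$resid <- res$resid
  if (keep_model) rec$model <- res$model
  rec
}

# ---- Gaussian-process expected-improvement machinery (unit hypercube) ----

.gp_kernel <- function(X1, X2, ls) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
  exp(-0.5 * pmax(d2, 0) / ls^2)
}

.gp_fit <- function(X, y, ls_grid = c(0.1, 0.2, 0.35, 0.6), nugget = 1e-6) {
  mu <- mean(y); sdv <- stats::sd(y); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  best <- NULL; best_ll <- -Inf
  for (ls in ls_grid) {
    K <- .gp_kernel(X, X, ls) + diag(nugget, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (ll > best_ll) { best_ll <- ll; best <- list(ls = ls, chol = ch, alpha = alpha) }
  }
  if (is.null(best)) return(NULL)
  c(best, list(X = X, mu = mu, sd = sdv, nugget = nugget))
}

.gp_predict <- function(gp, Xnew) {
  Ks <- .gp_kernel(Xnew, gp$X, gp$ls)
  mean_s <- drop(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var_s <- pmax(1 + gp$nugget - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sd * mean_s, sd = gp$sd * sqrt(var_s))
}

.expected_improvement <- function(gp, Xnew, y_best_std) {
  pr <- .gp_predict(gp, Xnew)
  z <- (y_best_std - pr$mean) / pr$sd
  (y_best_std - pr$mean) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
}

# Latin hypercube on [0,1]^d
.lhs <- function(n, d) {
  sapply(seq_len(d), function(j) (sample.int(n) - stats::runif(n)) / n)
}

#' Calibrate the chip model against a calibration set
#'
#' Seeded, reproducible Bayesian optimization of [spr_objective()] over the
#' four-parameter box: `n_initial` Latin-hypercube trials, Gaussian-process
#' expected-improvement proposals on log10(SSR), and a final Nelder-Mead
#' polish from the incumbent.  The total number of objective evaluations
#' never exceeds `n_iter`.
#'
#' @param calibration A [calibration_set()].
#' @param bounds A [parameter_bounds()]; defaults to
#'   [default_bounds()]`(calibration)`.
#' @param n_iter Total objective-evaluation budget (>= 20 recommended).
#' @param seed Integer seed; identical seed and inputs give an identical
#'   trace.
#' @param n_initial Space-filling initial trials.
#' @param ei_fraction Fraction of the post-initial budget spent on GP-EI
#'   proposals (the remainder goes to the polish).
#' @param extension,n_grid,penalty Passed to [spr_objective()].
#' @return An object of class `spr_fit`: `best` (trial record), `model` (the
#'   best [build_metamodel()] result), `trace` (data frame of all trials),
#'   `calibration`, `bounds`, `seed`, `n_iterations`.
#' @export
calibrate_chip <- function(calibration, bounds = default_bounds(calibration),
                           n_iter = 120L, seed = 0L, n_initial = 16L,
                           ei_fraction = 0.25, extension = 0.10,
                           n_grid = 301L, penalty = 1e3) {
  stopifnot(inherits(calibration, "calibration_set"),
            inherits(bounds, "parameter_bounds"))
  if (n_iter < 1) stop("'n_iter' must be >= 1")
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  names(lo) <- names(hi) <- c("incident_angle", "au_nm", "probe_nm", "probe_ri")
  free <- hi > lo
  d <- sum(free)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(seed)

  from_unit <- function(u) {
    p <- lo
    p[free] <- lo[free] + u * (hi - lo)[free]
    p
  }
  trace <- vector("list", n_iter)
  count <- 0L
  eval_u <- function(u) {
    if (count >= n_iter) stop(structure(class = c("psprmap_budget", "error",
                                                  "condition"),
                                        list(message = "budget", call = NULL)))
    rec <- spr_objective(from_unit(u), calibration, extension = extension,
                         n_grid = n_grid, penalty = penalty)
    count <<- count + 1L
    trace[[count]] <<- rec
    invisible(rec)
  }

  if (d == 0) {
    # fully pinned bounds: a single evaluation
    eval_u(numeric(0))
  } else {
    n_init <- min(n_initial, n_iter)
    U <- .lhs(n_init, d)
    if (n_init == 1) U <- matrix(U, nrow = 1)
    for (i in seq_len(n_init)) eval_u(U[i, ])
    budget_left <- n_iter - count
    n_ei <- floor(ei_fraction * budget_left)
    y <- vapply(trace[seq_len(count)], function(r) max(r$log10_ssr, -16), numeric(1))
    X <- U
    for (it in seq_len(n_ei)) {
      gp <- .gp_fit(X, y)
      cand <- rbind(matrix(stats::runif(1024 * d), ncol = d),
                    pmin(pmax(matrix(rep(X[which.min(y), ], each = 512), ncol = d) +
                                matrix(stats::rnorm(512 * d, sd = 0.05), ncol = d),
                              0), 1))
      u_next <- if (is.null(gp)) stats::runif(d) else {
        ei <- .expected_improvement(gp, cand, min(y))
        cand[which.max(ei), ]
      }
      eval_u(u_next)
      X <- rbind(X, u_next)
      y <- c(y, max(trace[[count]]$log10_ssr, -16))
    }
    # Levenberg-Marquardt polish of the incumbent (the objective is a
    # least-squares problem; secant/Broyden Jacobian updates keep the cost
    # per iteration low), followed by a walk along the least-identified
    # parameter direction: single-wavelength data leave a degenerate valley
    # of equivalent models along which the meta-model floor still varies,
    # so stepping along the smallest eigenvector of J'J and re-polishing
    # explores it cheaply.  Everything stays inside the n_iter budget.
    ib <- which.min(vapply(trace[seq_len(count)], `[[`, numeric(1), "ssr"))
    if (count < n_iter && !trace[[ib]]$penalized && ib <= nrow(X)) {
      lm_state <- NULL
      lm_run <- function(u, r, ssr_cur, max_iters, stall_max = 2L, J = NULL) {
        lambda <- 1e-4; stall <- 0L; fresh <- FALSE
        for (it in seq_len(max_iters)) {
          if (is.null(J)) {
            J <- matrix(0, length(r), d)
            for (j in seq_len(d)) {
              up <- u
              hj <- if (u[j] + 1e-7 <= 1) 1e-7 else -1e-7
              up[j] <- u[j] + hj
              rj <- eval_u(up)
              J[, j] <- if (rj$penalized) 0 else (rj$resid - r) / hj
            }
            fresh <- TRUE
          }
          A <- crossprod(J); g <- drop(crossprod(J, r))
          moved <- FALSE
          while (lambda < 1e12) {
            step <- tryCatch(
              drop(solve(A + lambda * diag(pmax(diag(A), 1e-12), d), -g)),
              error = function(e) NULL)
            if (!is.null(step)) {
              u_new <- pmin(pmax(u + step, 0), 1)
              du <- u_new - u
              if (sum(du^2) == 0) break
              rec2 <- eval_u(u_new)
              if (!rec2$penalized && rec2$ssr < ssr_cur) {
                imp <- 1 - rec2$ssr / ssr_cur
                # Broyden rank-1 secant update of the Jacobian
                J <- J + ((rec2$resid - r - J %*% du) %*% t(du)) / sum(du^2)
                u <- u_new; r <- rec2$resid; ssr_cur <- rec2$ssr
                lambda <- max(lambda / 10, 1e-12)
                stall <- if (imp < 1e-3) stall + 1L else 0L
                moved <- TRUE; fresh <- FALSE
                break
              }
            }
            lambda <- lambda * 10
          }
          if (!moved) {
            if (fresh) break          # genuine stationarity
            J <- NULL; lambda <- 1e-4 # refresh the Jacobian and retry
            next
          }
          if (stall >= stall_max || ssr_cur < 1e-18) break
        }
        lm_state <<- list(u = u, r = r, ssr = ssr_cur, J = J)
        ssr_cur
      }
      tryCatch({
        rec <- trace[[ib]]
        lm_run(X[ib, , drop = TRUE], rec$resid, rec$ssr, max_iters = 15L)
        repeat {
          if (is.null(lm_state$J) || count >= n_iter) break
          v <- eigen(crossprod(lm_state$J), symmetric = TRUE)$vectors[, d]
          base <- lm_state
          improved <- FALSE
          for (tt in c(0.35, -0.35, 0.15, -0.15)) {
            u_try <- pmin(pmax(base$u + tt * v, 0), 1)
            if (max(abs(u_try - base$u)) < 1e-10) next
            rec2 <- eval_u(u_try)
            if (rec2$penalized) next
            lm_run(u_try, rec2$resid, rec2$ssr, max_iters = 5L)
            if (lm_state$ssr < base$ssr) { improved <- TRUE; break }
          }
          if (!improved) { lm_state <- base; break }
        }
        # spend any leftover budget on a fresh-Jacobian re-polish
        if (count < n_iter - 5L)
          lm_run(lm_state$u, lm_state$r, lm_state$ssr, max_iters = 10L,
                 stall_max = 3L)
      }, psprmap_budget = function(e) NULL)
    }
  }

  trace <- trace[seq_len(count)]
  tr <- do.call(rbind, lapply(seq_along(trace), function(i) {
    r <- trace[[i]]
    data.frame(iteration = i, incident_angle = r$incident_angle,
               au_nm = r$au_nm, probe_nm = r$probe_nm, probe_ri = r$probe_ri,
               ssr = r$ssr, log10_ssr = r$log10_ssr, penalized = r$penalized)
  }))
  ib <- which.min(tr$ssr)
  best <- trace[[ib]]
  best_full <- spr_objective(unlist(best[c("incident_angle", "au_nm",
                                           "probe_nm", "probe_ri")]),
                             calibration, extension = extension,
                             n_grid = n_grid, penalty = penalty,
                             keep_model = TRUE)
  structure(list(best = best, model = best_full$model, trace = tr,
                 calibration = calibration, bounds = bounds,
                 seed = seed, n_iterations = count),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("SPR calibration fit (%d trials, seed %d)\n", x$n_iterations, x$seed))
  cat(sprintf("  best SSR %.4g rad^2 (log10 %.4f)\n", x$best$ssr, x$best$log10_ssr))
  cat(sprintf("  angle %.4f deg, Au %.3f nm, probe %.3f nm @ RI %.4f\n",
              x$best$incident_angle, x$best$au_nm, x$best$probe_nm, x$best$probe_ri))
  invisible(x)
}

#' Mapping discrepancy between two calibrated models
#'
#' Maximum absolute difference of the inverted refractive index over a dense
#' phase grid -- the operational test of model equivalence: parameter sets
#' may differ (they are not identifiable from single-wavelength data) while
#' the phase-to-RI mappings coincide.
#'
#' @param a,b [calibrate_chip()] results or `segmented_cubic` models.
#' @param phase_range Phase interval to scan, rad; default is the
#'   intersection of the two models' valid ranges (error if disjoint).
#' @param n Grid size.
#' @return Maximum `|invert_a - invert_b|` in RIU, with attribute `"grid"`.
#' @export
equivalent_model_check <- function(a, b, phase_range = NULL, n = 501L) {
  ma <- if (inherits(a, "spr_fit")) a$model else a
  mb <- if (inherits(b, "spr_fit")) b$model else b
  stopifnot(inherits(ma, "segmented_cubic"), inherits(mb, "segmented_cubic"))
  if (is.null(phase_range)) {
    phase_range <- c(max(ma$phase_range[1], mb$phase_range[1]),
                     min(ma$phase_range[2], mb$phase_range[2]))
  }
  if (phase_range[1] >= phase_range[2])
    stop("the two models' valid phase ranges do not overlap")
  grid <- seq(phase_range[1], phase_range[2], length.out = n)
  ria <- invert_phase(ma, grid)
  rib <- invert_phase(mb, grid)
  structure(max(abs(ria - rib)), grid = data.frame(dphase = grid, ri_a = ria, ri_b = rib))
}
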