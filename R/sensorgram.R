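# Phasogram -> sensorgram conversion and cross-ROI consistency.

#' Create a phasogram
#'
#' A time series of baseline-referenced SPR phase for one region of interest.
#'
#' @param time Strictly increasing times, s.
#' @param phase Phase values, rad.
#' @param roi_id Region-of-interest identifier.
#' @return An object of class `phasogram` (a data frame with columns
#'   `time_s`, `phase_rad`, `roi_id`).
#' @export
phasogram <- function(time, phase, roi_id = "roi1") {
  if (length(time) != length(phase)) stop("'time' and 'phase' lengths differ")
  if (is.unsorted(time, strictly = TRUE)) stop("'time' must be strictly increasing")
  if (any(!is.finite(time)) || any(!is.finite(phase))) stop("non-finite phasogram values")
  structure(data.frame(time_s = as.numeric(time), phase_rad = as.numeric(phase),
                       roi_id = as.character(roi_id)),
            class = c("phasogram", "data.frame"), units = "rad")
}

#' Create a sensorgram
#'
#' A time series of effective refractive-index change for one ROI.
#'
#' @param time Strictly increasing times, s.
#' @param ri Refractive-index values (RIU); by convention change from
#'   baseline.
#' @param roi_id Region-of-interest identifier.
#' @return An object of class `sensorgram` (columns `time_s`, `ri`,
#'   `roi_id`), tagged with `units = "RIU"`.
#' @export
sensorgram <- function(time, ri, roi_id = "roi1") {
  if (length(time) != length(ri)) stop("'time' and 'ri' lengths differ")
  if (is.unsorted(time, strictly = TRUE)) stop("'time' must be strictly increasing")
  structure(data.frame(time_s = as.numeric(time), ri = as.numeric(ri),
                       roi_id = as.character(roi_id)),
            class = c("sensorgram", "data.frame"), units = "RIU")
}

#' Re-reference a phasogram to its own baseline window
#'
#' Subtracts the mean phase over the initial baseline window (running-buffer
#' segment), so the phasogram is 0-referenced before conversion.
#'
#' @param pg A [phasogram()].
#' @param window Baseline window length from the first sample, s (default 60).
#' @return The re-referenced [phasogram()].
#' @export
rebaseline <- function(pg, window = 60) {
  stopifnot(inherits(pg, "phasogram"))
  sel <- pg$time_s <= pg$time_s[1] + window
  if (!any(sel)) stop("baseline window contains no samples")
  out <- pg
  out$phase_rad <- pg$phase_rad - mean(pg$phase_rad[sel])
  out
}

#' Convert a phasogram to a refractive-index sensorgram
#'
#' Pointwise inversion of the fitted meta-model with temporal-continuity root
#' selection; the output is the change in effective refractive index from the
#' model baseline.  Inputs already in RIU are rejected (unit tag enforced);
#' samples outside the model's valid phase range raise an error listing the
#' offending indices.
#'
#' @param pg A [phasogram()] (re-reference first with [rebaseline()] if the
#'   raw trace has a nonzero baseline).
#' @param model A [build_metamodel()] result (typically
#'   [calibrate_chip()]`$model`).
#' @param baseline_window Optional baseline window, s: when non-`NULL` the
#'   phasogram is passed through [rebaseline()] first.
#' @return A [sensorgram()] in delta-RIU on the same time base.
#' @export
convert_phasogram <- function(pg, model, baseline_window = NULL) {
  if (identical(attr(pg, "units"), "RIU") || inherits(pg, "sensorgram"))
    stop("input is already a refractive-index sensorgram; conversion applies to phasograms")
  stopifnot(inherits(pg, "phasogram"), inherits(model, "segmented_cubic"))
  if (!is.null(baseline_window)) pg <- rebaseline(pg, baseline_window)
  ptol <- 1e-9 * max(1, diff(model$phase_range))
  bad <- which(pg$phase_rad < model$phase_range[1] - ptol |
               pg$phase_rad > model$phase_range[2] + ptol)
  if (length(bad) > 0)
    stop("phase samples outside the model's valid range at indices: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "")
  ri0 <- invert_phase(model, 0, previous_ri = model$baseline_ri)
  ri <- invert_phase(model, pg$phase_rad, previous_ri = ri0)
  sensorgram(pg$time_s, ri - ri0, roi_id = pg$roi_id[1])
}

#' Pairwise consistency of converted sensorgrams
#'
#' Resamples every sensorgram onto a common regular time grid over the
#' intersection of their time ranges (linear interpolation) and reports the
#' symmetric matrix of pairwise root-mean-square differences.
#'
#' @param sensorgrams A list of [sensorgram()] objects (phasograms are also
#'   accepted, compared in rad).
#' @param n_grid Size of the common time grid.
#' @return A symmetric matrix of pairwise RMS differences (RIU or rad),
#'   zero diagonal, dimnames from ROI ids.
#' @export
consistency_report <- function(sensorgrams, n_grid = 512L) {
  if (!is.list(sensorgrams) || length(sensorgrams) < 2)
    stop("supply a list of at least two sensorgrams")
  val_col <- function(x) if ("ri" %in% names(x)) x$ri else x$phase_rad
  t_lo <- max(vapply(sensorgrams, function(x) min(x$time_s), numeric(1)))
  t_hi <- min(vapply(sensorgrams, function(x) max(x$time_s), numeric(1)))
  if (t_lo >= t_hi) stop("sensorgram time ranges do not overlap")
  grid <- seq(t_lo, t_hi, length.out = n_grid)
  Y <- vapply(sensorgrams,
              function(x) stats::approx(x$time_s, val_col(x), xout = grid)$y,
              numeric(n_grid))
  k <- length(sensorgrams)
  ids <- vapply(seq_len(k), function(i) {
    id <- unique(as.character(sensorgrams[[i]]$roi_id))
    if (length(id) == 1) id else paste0("series", i)
  }, character(1))
  if (anyDuplicated(ids)) ids <- paste0(ids, ".", seq_len(k))
  M <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    M[i, j] <- M[j, i] <- sqrt(mean((Y[, i] - Y[, j])^2))
  }
  M
}
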