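# Strict CSV / YAML readers and writers for the pipeline's file formats.
# All files are UTF-8 with '.' decimal separators; schema violations raise
# errors naming the offending column or row.

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
}

.numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(x)
  if (any(grepl(",", x, fixed = TRUE)))
    stop("column '", col, "' in '", path,
         "' uses a decimal comma; files must use '.' as the decimal separator")
  y <- suppressWarnings(as.numeric(x))
  if (anyNA(y) & !anyNA(x))
    stop("column '", col, "' in '", path, "' is not numeric")
  y
}

#' Read / write calibration CSV
#'
#' Columns `ri`, `dphase_rad` and logical `baseline` (exactly one `TRUE` row,
#' whose `dphase_rad` must be 0).
#'
#' @param path File path.
#' @return A [calibration_set()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("ri", "dphase_rad", "baseline"), path)
  ri <- .numeric_col(df, "ri", path)
  ph <- .numeric_col(df, "dphase_rad", path)
  bl <- as.logical(df$baseline)
  if (sum(bl) != 1) stop("file '", path, "' must flag exactly one baseline row")
  if (abs(ph[bl]) > 1e-12)
    stop("baseline row in '", path, "' must have dphase_rad = 0")
  o <- order(ri[!bl])
  calibration_set(ri[!bl][o], ph[!bl][o], baseline_ri = ri[bl])
}

#' @rdname read_calibration_csv
#' @param cal A [calibration_set()].
#' @export
write_calibration_csv <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_set"))
  df <- data.frame(ri = c(cal$baseline_ri, cal$ri),
                   dphase_rad = c(0, cal$dphase),
                   baseline = c(TRUE, rep(FALSE, length(cal$ri))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write phasogram CSV
#'
#' Columns `time_s`, `phase_rad`, `roi_id`.
#'
#' @param path File path.
#' @param roi Optional ROI id to select when the file holds several.
#' @return A [phasogram()] (or a list of them if several ROIs and no `roi`).
#' @export
read_phasogram_csv <- function(path, roi = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("time_s", "phase_rad", "roi_id"), path)
  t <- .numeric_col(df, "time_s", path)
  p <- .numeric_col(df, "phase_rad", path)
  ids <- as.character(df$roi_id)
  make <- function(id) phasogram(t[ids == id], p[ids == id], roi_id = id)
  if (!is.null(roi)) {
    if (!roi %in% ids) stop("ROI '", roi, "' not present in '", path, "'")
    return(make(roi))
  }
  u <- unique(ids)
  if (length(u) == 1) make(u) else stats::setNames(lapply(u, make), u)
}

#' @rdname read_phasogram_csv
#' @param pg A [phasogram()] (or list of them).
#' @export
write_phasogram_csv <- function(pg, path) {
  if (inherits(pg, "phasogram")) pg <- list(pg)
  df <- do.call(rbind, lapply(pg, function(x)
    data.frame(time_s = x$time_s, phase_rad = x$phase_rad, roi_id = x$roi_id)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sensorgram CSV
#'
#' Columns `time_s`, `ri`, `roi_id`.
#'
#' @param path File path.
#' @return A [sensorgram()] (or list of them per ROI).
#' @export
read_sensorgram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("time_s", "ri", "roi_id"), path)
  t <- .numeric_col(df, "time_s", path)
  r <- .numeric_col(df, "ri", path)
  ids <- as.character(df$roi_id)
  u <- unique(ids)
  make <- function(id) sensorgram(t[ids == id], r[ids == id], roi_id = id)
  if (length(u) == 1) make(u) else stats::setNames(lapply(u, make), u)
}

#' @rdname read_sensorgram_csv
#' @param sg A [sensorgram()] (or list of them).
#' @export
write_sensorgram_csv <- function(sg, path) {
  if (inherits(sg, "sensorgram")) sg <- list(sg)
  df <- do.call(rbind, lapply(sg, function(x)
    data.frame(time_s = x$time_s, ri = x$ri, roi_id = x$roi_id)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an optical-stack YAML config
#'
#' Layout: `wavelength_nm` plus a `layers` list of `{name, n_re, n_im,
#' thickness_nm}` where `thickness_nm` is a number or `"semi_infinite"`.
#'
#' @param path File path.
#' @return An [optical_stack()].
#' @export
read_stack_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || is.null(cfg$wavelength_nm))
    stop("stack config '", path, "' needs 'wavelength_nm' and 'layers'")
  layers <- lapply(cfg$layers, function(l) {
    if (is.null(l$name) || is.null(l$n_re))
      stop("each layer in '", path, "' needs 'name' and 'n_re'")
    th <- l$thickness_nm
    th <- if (is.character(th) && th == "semi_infinite") Inf else as.numeric(th)
    optical_layer(l$name, complex(real = l$n_re,
                                  imaginary = if (is.null(l$n_im)) 0 else l$n_im), th)
  })
  optical_stack(layers, wavelength_nm = cfg$wavelength_nm)
}

#' @rdname read_stack_config
#' @param stack An [optical_stack()].
#' @export
write_stack_config <- function(stack, path) {
  stopifnot(inherits(stack, "optical_stack"))
  cfg <- list(
    wavelength_nm = stack$wavelength_nm,
    layers = lapply(stack$layers, function(l) list(
      name = l$label, n_re = Re(l$n), n_im = Im(l$n),
      thickness_nm = if (is.infinite(l$thickness_nm)) "semi_infinite"
                     else l$thickness_nm)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read / write a parameter-bounds YAML config
#'
#' Layout: four entries (`incident_angle`, `au_nm`, `probe_nm`, `probe_ri`),
#' each `{lo, hi}`.
#'
#' @param path File path.
#' @return A [parameter_bounds()].
#' @export
read_bounds_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("incident_angle", "au_nm", "probe_nm", "probe_ri")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("bounds config '", path, "' is missing: ", paste(missing, collapse = ", "))
  args <- lapply(cfg[need], function(v) c(v$lo, v$hi))
  do.call(parameter_bounds, args)
}

#' @rdname read_bounds_config
#' @param bounds A [parameter_bounds()].
#' @export
write_bounds_config <- function(bounds, path) {
  stopifnot(inherits(bounds, "parameter_bounds"))
  yaml::write_yaml(lapply(unclass(bounds), function(v) list(lo = v[1], hi = v[2])),
                   path)
  invisible(path)
}

#' Write an optimization trace CSV
#'
#' @param trace The `trace` data frame of a [calibrate_chip()] result.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
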