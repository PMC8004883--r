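# Goodness-of-fit visualization of the four-parameter search.

#' Plot the optimization trace as a 3D goodness-of-fit chart
#'
#' One marker per trial: x = incident angle (deg), y = gold thickness (nm),
#' z = log10 SSR, color = probe refractive index, marker size = probe
#' thickness.  A converged search shows a funnel of markers dropping toward
#' the error minimum; flat degenerate valleys betray equivalent models.  The
#' plot is written as PNG; a companion CSV with exactly the plotted values
#' makes the chart reproducible and testable without image comparison.
#'
#' @param trace Trace data frame from [calibrate_chip()] (columns
#'   `incident_angle`, `au_nm`, `probe_nm`, `probe_ri`, `ssr`).
#' @param out_png Output image path.
#' @param out_csv Companion table path (default: `out_png` with `.csv`).
#' @param log10_floor Floor applied to log10(SSR) for zero SSR.
#' @return Invisibly, the companion data frame.
#' @export
plot_trace <- function(trace, out_png, out_csv = sub("\\.png$", ".csv", out_png),
                       log10_floor = -16) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty optimization trace")
  need <- c("incident_angle", "au_nm", "probe_nm", "probe_ri", "ssr")
  missing <- setdiff(need, names(trace))
  if (length(missing) > 0)
    stop("trace is missing column(s): ", paste(missing, collapse = ", "))
  z <- ifelse(trace$ssr > 0, log10(trace$ssr), log10_floor)
  z <- pmax(z, log10_floor)
  companion <- data.frame(
    x_incident_angle_deg = trace$incident_angle,
    y_au_thickness_nm = trace$au_nm,
    z_log10_ssr = z,
    color_probe_ri = trace$probe_ri,
    size_probe_thickness_nm = trace$probe_nm)
  utils::write.csv(companion, out_csv, row.names = FALSE, quote = FALSE)
  pal <- grDevices::hcl.colors(64, "Viridis")
  cidx <- if (diff(range(companion$color_probe_ri)) > 0)
    1 + floor(63 * (companion$color_probe_ri - min(companion$color_probe_ri)) /
                diff(range(companion$color_probe_ri)))
  else rep(32L, nrow(companion))
  szr <- range(companion$size_probe_thickness_nm)
  cex <- if (diff(szr) > 0)
    0.6 + 1.6 * (companion$size_probe_thickness_nm - szr[1]) / diff(szr)
  else rep(1, nrow(companion))
  grDevices::png(out_png, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  print(lattice::cloud(
    z_log10_ssr ~ x_incident_angle_deg * y_au_thickness_nm, data = companion,
    pch = 16, col = pal[cidx], cex = cex,
    xlab = "incident angle (deg)", ylab = "Au thickness (nm)",
    zlab = "log10 SSR (rad^2)",
    main = "Calibration goodness-of-fit (color: probe RI, size: probe nm)"))
  invisible(companion)
}
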