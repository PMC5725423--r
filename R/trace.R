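#' Uniformly sampled recording trace
#'
#' A `trace` is the package's container for a uniformly sampled current or
#' voltage time series, the raw material of every voltage-clamp and
#' current-clamp analysis here. It carries the sampling interval, start time,
#' physical unit, and optionally the (liquid-junction-corrected) holding
#' potential and a stimulus tag (grating angle in degrees or spot diameter in
#' micrometres).
#'
#' @param values Numeric vector of samples (pA for currents, mV for voltages).
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param unit Unit string, `"pA"` or `"mV"` (or `"Hz"` for rate traces such
#'   as PSTHs).
#' @param holding_mV Holding potential in mV, or `NULL` for current clamp.
#' @param tag Optional named stimulus tag, e.g. `c(angle_deg = 90)` or
#'   `c(diameter_um = 200)`.
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(sin(2 * pi * 2 * seq(0, 1, by = 1e-3)), dt = 1e-3, unit = "pA")
#' tr
#' @export
trace <- function(values, dt, t0 = 0, unit = c("pA", "mV", "Hz"),
                  holding_mV = NULL, tag = NULL) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0, length(values) >= 1L)
  if (anyNA(values)) stop("trace values must not contain NA")
  structure(
    list(values = values, dt = dt, t0 = t0, unit = unit,
         holding_mV = holding_mV, tag = tag),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  dur <- length(x$values) * x$dt
  cat(sprintf("<trace> %d samples @ dt = %g s (%.3g s), unit %s\n",
              length(x$values), x$dt, dur, x$unit))
  if (!is.null(x$holding_mV))
    cat(sprintf("  holding potential: %.2f mV\n", x$holding_mV))
  if (!is.null(x$tag))
    cat(sprintf("  tag: %s = %g\n", names(x$tag)[1], x$tag[[1]]))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Time axis of a trace
#'
#' @param x A [trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

is_trace <- function(x) inherits(x, "trace")

#' Set of cycle-averaged traces indexed by grating angle
#'
#' A `cycle_set` maps each drifting-grating direction (degrees, mod 360) to
#' one cycle-averaged [trace()] at the grating temporal frequency. All member
#' traces must share `dt` and length. This is the exchange format between the
#' synthetic generator, the current analyses and the integrate-and-fire model.
#'
#' @param traces List of [trace()] objects, one per angle.
#' @param angles_deg Numeric vector of direction angles in degrees, same
#'   length as `traces`, distinct modulo 360.
#' @param period_s Cycle period in seconds (1 / temporal frequency).
#' @return An object of class `cycle_set`.
#' @export
cycle_set <- function(traces, angles_deg, period_s) {
  stopifnot(is.list(traces), length(traces) == length(angles_deg),
            length(traces) >= 1L, period_s > 0)
  if (!all(vapply(traces, is_trace, logical(1))))
    stop("all elements of 'traces' must be trace objects")
  ang <- as.numeric(angles_deg) %% 360
  if (anyDuplicated(round(ang, 9)))
    stop("angles must be distinct modulo 360 degrees")
  dts <- vapply(traces, function(t) t$dt, numeric(1))
  lens <- vapply(traces, length, integer(1))
  if (diff(range(dts)) > 1e-12 || diff(range(lens)) > 0L)
    stop("all traces in a cycle_set must share dt and length")
  n_per <- period_s / dts[1]
  if (abs(n_per - round(n_per)) > 1e-6)
    stop("dt must divide the cycle period")
  structure(
    list(traces = traces, angles_deg = ang, period_s = period_s,
         dt = dts[1]),
    class = "cycle_set"
  )
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d angles (%s deg), period %g s, dt %g s, unit %s\n",
              length(x$angles_deg),
              paste(round(x$angles_deg, 1), collapse = ", "),
              x$period_s, x$dt, x$traces[[1]]$unit))
  invisible(x)
}

#' @export
length.cycle_set <- function(x) length(x$traces)

cycle_values <- function(cs) {
  # matrix: one column per angle, in stored order
  vapply(cs$traces, function(t) t$values, numeric(length(cs$traces[[1]])))
}

#' Write / read a trace as tab-separated text
#'
#' The TSV carries a `#`-prefixed header with the unit, sampling interval and
#' any holding-potential / stimulus metadata, followed by `time_s` and
#' `value_<unit>` columns, so traces survive a round trip through plain text.
#'
#' @param x A [trace()].
#' @param path File path.
#' @return `write_trace_tsv` returns `path` invisibly; `read_trace_tsv`
#'   returns a [trace()].
#' @export
write_trace_tsv <- function(x, path) {
  stopifnot(is_trace(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", x$unit), con)
  writeLines(sprintf("# dt_s: %.12g", x$dt), con)
  writeLines(sprintf("# t0_s: %.12g", x$t0), con)
  if (!is.null(x$holding_mV))
    writeLines(sprintf("# holding_mV: %.6g", x$holding_mV), con)
  if (!is.null(x$tag))
    writeLines(sprintf("# %s: %.6g", names(x$tag)[1], x$tag[[1]]), con)
  df <- data.frame(time_s = trace_times(x), value = x$values)
  names(df)[2] <- paste0("value_", x$unit)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", m[1]))
  }
  unit <- sub("^# unit:\\s*", "", grep("^# unit:", hdr, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  tag <- NULL
  for (key in c("angle_deg", "diameter_um")) {
    v <- get(key)
    if (!is.null(v)) tag <- stats::setNames(v, key)
  }
  trace(df[[2]], dt = get("dt_s"), t0 = get("t0_s"), unit = unit,
        holding_mV = get("holding_mV"), tag = tag)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fold an angle difference onto the orientation axis
#'
#' Orientations are 180-degree periodic, so the largest meaningful difference
#' between two preferred orientations is 90 degrees. This helper returns
#' `min |a - b|` over all 180-degree equivalents, folded into `[0, 90]` --
#' the quantity used when comparing a cell's preferred orientation with its
#' soma-to-centre-of-mass vector angle.
#'
#' @param a,b Angles in degrees (any real values).
#' @return Absolute orientation difference in degrees, in `[0, 90]`.
#' @examples
#' orientation_angle_difference(10, 190) # 0: same orientation
#' orientation_angle_difference(0, 95)   # 85
#' @export
orientation_angle_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
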