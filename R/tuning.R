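#' Tuning curve container
#'
#' Per-angle response magnitudes R(theta) from which selectivity indices and
#' preferred angles are computed. Responses must be non-negative: inward
#' currents are quantified by their magnitude *before* building the curve, so
#' that sign errors cannot silently flip a vector sum.
#'
#' @param angles_deg Direction angles in degrees (at least 3, distinct mod 360).
#' @param responses Non-negative responses, one per angle (spike count, firing
#'   rate, F1 amplitude, or |peak current|).
#' @param unit Unit of the responses (free text, recorded for provenance).
#' @param n_trials Trials per angle (recycled).
#' @return An object of class `tuning_curve`.
#' @export
tuning_curve <- function(angles_deg, responses, unit = "spikes", n_trials = 1L) {
  angles_deg <- as.numeric(angles_deg)
  responses <- as.numeric(responses)
  if (length(angles_deg) != length(responses))
    stop("angles and responses must have equal length")
  if (length(angles_deg) < 3L)
    stop("a tuning curve needs at least 3 angles")
  if (anyDuplicated(round(angles_deg %% 360, 9)))
    stop("angles must be distinct modulo 360 degrees")
  if (anyNA(responses) || any(responses < 0))
    stop("responses must be non-negative; take magnitudes of inward currents first")
  structure(
    list(angles_deg = angles_deg %% 360, responses = responses,
         unit = unit, n_trials = rep_len(as.integer(n_trials), length(responses))),
    class = "tuning_curve"
  )
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %d angles, unit %s\n", length(x$angles_deg), x$unit))
  print(data.frame(angle_deg = x$angles_deg, response = x$responses))
  invisible(x)
}

#' Vector-sum selectivity index and preferred angle
#'
#' The standard circular-variance metric for orientation and direction
#' selectivity. For responses R(theta) at direction angles theta the index is
#' \deqn{|\sum_\theta R(\theta) e^{ik\theta}| / \sum_\theta R(\theta)}
#' with k = 2 for orientation selectivity (OSI) and k = 1 for direction
#' selectivity (DSI). The preferred angle is the complex phase divided by k:
#' reported modulo 180 degrees for orientation, modulo 360 for direction.
#'
#' A perfectly untuned curve gives index 0 with an undefined preferred angle;
#' below `reliable_min` the preferred angle is still reported but flagged
#' unreliable rather than omitted.
#'
#' @param curve A [tuning_curve()].
#' @param order 2 for orientation (OSI), 1 for direction (DSI).
#' @param reliable_min Index below which `preferred_reliable` is `FALSE`
#'   (default 0.02).
#' @return List with `index` (in `[0, 1]`), `preferred_deg` (mod 180 for
#'   order 2, mod 360 for order 1; `NA` if the index is numerically 0),
#'   and `preferred_reliable`.
#' @examples
#' th <- seq(0, 330, by = 30)
#' cv <- tuning_curve(th, 1 + cos(2 * (th - 30) * pi / 180))
#' vector_sum_index(cv, order = 2) # index 0.5, preferred 30 degrees
#' @export
vector_sum_index <- function(curve, order = c(2, 1), reliable_min = 0.02) {
  stopifnot(inherits(curve, "tuning_curve"))
  order <- as.integer(order[1])
  if (!order %in% c(1L, 2L)) stop("order must be 1 (direction) or 2 (orientation)")
  R <- curve$responses
  total <- sum(R)
  if (total <= 0) stop("sum of responses is zero: selectivity index undefined")
  z <- sum(R * exp(1i * order * deg2rad(curve$angles_deg))) / total
  index <- Mod(z)
  modulus <- 360 / order
  pref <- if (index < .Machine$double.eps * 100) NA_real_ else
    (rad2deg(Arg(z)) / order) %% modulus
  # floating-point Arg of a positive-real sum can sit a hair below 0,
  # which the modulo maps to just under the modulus; snap it back
  if (is.finite(pref) && modulus - pref < 1e-9) pref <- 0
  list(index = index, preferred_deg = pref,
       preferred_reliable = is.finite(pref) && index >= reliable_min)
}

#' Cycle average of a periodic response
#'
#' Averages a trace over repeats of one temporal period of the drifting
#' grating, after discarding the first `n_discard_cycles` (onset transient).
#' Only whole cycles are used; a trailing partial cycle is dropped.
#'
#' @param trace A [trace()].
#' @param temporal_frequency_hz Grating temporal frequency in Hz.
#' @param n_discard_cycles Cycles discarded from the start (default 0).
#' @return A [trace()] of exactly one cycle (pointwise mean over retained
#'   cycles), inheriting unit and metadata.
#' @export
cycle_average <- function(trace, temporal_frequency_hz, n_discard_cycles = 0L) {
  stopifnot(is_trace(trace), temporal_frequency_hz > 0, n_discard_cycles >= 0)
  period <- 1 / temporal_frequency_hz
  n_per <- period / trace$dt
  if (abs(n_per - round(n_per)) > 1e-6)
    stop("dt does not divide the cycle period")
  n_per <- as.integer(round(n_per))
  n_cycles <- length(trace$values) %/% n_per
  if (n_cycles < n_discard_cycles + 1L)
    stop("trace too short: need at least n_discard_cycles + 1 whole cycles")
  keep <- (n_discard_cycles * n_per + 1L):(n_cycles * n_per)
  m <- matrix(trace$values[keep], nrow = n_per)
  trace(rowMeans(m), dt = trace$dt, t0 = 0, unit = trace$unit,
        holding_mV = trace$holding_mV, tag = trace$tag)
}

#' F1 amplitude of a single-cycle response
#'
#' Magnitude of the fundamental Fourier component of a cycle-averaged
#' response, in the peak-amplitude convention (a pure sinusoid of amplitude A
#' returns A, not A/sqrt(2)).
#'
#' @param cycle A [trace()] spanning exactly one period.
#' @param temporal_frequency_hz Grating temporal frequency in Hz; must equal
#'   1 / (cycle duration).
#' @return F1 amplitude, in the units of the trace.
#' @export
f1_amplitude <- function(cycle, temporal_frequency_hz) {
  stopifnot(is_trace(cycle))
  n <- length(cycle$values)
  dur <- n * cycle$dt
  if (abs(dur * temporal_frequency_hz - 1) > 1e-6)
    stop("cycle must span exactly one period of temporal_frequency_hz")
  ph <- 2 * pi * (seq_len(n) - 1L) / n
  2 * Mod(sum(cycle$values * exp(-1i * ph))) / n
}

#' Spike trains aligned to a light-step stimulus
#'
#' @param trials List of numeric vectors of spike times in seconds, one per
#'   epoch, each aligned so the stimulus onset is at `onset_s`.
#' @param onset_s,offset_s Stimulus onset and offset times (common to trials).
#' @param duration_s Total epoch duration in seconds.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(trials, onset_s, offset_s, duration_s) {
  stopifnot(is.list(trials), length(trials) >= 1L,
            onset_s >= 0, offset_s > onset_s, duration_s >= offset_s)
  trials <- lapply(trials, function(tt) {
    tt <- as.numeric(tt)
    if (is.unsorted(tt)) stop("spike times must be sorted")
    if (length(tt) && (tt[1] < 0 || tt[length(tt)] > duration_s))
      stop("spike times must lie within [0, duration_s]")
    tt
  })
  structure(list(trials = trials, onset_s = onset_s, offset_s = offset_s,
                 duration_s = duration_s),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d epochs, %.3g s each, step %g-%g s, %d spikes total\n",
              length(x$trials), x$duration_s, x$onset_s, x$offset_s,
              sum(lengths(x$trials))))
  invisible(x)
}

#' Peri-stimulus time histogram and light-step firing-rate features
#'
#' `psth` bins spikes across epochs into a trial-averaged rate trace.
#' `baseline_rate` is the mean firing rate in the 500 ms window immediately
#' before stimulus onset, averaged across epochs; `peak_offset_rate` is the
#' maximum PSTH bin within a window after stimulus offset. These are the two
#' coordinates used to classify OFF OS cells (see [classify_off_os()]).
#'
#' @param trains A [spike_trains()] object.
#' @param bin_width_s PSTH bin width in seconds (default 0.025 = 25 ms).
#' @param window_s Baseline window length before onset (default 0.5 s), or
#'   post-offset window length for the peak rate (default 1 s).
#' @return `psth` returns a [trace()] in Hz; the rate helpers return scalars
#'   in Hz.
#' @export
psth <- function(trains, bin_width_s = 0.025) {
  stopifnot(inherits(trains, "spike_trains"), bin_width_s > 0)
  breaks <- seq(0, trains$duration_s + bin_width_s, by = bin_width_s)
  counts <- rep(0, length(breaks) - 1L)
  for (tt in trains$trials) {
    if (length(tt))
      counts <- counts + tabulate(findInterval(tt, breaks,
                                               rightmost.closed = TRUE),
                                  nbins = length(counts))
  }
  rate <- counts / (length(trains$trials) * bin_width_s)
  trace(rate, dt = bin_width_s, t0 = 0, unit = "Hz")
}

#' @rdname psth
#' @export
baseline_rate <- function(trains, window_s = 0.5) {
  stopifnot(inherits(trains, "spike_trains"), window_s > 0)
  if (trains$onset_s < window_s)
    stop("pre-stimulus period shorter than the baseline window")
  lo <- trains$onset_s - window_s
  n <- vapply(trains$trials,
              function(tt) sum(tt >= lo & tt < trains$onset_s), numeric(1))
  mean(n) / window_s
}

#' @rdname psth
#' @export
peak_offset_rate <- function(trains, bin_width_s = 0.025, window_s = 1) {
  stopifnot(inherits(trains, "spike_trains"), bin_width_s > 0, window_s > 0)
  hi <- min(trains$offset_s + window_s, trains$duration_s)
  breaks <- seq(trains$offset_s, hi, by = bin_width_s)
  if (length(breaks) < 2L) stop("post-offset window is empty")
  counts <- rep(0, length(breaks) - 1L)
  for (tt in trains$trials) {
    sel <- tt[tt >= trains$offset_s & tt < hi]
    if (length(sel))
      counts <- counts + tabulate(findInterval(sel, breaks,
                                               rightmost.closed = TRUE),
                                  nbins = length(counts))
  }
  max(counts) / (length(trains$trials) * bin_width_s)
}

#' Classify an OFF cell as OFF OS by its light-step response
#'
#' OFF OS cells form a distinct low-rate cluster: the classification is a
#' strict `baseline < 50 Hz` AND `peak offset rate < 120 Hz`. The alternative
#' 135 Hz peak boundary (drawn in some displays) is available via
#' `peak_max_hz`.
#'
#' @param baseline_hz Mean baseline firing rate (Hz).
#' @param peak_offset_hz Peak light-offset firing rate (Hz).
#' @param baseline_max_hz,peak_max_hz Strict upper bounds (defaults 50, 120).
#' @return Logical flag.
#' @export
classify_off_os <- function(baseline_hz, peak_offset_hz,
                            baseline_max_hz = 50, peak_max_hz = 120) {
  stopifnot(all(baseline_hz >= 0), all(peak_offset_hz >= 0))
  baseline_hz < baseline_max_hz & peak_offset_hz < peak_max_hz
}

#' Classify a preferred orientation as horizontal or vertical
#'
#' Preferred orientations cluster around the horizontal (nasal-temporal, 0
#' degrees) and vertical (dorsoventral, 90 degrees) retinal axes. Orientations
#' in `[0, 45) U [135, 180)` are horizontal (hOS); `[45, 135)` vertical (vOS).
#' The 45-degree boundary belongs to vOS by the half-open convention.
#'
#' @param preferred_deg Preferred orientation(s) in degrees; reduced mod 180.
#' @return Character vector, `"hOS"` or `"vOS"`.
#' @export
classify_orientation_type <- function(preferred_deg) {
  a <- preferred_deg %% 180
  ifelse(a >= 45 & a < 135, "vOS", "hOS")
}
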