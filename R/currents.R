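#' Peak current within a time window
#'
#' Signed extremum of a current trace inside a stated window, in the
#' voltage-clamp sign convention (inward negative, outward positive). The
#' canonical windows are 0-200 ms after stimulus onset for the fast
#' (inhibition-dominated) component and 500-1000 ms for the sustained
#' (gap-junction) component.
#'
#' @param trace A current [trace()].
#' @param window_s Length-2 numeric, window start/end in seconds (relative to
#'   the trace time axis).
#' @param polarity `"inward"` (most negative), `"outward"` (most positive) or
#'   `"absolute"` (signed value of largest magnitude).
#' @return Peak current in pA (signed).
#' @export
peak_current <- function(trace, window_s,
                         polarity = c("inward", "outward", "absolute")) {
  stopifnot(is_trace(trace), length(window_s) == 2L, window_s[1] < window_s[2])
  polarity <- match.arg(polarity)
  tt <- trace_times(trace)
  sel <- tt >= window_s[1] & tt <= window_s[2]
  if (!any(sel)) stop("window contains no samples of the trace")
  v <- trace$values[sel]
  switch(polarity,
         inward = min(v),
         outward = max(v),
         absolute = v[which.max(abs(v))])
}

#' Build a current-voltage (IV) series from traces at multiple holdings
#'
#' @param traces List of current [trace()]s, each with `holding_mV` set; all
#'   holdings distinct, at least 3.
#' @param window_s Measurement window passed to [peak_current()].
#' @param polarity Peak polarity, see [peak_current()].
#' @param window_role Label for provenance: `"onset"` (0-200 ms convention)
#'   or `"sustained"` (500-1000 ms convention).
#' @return An `iv_series`: list with sorted `holdings_mV`, `peak_pA`,
#'   `window_s`, `window_role`.
#' @export
build_iv <- function(traces, window_s, polarity = "absolute",
                     window_role = c("onset", "sustained", "other")) {
  window_role <- match.arg(window_role)
  stopifnot(is.list(traces), length(traces) >= 3L)
  holds <- vapply(traces, function(t) {
    if (is.null(t$holding_mV)) stop("every trace needs a holding_mV")
    t$holding_mV
  }, numeric(1))
  if (anyDuplicated(holds)) stop("duplicate holding potentials")
  peaks <- vapply(traces, peak_current, numeric(1),
                  window_s = window_s, polarity = polarity)
  o <- order(holds)
  structure(list(holdings_mV = holds[o], peak_pA = peaks[o],
                 window_s = window_s, window_role = window_role),
            class = "iv_series")
}

#' @export
print.iv_series <- function(x, ...) {
  cat(sprintf("<iv_series> %d holdings, window %g-%g s (%s)\n",
              length(x$holdings_mV), x$window_s[1], x$window_s[2],
              x$window_role))
  print(data.frame(holding_mV = x$holdings_mV, peak_pA = x$peak_pA))
  invisible(x)
}

#' Construct an IV series directly from (holding, current) pairs
#'
#' @param holdings_mV,peak_pA Equal-length numeric vectors.
#' @inheritParams build_iv
#' @return An `iv_series`.
#' @export
iv_series <- function(holdings_mV, peak_pA, window_s = c(0, 0.2),
                      window_role = "other") {
  stopifnot(length(holdings_mV) == length(peak_pA))
  if (anyDuplicated(holdings_mV)) stop("duplicate holding potentials")
  o <- order(holdings_mV)
  structure(list(holdings_mV = as.numeric(holdings_mV)[o],
                 peak_pA = as.numeric(peak_pA)[o],
                 window_s = window_s, window_role = window_role),
            class = "iv_series")
}

#' Reversal potential and electrical-vs-chemical classification
#'
#' Fits the least-squares line I = g (V - E) through an IV series. A current
#' from a chemical synapse scales with holding potential and reverses at E;
#' a gap-junction (electrical) current remains constant in magnitude and does
#' not reverse, i.e. its IV slope is essentially zero. When the fitted slope
#' magnitude is below `flat_threshold_nS` the source is classified
#' `"electrical"` and the reversal potential is undefined (`NA`).
#'
#' @param iv An `iv_series` with at least 3 points.
#' @param flat_threshold_nS Slope magnitude below which the IV is flat
#'   (default 0.1 nS, an order of magnitude below typical chemical slopes).
#' @return List with `kind` (`"chemical"` or `"electrical"`), `slope_nS`,
#'   `reversal_mV` (`NA` for electrical), `intercept_pA`.
#' @examples
#' est <- estimate_reversal(iv_series(c(-80, -60, 0), c(-20, 0, 60)))
#' est$reversal_mV # -60
#' @export
estimate_reversal <- function(iv, flat_threshold_nS = 0.1) {
  stopifnot(inherits(iv, "iv_series"))
  if (length(iv$holdings_mV) < 3L)
    stop("reversal fitting needs at least 3 holding potentials")
  fit <- stats::lm.fit(cbind(1, iv$holdings_mV), iv$peak_pA)
  b <- unname(fit$coefficients) # pA = b1 + b2 * mV; slope pA/mV = nS
  slope <- b[2]
  if (abs(slope) < flat_threshold_nS) {
    list(kind = "electrical", slope_nS = slope, reversal_mV = NA_real_,
         intercept_pA = b[1])
  } else {
    list(kind = "chemical", slope_nS = slope, reversal_mV = -b[1] / slope,
         intercept_pA = b[1])
  }
}

#' Pointwise subtraction of currents recorded at two reversal potentials
#'
#' The inhibitory current is isolated by subtracting the record at the
#' chloride reversal potential (gap-junction current only) from the record at
#' the cation reversal potential (gap junction + inhibition).
#'
#' @param I_at_Ecat,I_at_ECl Current [trace()]s of equal length and dt.
#' @return A [trace()] of the difference (`I_at_Ecat - I_at_ECl`).
#' @export
subtract_currents <- function(I_at_Ecat, I_at_ECl) {
  stopifnot(is_trace(I_at_Ecat), is_trace(I_at_ECl))
  if (length(I_at_Ecat$values) != length(I_at_ECl$values) ||
      abs(I_at_Ecat$dt - I_at_ECl$dt) > 1e-12)
    stop("traces must share length and dt")
  trace(I_at_Ecat$values - I_at_ECl$values, dt = I_at_Ecat$dt,
        t0 = I_at_Ecat$t0, unit = "pA", tag = I_at_Ecat$tag)
}

#' Convert a clamped current to a conductance waveform
#'
#' g(t) = I(t) / (V_hold - V_rev), with pA / mV giving nS directly.
#'
#' @param I A current [trace()] in pA.
#' @param V_hold_mV Clamped (liquid-junction-corrected) potential, mV.
#' @param V_rev_mV Reversal potential of the conductance, mV.
#' @return Numeric vector g(t) in nS (same sampling as `I`).
#' @export
conductance_from_current <- function(I, V_hold_mV, V_rev_mV) {
  stopifnot(is_trace(I))
  drive <- V_hold_mV - V_rev_mV
  if (abs(drive) <= 1)
    stop("V_hold within 1 mV of V_rev: conductance is ill-defined")
  I$values / drive
}

#' Remove spikes from a current-clamp trace by sliding-window averaging
#'
#' Centred moving average with a 25 ms default window (250 samples at the
#' 10 kHz acquisition rate), which attenuates millisecond-scale action
#' potentials by more than an order of magnitude while leaving the 2 Hz
#' subthreshold grating oscillation essentially untouched (sinc attenuation
#' about 0.4% at 2 Hz). Edges are handled by shrinking the window, so the
#' trace length is preserved.
#'
#' @param Vm A voltage [trace()].
#' @param window_ms Averaging window in milliseconds (default 25).
#' @return A smoothed [trace()] of equal length.
#' @export
remove_spikes <- function(Vm, window_ms = 25) {
  stopifnot(is_trace(Vm), window_ms > 0)
  n <- length(Vm$values)
  w <- as.integer(round(window_ms * 1e-3 / Vm$dt))
  if (w >= n) stop("window must be shorter than the trace")
  if (w <= 1L) return(Vm)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- cumsum(c(0, Vm$values))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  trace(sm, dt = Vm$dt, t0 = Vm$t0, unit = Vm$unit,
        holding_mV = Vm$holding_mV, tag = Vm$tag)
}

#' Percentage change of a peak current under a pharmacological manipulation
#'
#' 100 * (after - before) / |before|, so a block that removes 62% of an
#' outward current reports -62 regardless of the current's sign.
#'
#' @param peak_before_pA,peak_after_pA Peak currents (pA); before must be
#'   non-zero.
#' @return Percentage change.
#' @export
percent_change <- function(peak_before_pA, peak_after_pA) {
  if (any(peak_before_pA == 0)) stop("baseline peak is zero")
  100 * (peak_after_pA - peak_before_pA) / abs(peak_before_pA)
}

#' Nernst equilibrium potential
#'
#' E = (RT / zF) ln(c_out / c_in), in mV. With the Ames-medium chloride
#' concentration (105 mM outside) and the caesium internal solution
#' (12 mM chloride: 10 TEA-Cl + 2 QX-314), z = -1 and T = 305 K give
#' E_Cl of about -57 mV.
#'
#' @param c_out_mM,c_in_mM Concentrations (mM), > 0.
#' @param z Ion valence (e.g. -1 for chloride).
#' @param T_K Absolute temperature in kelvin (default 305, i.e. 32 C).
#' @return Equilibrium potential in mV.
#' @examples
#' nernst(105, 12, z = -1) # about -57 mV
#' @export
nernst <- function(c_out_mM, c_in_mM, z, T_K = 305) {
  if (any(c_out_mM <= 0) || any(c_in_mM <= 0))
    stop("concentrations must be positive")
  stopifnot(z != 0, T_K > 0)
  R_gas <- 8.314462618   # J / (mol K)
  F_far <- 96485.33212   # C / mol
  1000 * (R_gas * T_K) / (z * F_far) * log(c_out_mM / c_in_mM)
}

#' Liquid-junction-potential correction
#'
#' Reported membrane potentials are the commanded values plus the measured
#' liquid junction potential (default -8.58 mV for the caesium internal
#' solution): a -60 mV command reports as -68.58 mV. Note the sign
#' convention: the LJP value is *added* to the command.
#'
#' @param V_cmd_mV Commanded potential(s), mV.
#' @param ljp_mV Liquid junction potential, mV (default -8.58).
#' @return Corrected potential(s), mV.
#' @export
ljp_correct <- function(V_cmd_mV, ljp_mV = -8.58) {
  V_cmd_mV + ljp_mV
}

#' Normalize an IV series to its maximum-magnitude current
#'
#' Population-averaged IV curves are built by normalizing each cell's
#' currents across all voltages to that cell's maximum-magnitude current
#' (so every cell's normalized IV has max |value| = 1), then averaging
#' across cells.
#'
#' @param iv An `iv_series`.
#' @return The `iv_series` with `peak_pA` scaled to max magnitude 1.
#' @export
normalize_iv <- function(iv) {
  stopifnot(inherits(iv, "iv_series"))
  m <- max(abs(iv$peak_pA))
  if (m == 0) stop("all currents are zero: cannot normalize")
  iv$peak_pA <- iv$peak_pA / m
  iv
}

#' Spot-size tuning table from per-diameter traces at two potentials
#'
#' For each stimulus diameter, measures the outward peak at the cation
#' reversal potential in the onset window (inhibition) and at the chloride
#' reversal potential in the sustained window (gap junction), and summarizes
#' spatial profiles: the diameter of maximal response and the
#' large-spot / maximum ratio (surround-suppression index; 1 means no
#' suppression). Inhibition is surround-suppressed (interior optimum) while
#' the gap-junction input is wide-field (ratio near 1).
#'
#' @param traces_Ecat,traces_ECl Lists of current [trace()]s tagged with
#'   `diameter_um`, one per diameter (same diameters in both lists).
#' @param window_Ecat_s,window_ECl_s Measurement windows in seconds
#'   (defaults 0-200 ms and 500-1000 ms).
#' @param polarity Peak polarity (default `"outward"`).
#' @return List with `table` (data.frame: diameter_um, peak_Ecat_pA,
#'   peak_ECl_pA), `argmax_um` and `suppression_ratio` per potential
#'   (`NA`-flagged when only one diameter is supplied).
#' @export
size_tuning <- function(traces_Ecat, traces_ECl,
                        window_Ecat_s = c(0, 0.2),
                        window_ECl_s = c(0.5, 1),
                        polarity = "outward") {
  get_diam <- function(t) {
    if (is.null(t$tag) || names(t$tag)[1] != "diameter_um")
      stop("every trace must be tagged with diameter_um")
    unname(t$tag[[1]])
  }
  d1 <- vapply(traces_Ecat, get_diam, numeric(1))
  d2 <- vapply(traces_ECl, get_diam, numeric(1))
  if (!identical(sort(d1), sort(d2)))
    stop("diameter sets differ between the two potentials")
  o1 <- order(d1); o2 <- order(d2)
  p_cat <- vapply(traces_Ecat[o1], peak_current, numeric(1),
                  window_s = window_Ecat_s, polarity = polarity)
  p_cl <- vapply(traces_ECl[o2], peak_current, numeric(1),
                 window_s = window_ECl_s, polarity = polarity)
  tab <- data.frame(diameter_um = d1[o1], peak_Ecat_pA = p_cat,
                    peak_ECl_pA = p_cl)
  summ <- function(p, d) {
    if (length(d) < 2L || max(abs(p)) == 0)
      return(list(argmax_um = NA_real_, suppression_ratio = NA_real_))
    list(argmax_um = d[which.max(p)],
         suppression_ratio = p[length(p)] / max(p))
  }
  list(table = tab,
       Ecat = summ(p_cat, tab$diameter_um),
       ECl = summ(p_cl, tab$diameter_um))
}
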