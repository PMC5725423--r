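#' Parameters of the conductance-based leaky integrate-and-fire model
#'
#' Subthreshold dynamics follow
#' \deqn{\tau \, dV/dt = V_{rest} - V(t) - R \, I_{ext}(t)}
#' with the external current decomposed into the gap-junction current and an
#' inhibitory conductance,
#' \deqn{I_{ext}(t) = I_{gj}(t) + (V(t) - V_{rev,inh}) \, g_{inh}(t).}
#' A spike is recorded when V crosses `V_th`; V resets to `V_reset` and the
#' membrane time constant is temporarily increased to `tau_refractory` for
#' `refractory_duration` to mimic refractoriness. Sign convention: outward
#' current is positive and hyperpolarizes (the minus sign in the equation),
#' so the outward gap-junction current at light onset suppresses firing.
#'
#' Default constants are generic small-RGC values: `tau` 15 ms and `R`
#' 500 MOhm imply a 30 pF cell; thresholds -45/-65/-60 mV; the refractory
#' swap triples the effective sluggishness after each spike for 3 ms.
#'
#' @param tau_ms Membrane time constant (default 15 ms).
#' @param R_Mohm Leak resistance (default 500 MOhm).
#' @param V_rest_mV,V_th_mV,V_reset_mV Resting, threshold and reset
#'   potentials (defaults -60, -45, -65 mV).
#' @param tau_refractory_ms Temporarily increased time constant after a
#'   spike (default 45 ms; must be >= `tau_ms`).
#' @param refractory_ms Duration of the increased time constant (default
#'   3 ms).
#' @param V_rev_inh_mV Inhibitory reversal potential (default -67 mV, the
#'   measured reversal of the onset current).
#' @param dt_ms Integration step (default 0.1 ms).
#' @param t_total_s Simulated duration per grating angle (default 5 s).
#' @return Validated list of class `lif_params`.
#' @export
lif_params <- function(tau_ms = 15, R_Mohm = 500, V_rest_mV = -60,
                       V_th_mV = -45, V_reset_mV = -65,
                       tau_refractory_ms = 45, refractory_ms = 3,
                       V_rev_inh_mV = -67, dt_ms = 0.1, t_total_s = 5) {
  p <- list(tau_ms = tau_ms, R_Mohm = R_Mohm, V_rest_mV = V_rest_mV,
            V_th_mV = V_th_mV, V_reset_mV = V_reset_mV,
            tau_refractory_ms = tau_refractory_ms,
            refractory_ms = refractory_ms, V_rev_inh_mV = V_rev_inh_mV,
            dt_ms = dt_ms, t_total_s = t_total_s)
  if (p$tau_ms <= 0 || p$R_Mohm <= 0 || p$dt_ms <= 0 || p$refractory_ms <= 0)
    stop("tau, R, dt and refractory_duration must be positive")
  if (p$V_reset_mV > p$V_th_mV) stop("V_reset must not exceed V_th")
  if (p$tau_refractory_ms < p$tau_ms)
    stop("tau_refractory must be >= tau")
  if (p$t_total_s <= 0) stop("t_total must be positive")
  structure(p, class = "lif_params")
}

#' Build per-angle model inputs from measured cycle averages
#'
#' Converts the inhibitory current cycle (recorded in voltage clamp at
#' `V_hold_inh_mV`, typically the cation reversal potential) into a
#' conductance waveform via [conductance_from_current()], tiles both the
#' gap-junction current and the conductance to cover `t_total_s`, and
#' returns them per angle. The gap-junction current is passed through
#' unchanged in the voltage-clamp sign convention (outward positive).
#' Negative conductance samples (noise artefacts of the current
#' subtraction) are clipped at zero by default.
#'
#' @param gj_cycles,inh_cycles [cycle_set()]s sharing angles and dt: the
#'   gap-junction current (pA) and the inhibitory current (pA) cycles.
#' @param V_hold_inh_mV Holding potential of the inhibition measurement
#'   (default +10 mV).
#' @param V_rev_inh_mV Inhibitory reversal potential (default -67 mV).
#' @param t_total_s Total simulated duration (default 5 s).
#' @param clip_negative_g Clip negative conductances at 0 (default TRUE).
#' @return An object of class `sim_inputs`: per-angle `I_gj_pA` and
#'   `g_inh_nS` waveform lists plus `angles_deg` and `dt_ms`.
#' @export
build_inputs <- function(gj_cycles, inh_cycles, V_hold_inh_mV = 10,
                         V_rev_inh_mV = -67, t_total_s = 5,
                         clip_negative_g = TRUE) {
  stopifnot(inherits(gj_cycles, "cycle_set"), inherits(inh_cycles, "cycle_set"))
  if (length(gj_cycles$angles_deg) != length(inh_cycles$angles_deg) ||
      any(abs(gj_cycles$angles_deg - inh_cycles$angles_deg) > 1e-9))
    stop("gap-junction and inhibition cycle sets must share the same angles")
  if (abs(gj_cycles$dt - inh_cycles$dt) > 1e-12)
    stop("cycle sets must share dt")
  n_tile <- ceiling(t_total_s / gj_cycles$period_s)
  n_keep <- as.integer(round(t_total_s / gj_cycles$dt))
  tile <- function(v) rep(v, n_tile)[seq_len(n_keep)]
  g_of <- function(tr) {
    g <- conductance_from_current(tr, V_hold_inh_mV, V_rev_inh_mV)
    if (clip_negative_g) g <- pmax(g, 0)
    g
  }
  structure(
    list(angles_deg = gj_cycles$angles_deg,
         I_gj_pA = lapply(gj_cycles$traces, function(tr) tile(tr$values)),
         g_inh_nS = lapply(inh_cycles$traces, function(tr) tile(g_of(tr))),
         dt_ms = gj_cycles$dt * 1000),
    class = "sim_inputs"
  )
}

#' @export
print.sim_inputs <- function(x, ...) {
  cat(sprintf("<sim_inputs> %d angles, %d samples per angle @ dt = %g ms\n",
              length(x$angles_deg), length(x$I_gj_pA[[1]]), x$dt_ms))
  invisible(x)
}

#' Simulate the integrate-and-fire response to one angle's inputs
#'
#' Forward-Euler integration of the model in [lif_params()] at step `dt_ms`.
#' Deterministic given inputs.
#'
#' @param params A [lif_params()] object.
#' @param I_gj_pA Gap-junction current waveform (pA, outward positive),
#'   sampled at `params$dt_ms`.
#' @param g_inh_nS Inhibitory conductance waveform (nS), same length
#'   (default 0).
#' @param V0_mV Initial voltage (default `V_rest`).
#' @return List with `V` (a voltage [trace()]), `spike_times_s`, `n_spikes`.
#' @export
simulate_lif <- function(params, I_gj_pA, g_inh_nS = NULL, V0_mV = NULL) {
  stopifnot(inherits(params, "lif_params"))
  I_gj_pA <- as.numeric(I_gj_pA)
  if (is.null(g_inh_nS)) g_inh_nS <- numeric(length(I_gj_pA)) else
    g_inh_nS <- as.numeric(g_inh_nS)
  if (length(g_inh_nS) != length(I_gj_pA))
    stop("I_gj and g_inh must have equal length")
  if (is.null(V0_mV)) V0_mV <- params$V_rest_mV
  out <- lif_euler_cpp(I_gj_pA, g_inh_nS, params$dt_ms, params$tau_ms,
                       params$R_Mohm, params$V_rest_mV, params$V_th_mV,
                       params$V_reset_mV, params$tau_refractory_ms,
                       params$refractory_ms, params$V_rev_inh_mV, V0_mV)
  list(V = trace(out$V_mV, dt = params$dt_ms / 1000,
                 t0 = params$dt_ms / 1000, unit = "mV"),
       spike_times_s = out$spike_times_ms / 1000,
       n_spikes = length(out$spike_times_ms))
}

#' Simulate a full grating sweep and measure the model's tuning
#'
#' Runs [simulate_lif()] for every angle of a [build_inputs()] object,
#' counts spikes over the simulated duration, and computes the model's
#' orientation tuning with [vector_sum_index()] (order 2). If the model is
#' silent at every angle the index is reported as 0 with an undefined
#' preferred angle.
#'
#' @param params A [lif_params()] object.
#' @param inputs A `sim_inputs` object.
#' @return List with `curve` (a [tuning_curve()] of spike counts, or `NULL`
#'   if silent), `osi`, `preferred_deg`, `counts`, `angles_deg`.
#' @export
grating_sweep <- function(params, inputs) {
  stopifnot(inherits(inputs, "sim_inputs"))
  if (length(inputs$angles_deg) < 3) stop("need at least 3 angles")
  if (abs(inputs$dt_ms - params$dt_ms) > 1e-9)
    stop("inputs dt does not match params dt")
  counts <- vapply(seq_along(inputs$angles_deg), function(i) {
    simulate_lif(params, inputs$I_gj_pA[[i]], inputs$g_inh_nS[[i]])$n_spikes
  }, numeric(1))
  if (sum(counts) == 0) {
    return(list(curve = NULL, osi = 0, preferred_deg = NA_real_,
                counts = counts, angles_deg = inputs$angles_deg))
  }
  curve <- tuning_curve(inputs$angles_deg, counts, unit = "spikes")
  vs <- vector_sum_index(curve, order = 2)
  list(curve = curve, osi = vs$index, preferred_deg = vs$preferred_deg,
       counts = counts, angles_deg = inputs$angles_deg)
}

# OSI of a raw count vector without container overhead (bootstrap hot path)
osi_of_counts <- function(counts, angles_rad2) {
  tot <- sum(counts)
  if (tot <= 0) return(0)
  Mod(sum(counts * angles_rad2)) / tot
}
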