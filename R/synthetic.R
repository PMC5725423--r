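#' Orientation-tuned weight profile with an exact vector-sum index
#'
#' Returns non-negative weights w(theta) in `[0, 1]` over the given direction
#' angles, peaking at `pref_deg`, whose orientation vector-sum index (order
#' 2, see [vector_sum_index()]) equals `osi` on that angle grid.
#'
#' Two regimes are used. For shallow tuning (`osi < 0.3`) the profile is the
#' classic cosine
#' \deqn{w(\theta) = (1 + m \cos 2(\theta - \mathrm{pref})) / (1 + m)}
#' whose index on a uniform grid is exactly m/2 (m is still solved
#' numerically so the identity holds on any grid). For `osi >= 0.3` the
#' profile is the raised-cosine power
#' \deqn{w(\theta) = ((1 + \cos 2(\theta - \mathrm{pref})) / 2)^p,}
#' which is exactly zero at the null orientation -- matching the recorded
#' structure in which null-orientation gap-junction cycles carry no inward
#' component -- and reaches any index up to 1 (p = 1 recovers the cosine at
#' index 0.5). A profile with exact null zeros cannot have an index below
#' (n-2)/n on an n-direction grid, which is why shallow targets fall back to
#' the strictly positive cosine. `osi = 1` returns an indicator on the
#' angles nearest the preferred orientation.
#'
#' @param angles_deg Direction angles in degrees (>= 3, distinct mod 360).
#' @param pref_deg Preferred orientation in degrees.
#' @param osi Requested orientation index in `[0, 1]`.
#' @return Numeric weights, one per angle, max 1.
#' @export
tuning_profile <- function(angles_deg, pref_deg, osi) {
  if (osi < 0 || osi > 1) stop("osi must lie in [0, 1]")
  d <- deg2rad(angles_deg - pref_deg)
  cos2d <- cos(2 * d)
  base <- (1 + cos2d) / 2
  if (osi == 0) return(rep(1, length(angles_deg)))
  if (osi == 1) return(as.numeric(base >= max(base) - 1e-12))
  idx_of <- function(w)
    vector_sum_index(tuning_curve(angles_deg, w, unit = "weight"))$index
  if (osi < 0.3) {
    # cosine regime: index = m/2 on a uniform grid; solved for exactness
    f <- function(m) idx_of((1 + m * cos2d) / (1 + m)) - osi
    if (f(1) < 0)
      stop(sprintf("osi = %g unreachable in the cosine regime on this grid",
                   osi))
    m <- stats::uniroot(f, c(1e-12, 1), tol = 1e-12)$root
    (1 + m * cos2d) / (1 + m)
  } else {
    f <- function(p) idx_of(base^p) - osi
    if (f(500) < 0)
      stop(sprintf("osi = %g unreachable for this angle grid / preferred angle",
                   osi))
    p <- stats::uniroot(f, c(1e-9, 500), tol = 1e-12)$root
    base^p
  }
}

#' Parameters of the synthetic drifting-grating current generator
#'
#' Describes the stimulus and the target statistical structure of the two
#' synaptic inputs of an OFF OS cell: a gap-junction current whose outward
#' (light-phase) lobe has fixed amplitude and whose inward (dark-phase) lobe
#' carries the orientation tuning, and an inhibitory current that is outward
#' only and roughly ten-fold larger, untuned by default.
#'
#' @param angles_deg Grating directions, degrees (default 12, uniform over
#'   360).
#' @param temporal_frequency_hz Grating temporal frequency (default 2 Hz).
#' @param stimulus_duration_s Stimulus duration (default 5 s).
#' @param pref_orientation_deg Preferred orientation in `[0, 180)`
#'   (default 90, a vertical-preferring cell).
#' @param osi_gj Target orientation index of the gap-junction inward lobe
#'   (default 0.4).
#' @param osi_inh Target orientation index of inhibition (default 0:
#'   untuned).
#' @param gj_peak_outward_pA Outward peak of the gap-junction cycle
#'   (default 80 pA).
#' @param gj_inward_depth_pref_pA Inward excursion below baseline in the
#'   preferred orientation (default 120 pA; not constrained by recordings --
#'   chosen so the default integrate-and-fire cell fires at ~100 Hz in the
#'   preferred dark phase, see package vignette).
#' @param inh_peak_outward_pA Outward peak of inhibition at the cation
#'   reversal potential (default 757 pA).
#' @param noise_sd_pA Additive Gaussian noise SD (default 0; noise is
#'   opt-in).
#' @param dt_s Sampling interval (default 1e-4 s = 0.1 ms); must divide the
#'   cycle period.
#' @param seed Integer seed.
#' @return Validated list of class `grating_params`.
#' @export
grating_params <- function(angles_deg = seq(0, 330, by = 30),
                           temporal_frequency_hz = 2,
                           stimulus_duration_s = 5,
                           pref_orientation_deg = 90,
                           osi_gj = 0.4, osi_inh = 0,
                           gj_peak_outward_pA = 80,
                           gj_inward_depth_pref_pA = 120,
                           inh_peak_outward_pA = 757,
                           noise_sd_pA = 0,
                           dt_s = 1e-4, seed = 1L) {
  p <- list(angles_deg = as.numeric(angles_deg),
            temporal_frequency_hz = temporal_frequency_hz,
            cycle_duration_s = 1 / temporal_frequency_hz,
            stimulus_duration_s = stimulus_duration_s,
            pref_orientation_deg = pref_orientation_deg %% 180,
            osi_gj = osi_gj, osi_inh = osi_inh,
            gj_peak_outward_pA = gj_peak_outward_pA,
            gj_inward_depth_pref_pA = gj_inward_depth_pref_pA,
            inh_peak_outward_pA = inh_peak_outward_pA,
            noise_sd_pA = noise_sd_pA, dt_s = dt_s, seed = as.integer(seed))
  if (length(p$angles_deg) < 3 || anyDuplicated(round(p$angles_deg %% 360, 9)))
    stop("angles must be at least 3, distinct modulo 360")
  if (p$osi_gj < 0 || p$osi_gj > 1 || p$osi_inh < 0 || p$osi_inh > 1)
    stop("osi_gj and osi_inh must lie in [0, 1]")
  if (p$gj_peak_outward_pA <= 0 || p$inh_peak_outward_pA <= 0 ||
      p$gj_inward_depth_pref_pA < 0)
    stop("amplitudes must be positive")
  if (p$dt_s <= 0) stop("dt must be positive")
  n_per <- p$cycle_duration_s / p$dt_s
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("dt must divide the cycle duration")
  if (p$noise_sd_pA < 0) stop("noise_sd must be non-negative")
  structure(p, class = "grating_params")
}

#' Generate cycle-averaged gap-junction and inhibitory grating currents
#'
#' One cycle-average [trace()] per grating direction per current type,
#' emulating the recorded structure: the gap-junction current is a half-wave
#' sinusoid whose outward (light-phase) lobe has fixed amplitude at every
#' angle and whose inward (dark-phase) lobe depth follows an
#' orientation-tuned profile, so it dips below baseline (net inward) in the
#' preferred orientation and is everywhere outward in the null orientation.
#' Inhibition is outward-only, with the same phase, untuned unless
#' `osi_inh > 0`. The vector-sum index of the per-angle peak-inward
#' magnitudes equals `osi_gj` exactly in the noise-free case (see
#' [tuning_profile()]).
#'
#' @param params A [grating_params()] object.
#' @return List with elements `gj` and `inh`, each a [cycle_set()].
#' @export
gen_grating_currents <- function(params) {
  stopifnot(inherits(params, "grating_params"))
  n <- as.integer(round(params$cycle_duration_s / params$dt_s))
  phase <- 2 * pi * (seq_len(n) - 1L) / n
  s <- sin(phase)
  pos <- pmax(s, 0)
  neg <- pmin(s, 0)
  w_gj <- tuning_profile(params$angles_deg, params$pref_orientation_deg,
                         params$osi_gj)
  w_inh <- tuning_profile(params$angles_deg, params$pref_orientation_deg,
                          params$osi_inh)
  withr::with_seed(params$seed, {
    mk <- function(values, angle) {
      if (params$noise_sd_pA > 0)
        values <- values + stats::rnorm(n, 0, params$noise_sd_pA)
      trace(values, dt = params$dt_s, unit = "pA",
            tag = c(angle_deg = angle))
    }
    gj <- mapply(function(a, w) {
      mk(params$gj_peak_outward_pA * pos +
           params$gj_inward_depth_pref_pA * w * neg, a)
    }, params$angles_deg, w_gj, SIMPLIFY = FALSE)
    inh <- mapply(function(a, w) {
      mk(params$inh_peak_outward_pA * w * pos, a)
    }, params$angles_deg, w_inh, SIMPLIFY = FALSE)
  })
  list(gj = cycle_set(gj, params$angles_deg, params$cycle_duration_s),
       inh = cycle_set(inh, params$angles_deg, params$cycle_duration_s))
}

#' Parameters of the synthetic light-step spike generator
#'
#' @param baseline_rate_hz Baseline firing rate in darkness (default 20 Hz).
#' @param pre_duration_s Pre-stimulus duration (>= 0.5 s; default 1).
#' @param step_duration_s Light-step duration (default 1 s).
#' @param post_duration_s Post-offset duration (default 1.5 s).
#' @param recovery_tau_s Time constant of the rate recovery after light
#'   offset (default 0.2 s).
#' @param overshoot_factor Fractional overshoot of the recovered rate above
#'   baseline (default 0.2).
#' @param n_epochs Number of independent trials (default 10).
#' @param seed Integer seed.
#' @return Validated list of class `step_params`.
#' @export
step_params <- function(baseline_rate_hz = 20, pre_duration_s = 1,
                        step_duration_s = 1, post_duration_s = 1.5,
                        recovery_tau_s = 0.2, overshoot_factor = 0.2,
                        n_epochs = 10L, seed = 1L) {
  p <- list(baseline_rate_hz = baseline_rate_hz,
            pre_duration_s = pre_duration_s,
            step_duration_s = step_duration_s,
            post_duration_s = post_duration_s,
            recovery_tau_s = recovery_tau_s,
            overshoot_factor = overshoot_factor,
            n_epochs = as.integer(n_epochs), seed = as.integer(seed))
  if (p$baseline_rate_hz < 0) stop("baseline rate must be >= 0")
  if (p$pre_duration_s < 0.5) stop("pre_duration must be at least 0.5 s")
  if (p$step_duration_s <= 0 || p$post_duration_s <= 0 ||
      p$recovery_tau_s <= 0)
    stop("durations and recovery_tau must be positive")
  if (p$overshoot_factor < 0) stop("overshoot_factor must be >= 0")
  if (p$n_epochs < 1) stop("need at least one epoch")
  structure(p, class = "step_params")
}

#' Generate OFF-type light-step spike trains
#'
#' Inhomogeneous Poisson spikes with the OFF OS response profile: firing at
#' the baseline rate before the light step, complete suppression during the
#' step, and after light offset an exponential recovery (time constant
#' `recovery_tau_s`) towards `baseline * (1 + overshoot_factor)`. Spikes are
#' drawn by thinning a homogeneous process, so identical parameters and seed
#' give identical trains.
#'
#' @param params A [step_params()] object.
#' @return A [spike_trains()] object with `n_epochs` trials.
#' @export
gen_light_step_spikes <- function(params) {
  stopifnot(inherits(params, "step_params"))
  onset <- params$pre_duration_s
  offset <- onset + params$step_duration_s
  total <- offset + params$post_duration_s
  peak <- params$baseline_rate_hz * (1 + params$overshoot_factor)
  rate_fn <- function(t) {
    ifelse(t < onset, params$baseline_rate_hz,
           ifelse(t < offset, 0,
                  peak * (1 - exp(-(t - offset) / params$recovery_tau_s))))
  }
  trials <- withr::with_seed(params$seed, {
    lapply(seq_len(params$n_epochs), function(i) {
      if (peak <= 0) return(numeric(0))
      n_cand <- stats::rpois(1, peak * total)
      cand <- sort(stats::runif(n_cand, 0, total))
      keep <- stats::runif(n_cand) < rate_fn(cand) / peak
      cand[keep]
    })
  })
  spike_trains(trials, onset_s = onset, offset_s = offset, duration_s = total)
}

#' Parameters of the synthetic dendritic-arbor generator
#'
#' @param soma_xy_um Soma position, length-2 (default origin).
#' @param mean_radius_um Geometric-mean field radius (default 120).
#' @param elongation Axis ratio >= 1 (default 1: circular field).
#' @param orientation_deg Long-axis orientation, degrees (default 0).
#' @param com_offset_um Offset of the field centre from the soma, length-2
#'   vector in micrometres (default none). A vertical-type arbor is emulated
#'   with `c(0, -145)` (ventral offset).
#' @param n_perimeter_points Perimeter resampling count (default 1000).
#' @param jaggedness_sd_um SD of radial perimeter noise (default 0).
#' @param seed Integer seed.
#' @return Validated list of class `arbor_params`.
#' @export
arbor_params <- function(soma_xy_um = c(0, 0), mean_radius_um = 120,
                         elongation = 1, orientation_deg = 0,
                         com_offset_um = c(0, 0),
                         n_perimeter_points = 1000L,
                         jaggedness_sd_um = 0, seed = 1L) {
  p <- list(soma_xy_um = as.numeric(soma_xy_um),
            mean_radius_um = mean_radius_um, elongation = elongation,
            orientation_deg = orientation_deg,
            com_offset_um = as.numeric(com_offset_um),
            n_perimeter_points = as.integer(n_perimeter_points),
            jaggedness_sd_um = jaggedness_sd_um, seed = as.integer(seed))
  if (length(p$soma_xy_um) != 2 || length(p$com_offset_um) != 2)
    stop("soma_xy and com_offset must be length-2")
  if (p$mean_radius_um <= 0) stop("mean_radius must be positive")
  if (p$elongation < 1) stop("elongation must be >= 1")
  if (p$n_perimeter_points < 8) stop("need at least 8 perimeter points")
  if (p$jaggedness_sd_um < 0) stop("jaggedness_sd must be >= 0")
  structure(p, class = "arbor_params")
}

#' Generate a synthetic dendritic-field outline
#'
#' An (optionally elongated, optionally soma-offset) ellipse with optional
#' radial jagged noise, resampled to `n_perimeter_points` at uniform arc
#' length. Radial noise keeps the outline a simple polygon by construction;
#' if the noise would drive the radius non-positive the arbor is regenerated
#' with the noise halved, with a warning.
#'
#' @param params An [arbor_params()] object.
#' @return An [arbor_polygon()] with provenance `"synthetic"`.
#' @export
gen_morphology <- function(params) {
  stopifnot(inherits(params, "arbor_params"))
  centre <- params$soma_xy_um + params$com_offset_um
  a <- params$mean_radius_um * sqrt(params$elongation)
  b <- params$mean_radius_um / sqrt(params$elongation)
  th0 <- deg2rad(params$orientation_deg)
  n_dense <- max(4096L, 4L * params$n_perimeter_points)
  phi <- 2 * pi * (seq_len(n_dense) - 1L) / n_dense
  sd_try <- params$jaggedness_sd_um
  repeat {
    noise <- if (sd_try > 0) {
      withr::with_seed(params$seed, stats::rnorm(n_dense, 0, sd_try))
    } else rep(0, n_dense)
    # radius of the rotated ellipse along polar angle phi, plus radial noise
    r_ell <- (a * b) / sqrt((b * cos(phi - th0))^2 + (a * sin(phi - th0))^2)
    r <- r_ell + noise
    if (all(r > 0)) break
    warning("jagged perimeter collapsed through the centre; ",
            "halving jaggedness_sd and regenerating")
    sd_try <- sd_try / 2
  }
  xy <- cbind(centre[1] + r * cos(phi), centre[2] + r * sin(phi))
  arbor_polygon_from_perimeter(xy, soma_xy = params$soma_xy_um,
                               n = params$n_perimeter_points,
                               provenance = "synthetic")
}

#' Generate a synthetic IV family
#'
#' Emulates light-evoked currents measured over a range of holding
#' potentials. A chemical (conductance-based) source scales linearly with
#' driving force and reverses at `E_rev`; an electrical (gap-junction)
#' source is the same at every holding potential -- the flat-IV signature
#' used to identify coupling.
#'
#' @param mechanism List: either `list(kind = "chemical", E_rev_mV=, g_nS=)`
#'   or `list(kind = "electrical", I_const_pA=)`.
#' @param holdings_mV At least 3 distinct holding potentials.
#' @param noise_sd_pA SD of the measurement noise: one Gaussian draw per
#'   holding potential, added to the evoked amplitude, so the measured IV
#'   point is exactly I = g (V - E_rev) + noise (or I_const + noise). A
#'   per-sample noise model would bias the windowed peak towards extreme
#'   noise excursions; amplitude noise matches how trial-averaged peaks
#'   behave. Default 0.
#' @param seed Integer seed.
#' @param dt_s,duration_s Trace sampling (defaults 1 ms, 1.2 s); the current
#'   turns on at 0.2 s.
#' @return List with `iv` (an `iv_series` measured from the traces in a
#'   0-200 ms post-onset window, consistent with the noise model) and
#'   `traces` (list of [trace()]s with holding metadata).
#' @export
gen_iv_family <- function(mechanism, holdings_mV, noise_sd_pA = 0, seed = 1L,
                          dt_s = 1e-3, duration_s = 1.2) {
  if (length(holdings_mV) < 3) stop("need at least 3 holding potentials")
  if (anyDuplicated(holdings_mV)) stop("holding potentials must be distinct")
  kind <- mechanism$kind
  amp <- switch(kind,
    chemical = function(V) mechanism$g_nS * (V - mechanism$E_rev_mV),
    electrical = function(V) rep(mechanism$I_const_pA, length(V)),
    stop("mechanism$kind must be 'chemical' or 'electrical'"))
  n <- as.integer(round(duration_s / dt_s))
  tt <- (seq_len(n) - 1L) * dt_s
  on <- as.numeric(tt >= 0.2)
  traces <- withr::with_seed(as.integer(seed), {
    lapply(holdings_mV, function(V) {
      a <- amp(V)
      if (noise_sd_pA > 0) a <- a + stats::rnorm(1, 0, noise_sd_pA)
      trace(a * on, dt = dt_s, unit = "pA", holding_mV = V)
    })
  })
  iv <- build_iv(traces, window_s = c(0.2, 0.4), polarity = "absolute",
                 window_role = "onset")
  list(iv = iv, traces = traces)
}

#' Generate spot-size tuning of inhibitory and gap-junction inputs
#'
#' Parametric spatial profiles: inhibition is a difference of saturating
#' exponentials (centre recruits, surround suppresses), so its response
#' peaks at an interior diameter; the gap-junction input is a single
#' saturating exponential (wide-field, no surround suppression).
#'
#' @param diameters_um Positive ascending spot diameters (micrometres).
#' @param inh_peak_pA,gj_peak_pA Profile amplitude scales (defaults 757, 80).
#' @param lambda_centre_um,lambda_surround_um,surround_weight Inhibition
#'   profile constants (defaults 80, 500, 0.8).
#' @param lambda_gj_um Gap-junction saturation constant (default 300).
#' @return Data frame: `diameter_um`, `inh_pA` (outward peak at the cation
#'   reversal), `gj_pA` (outward peak at the chloride reversal).
#' @export
gen_spot_size_series <- function(diameters_um,
                                 inh_peak_pA = 757, gj_peak_pA = 80,
                                 lambda_centre_um = 80,
                                 lambda_surround_um = 500,
                                 surround_weight = 0.8,
                                 lambda_gj_um = 300) {
  d <- as.numeric(diameters_um)
  if (any(d <= 0) || is.unsorted(d, strictly = TRUE))
    stop("diameters must be positive and strictly ascending")
  sat <- function(x, lam) 1 - exp(-x / lam)
  inh_raw <- sat(d, lambda_centre_um) * (1 - surround_weight * sat(d, lambda_surround_um))
  gj_raw <- sat(d, lambda_gj_um)
  scale_inh <- if (max(inh_raw) > 0) inh_peak_pA / max(inh_raw) else 0
  data.frame(diameter_um = d,
             inh_pA = scale_inh * inh_raw,
             gj_pA = gj_peak_pA * gj_raw)
}

#' Write a cycle set and its generation parameters to delimited text
#'
#' One TSV per angle (see [write_trace_tsv()]) plus a JSON sidecar recording
#' the generation parameters and seed.
#'
#' @param cs A [cycle_set()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param params Optional parameter object stored in the sidecar.
#' @return Invisibly, the written file paths.
#' @export
write_cycle_set_tsv <- function(cs, dir, prefix = "cycle", params = NULL) {
  stopifnot(inherits(cs, "cycle_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(cs$angles_deg), function(i) {
    p <- file.path(dir, sprintf("%s_angle%03d.tsv", prefix,
                                as.integer(round(cs$angles_deg[i]))))
    write_trace_tsv(cs$traces[[i]], p)
    p
  }, character(1))
  if (!is.null(params)) {
    side <- file.path(dir, paste0(prefix, "_params.json"))
    jsonlite::write_json(unclass(params), side, auto_unbox = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, side)
  }
  invisible(paths)
}

#' Write spike trains as delimited text plus JSON epoch metadata
#'
#' @param trains A [spike_trains()] object.
#' @param path TSV output path (columns `trial_id`, `time_s`); epoch
#'   metadata goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_spike_trains_tsv <- function(trains, path) {
  stopifnot(inherits(trains, "spike_trains"))
  df <- do.call(rbind, lapply(seq_along(trains$trials), function(i) {
    if (!length(trains$trials[[i]])) return(NULL)
    data.frame(trial_id = i, time_s = trains$trials[[i]])
  }))
  if (is.null(df)) df <- data.frame(trial_id = integer(0), time_s = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(n_epochs = length(trains$trials), onset_s = trains$onset_s,
               offset_s = trains$offset_s, duration_s = trains$duration_s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
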