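#' Specification of a current-shuffling condition
#'
#' The shuffling bootstrap destroys, selectively, the orientation
#' information carried by one synaptic input: per draw, the per-angle cycle
#' waveforms of the chosen input type are randomly permuted across grating
#' angles while the other input stays put. Conditions: `intact` (identity),
#' `shuffle_inh`, `shuffle_gj`, `shuffle_both` (independent permutations of
#' each input). "Bootstrapping" here means sampling permutations with
#' replacement, the only reading consistent with random permutation between
#' angles.
#'
#' @param condition One of `"intact"`, `"shuffle_inh"`, `"shuffle_gj"`,
#'   `"shuffle_both"`.
#' @param n_boot Number of permutation draws (default 10000).
#' @param seed Integer master seed for the permutation stream.
#' @return Validated list of class `shuffle_spec`.
#' @export
shuffle_spec <- function(condition = c("intact", "shuffle_inh", "shuffle_gj",
                                       "shuffle_both"),
                         n_boot = 10000L, seed = 1L) {
  condition <- match.arg(condition)
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be at least 1")
  structure(list(condition = condition, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "shuffle_spec")
}

# permutation pair (gj, inh) for draws 1..n from the spec's seeded stream
shuffle_permutations <- function(n_angles, spec, n_draws = spec$n_boot) {
  withr::with_seed(spec$seed, {
    lapply(seq_len(n_draws), function(i) {
      p_gj <- if (spec$condition %in% c("shuffle_gj", "shuffle_both"))
        sample.int(n_angles) else seq_len(n_angles)
      p_inh <- if (spec$condition %in% c("shuffle_inh", "shuffle_both"))
        sample.int(n_angles) else seq_len(n_angles)
      list(gj = p_gj, inh = p_inh)
    })
  })
}

#' Apply one shuffle draw to a pair of cycle sets
#'
#' Returns the permuted cycle sets for draw `draw_index` of the seeded
#' permutation stream defined by `spec` (the stream is replayed up to that
#' index, so any draw is individually reproducible). Angle labels stay in
#' place; the waveforms move. The multiset of waveforms is preserved
#' exactly.
#'
#' @param gj_cycles,inh_cycles [cycle_set()]s sharing an angle list.
#' @param spec A [shuffle_spec()].
#' @param draw_index Which draw of the stream to apply (default 1).
#' @return List with permuted `gj` and `inh` cycle sets and the applied
#'   `permutation` (indices of the source angle for each target angle).
#' @export
shuffle_currents <- function(gj_cycles, inh_cycles, spec, draw_index = 1L) {
  stopifnot(inherits(gj_cycles, "cycle_set"), inherits(inh_cycles, "cycle_set"),
            inherits(spec, "shuffle_spec"))
  if (length(gj_cycles$angles_deg) != length(inh_cycles$angles_deg) ||
      any(abs(gj_cycles$angles_deg - inh_cycles$angles_deg) > 1e-9))
    stop("cycle sets must share the same angle list")
  perms <- shuffle_permutations(length(gj_cycles$angles_deg), spec,
                                n_draws = draw_index)
  pp <- perms[[draw_index]]
  permute_cs <- function(cs, p) {
    tr <- cs$traces[p]
    # keep the target angle labels: the waveform moves, the label stays
    tr <- mapply(function(t, a) { t$tag <- c(angle_deg = a); t },
                 tr, cs$angles_deg, SIMPLIFY = FALSE)
    cycle_set(tr, cs$angles_deg, cs$period_s)
  }
  list(gj = permute_cs(gj_cycles, pp$gj),
       inh = permute_cs(inh_cycles, pp$inh),
       permutation = pp)
}

# spike-count matrix M[i, j]: count when gj waveform i is paired with inh
# waveform j. One angle's simulation depends only on its own waveform pair,
# so every permutation draw is a lookup into this matrix -- an exact
# shortcut, not an approximation. Duplicate waveforms (e.g. untuned
# noise-free inhibition) are simulated once.
shuffle_count_matrix <- function(params, inputs) {
  n <- length(inputs$angles_deg)
  first_match <- function(waves) {
    u <- integer(length(waves))
    for (i in seq_along(waves)) {
      u[i] <- i
      for (j in seq_len(i - 1L)) {
        if (identical(waves[[i]], waves[[j]])) { u[i] <- u[j]; break }
      }
    }
    match(u, unique(u))
  }
  gj_u <- first_match(inputs$I_gj_pA)
  inh_u <- first_match(inputs$g_inh_nS)
  cache <- matrix(NA_real_, max(gj_u), max(inh_u))
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- gj_u[i]; b <- inh_u[j]
      if (is.na(cache[a, b]))
        cache[a, b] <- simulate_lif(params, inputs$I_gj_pA[[i]],
                                    inputs$g_inh_nS[[j]])$n_spikes
      M[i, j] <- cache[a, b]
    }
  }
  M
}

#' Bootstrap the model's orientation index under a shuffling condition
#'
#' For each of `n_boot` draws, permutes the per-angle input waveforms
#' according to the condition, runs the grating sweep, and records the
#' model OSI. The `intact` condition short-circuits to a single
#' deterministic evaluation (sd 0). Also reported, as a diagnostic, is the
#' OSI of the draw-averaged tuning curve (`osi_of_mean_curve`), which tends
#' to 0 for any shuffled condition as draws accumulate.
#'
#' @param params A [lif_params()] object.
#' @param gj_cycles,inh_cycles Input [cycle_set()]s (gap-junction current
#'   and inhibitory current).
#' @param spec A [shuffle_spec()].
#' @param V_hold_inh_mV,V_rev_inh_mV,t_total_s Passed to [build_inputs()];
#'   reversal defaults to `params$V_rev_inh_mV` and duration to
#'   `params$t_total_s`.
#' @param verbose Print progress for long runs (default FALSE).
#' @return List with `condition`, `mean_osi`, `sd_osi` (`NA` when
#'   `n_boot = 1`), `per_draw_osi`, `osi_of_mean_curve`, `n_boot`.
#' @export
bootstrap_osi <- function(params, gj_cycles, inh_cycles, spec,
                          V_hold_inh_mV = 10, V_rev_inh_mV = NULL,
                          t_total_s = NULL, verbose = FALSE) {
  stopifnot(inherits(params, "lif_params"), inherits(spec, "shuffle_spec"))
  if (is.null(V_rev_inh_mV)) V_rev_inh_mV <- params$V_rev_inh_mV
  if (is.null(t_total_s)) t_total_s <- params$t_total_s
  inputs <- build_inputs(gj_cycles, inh_cycles, V_hold_inh_mV = V_hold_inh_mV,
                         V_rev_inh_mV = V_rev_inh_mV, t_total_s = t_total_s)
  n <- length(inputs$angles_deg)
  ez2 <- exp(2i * deg2rad(inputs$angles_deg))
  if (spec$condition == "intact") {
    sw <- grating_sweep(params, inputs)
    return(list(condition = "intact", mean_osi = sw$osi, sd_osi = 0,
                per_draw_osi = sw$osi,
                osi_of_mean_curve = sw$osi, n_boot = 1L,
                intact_counts = sw$counts))
  }
  if (verbose)
    message(sprintf("precomputing %d x %d spike-count matrix ...", n, n))
  M <- shuffle_count_matrix(params, inputs)
  perms <- shuffle_permutations(n, spec)
  idx <- seq_len(n)
  mean_counts <- numeric(n)
  per_draw <- vapply(seq_len(spec$n_boot), function(b) {
    pp <- perms[[b]]
    counts <- M[cbind(pp$gj, pp$inh)]
    mean_counts <<- mean_counts + counts / spec$n_boot
    if (verbose && b %% 2000L == 0L)
      message(sprintf("  draw %d / %d", b, spec$n_boot))
    osi_of_counts(counts, ez2)
  }, numeric(1))
  list(condition = spec$condition,
       mean_osi = mean(per_draw),
       sd_osi = if (spec$n_boot > 1L) stats::sd(per_draw) else NA_real_,
       per_draw_osi = per_draw,
       osi_of_mean_curve = osi_of_counts(mean_counts, ez2),
       n_boot = spec$n_boot,
       intact_counts = M[cbind(idx, idx)])
}

#' Compare the four shuffling conditions
#'
#' Runs [bootstrap_osi()] for `intact`, `shuffle_inh`, `shuffle_gj` and
#' `shuffle_both` with independent, reproducible permutation substreams
#' derived from one master seed, and tabulates mean and sd of the model OSI
#' per condition together with the intact-vs-shuffled deltas.
#'
#' @inheritParams bootstrap_osi
#' @param n_boot Draws per shuffled condition (default 10000).
#' @param seed Master seed; per-condition substream seeds are drawn from it.
#' @return List with `table` (data.frame: condition, mean_osi, sd_osi,
#'   osi_of_mean_curve, delta_vs_intact, n_boot) and `runs` (the four
#'   [bootstrap_osi()] results).
#' @export
compare_conditions <- function(params, gj_cycles, inh_cycles,
                               n_boot = 10000L, seed = 1L,
                               V_hold_inh_mV = 10, verbose = FALSE) {
  conds <- c("intact", "shuffle_inh", "shuffle_gj", "shuffle_both")
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, 4L))
  runs <- lapply(seq_along(conds), function(k) {
    bootstrap_osi(params, gj_cycles, inh_cycles,
                  shuffle_spec(conds[k], n_boot = n_boot,
                               seed = sub_seeds[k]),
                  V_hold_inh_mV = V_hold_inh_mV, verbose = verbose)
  })
  names(runs) <- conds
  tab <- data.frame(
    condition = conds,
    mean_osi = vapply(runs, `[[`, numeric(1), "mean_osi"),
    sd_osi = vapply(runs, `[[`, numeric(1), "sd_osi"),
    osi_of_mean_curve = vapply(runs, `[[`, numeric(1), "osi_of_mean_curve"),
    n_boot = vapply(runs, `[[`, integer(1), "n_boot"),
    row.names = NULL
  )
  tab$delta_vs_intact <- tab$mean_osi - tab$mean_osi[1]
  list(table = tab, runs = runs)
}
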