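test_that("peak extraction respects polarity and matches an exhaustive scan", {
  dt <- 1e-3
  tr <- trace(rep(-50, 1000), dt = dt, unit = "pA")
  expect_equal(peak_current(tr, c(0, 0.5), "inward"), -50)

  t <- seq(0, 0.999, by = dt)
  sine <- trace(80 * sin(2 * pi * 2 * t), dt = dt, unit = "pA")
  expect_equal(peak_current(sine, c(0, 1), "outward"), 80, tolerance = 1e-3)

  set.seed(6)
  noisy <- trace(rnorm(1000, 0, 20), dt = dt, unit = "pA")
  w <- c(0.2, 0.6)
  sel <- which(t >= w[1] & t <= w[2])
  expect_equal(peak_current(noisy, w, "inward"), min(noisy$values[sel]))
  expect_equal(peak_current(noisy, w, "outward"), max(noisy$values[sel]))
  expect_equal(abs(peak_current(noisy, w, "absolute")),
               max(abs(noisy$values[sel])))
  expect_error(peak_current(noisy, c(2, 3)), "no samples")
})

test_that("IV construction and reversal estimation follow the stated rules", {
  mk <- function(v, hold) trace(rep(v, 100), dt = 1e-3, unit = "pA",
                                holding_mV = hold)
  iv <- build_iv(list(mk(-20, -80), mk(0, -60), mk(60, 0)), c(0, 0.05))
  expect_equal(iv$holdings_mV, c(-80, -60, 0))
  est <- estimate_reversal(iv)
  expect_equal(est$kind, "chemical")
  expect_equal(est$reversal_mV, -60, tolerance = 1e-9)
  expect_equal(est$slope_nS, 1, tolerance = 1e-9)

  expect_error(build_iv(list(mk(1, -80), mk(2, -80), mk(3, 0)), c(0, 0.05)),
               "duplicate")

  flat <- iv_series(seq(-100, 20, by = 10), rep(80, 13))
  est <- estimate_reversal(flat)
  expect_equal(est$kind, "electrical")
  expect_true(is.na(est$reversal_mV))

  expect_error(estimate_reversal(iv_series(c(-80, 0), c(0, 1))), "at least 3")

  # Monte-Carlo on the generator: mean recovery within 2 mV (sigma = 5 pA)
  revs <- vapply(1:100, function(s) {
    fam <- gen_iv_family(list(kind = "chemical", E_rev_mV = -67, g_nS = 1),
                         seq(-100, 20, by = 10), noise_sd_pA = 5, seed = s)
    estimate_reversal(fam$iv)$reversal_mV
  }, numeric(1))
  expect_lt(abs(mean(revs) + 67), 2)
})

test_that("population IV normalization has unit maximum magnitude", {
  iv <- iv_series(c(-80, -40, 0, 40), c(-120, -60, 10, 90))
  nn <- normalize_iv(iv)
  expect_equal(max(abs(nn$peak_pA)), 1)
  expect_equal(nn$peak_pA * 120, iv$peak_pA, tolerance = 1e-12)
  # zero crossings survive averaging of symmetric inputs
  iv2 <- iv_series(c(-80, -40, 0, 40), c(-240, -120, 20, 180))
  avg <- (normalize_iv(iv)$peak_pA + normalize_iv(iv2)$peak_pA) / 2
  expect_equal(sum(sign(avg) != sign(iv$peak_pA)), 0)
})

test_that("current subtraction and conductance conversion invert each other", {
  dt <- 1e-4
  t <- seq(0, 0.499, by = dt)
  gj <- 80 * pmax(sin(2 * pi * 2 * t), 0)
  inh <- 700 * pmax(sin(2 * pi * 2 * t + 0.3), 0)
  tot <- trace(gj + inh, dt = dt, unit = "pA")
  gj_tr <- trace(gj, dt = dt, unit = "pA")
  rec <- subtract_currents(tot, gj_tr)
  expect_equal(rec$values, inh, tolerance = 1e-12)
  expect_equal(subtract_currents(tot, tot)$values, rep(0, length(t)))
  expect_error(subtract_currents(tot, trace(1:10, dt, unit = "pA")),
               "share length")

  expect_equal(conductance_from_current(trace(70, 1e-4, unit = "pA"),
                                        10, -60), 1)
  expect_error(conductance_from_current(trace(70, 1e-4, unit = "pA"),
                                        -60, -60), "ill-defined")
  # g -> I -> g round trip at several holdings
  g <- abs(sin(1:100))
  for (vh in c(10, -20, -40)) {
    I <- trace(g * (vh - (-67)), dt = 1e-3, unit = "pA")
    expect_equal(conductance_from_current(I, vh, -67), g, tolerance = 1e-12)
  }
})

test_that("sliding-window spike removal attenuates spikes but not the grating response", {
  dt <- 1e-4 # 10 kHz
  t <- seq(0, 5 - dt, by = dt)
  clean <- 5 * sin(2 * pi * 2 * t) - 55
  vm <- clean
  for (st in seq(0.1, 4.8, by = 0.23)) {
    ix <- which(t >= st & t < st + 0.002)
    vm[ix] <- vm[ix] + 60 * sin(pi * (t[ix] - st) / 0.002)
  }
  tr <- trace(vm, dt = dt, unit = "mV")
  sm <- remove_spikes(tr, window_ms = 25)

  # the window is exactly 250 samples at 10 kHz
  expect_equal(as.integer(round(25e-3 / dt)), 250L)
  expect_length(sm$values, length(vm))

  # F1 of the smoothed subthreshold oscillation within 1% of the clean F1
  f1_clean <- f1_amplitude(cycle_average(trace(clean + 55, dt, unit = "mV"), 2), 2)
  f1_sm <- f1_amplitude(cycle_average(trace(sm$values + 55, dt, unit = "mV"), 2), 2)
  expect_lt(abs(f1_sm - f1_clean) / f1_clean, 0.01)

  # spikes attenuated more than 10-fold (vs the smoothed clean trace)
  resid <- sm$values - remove_spikes(trace(clean, dt, unit = "mV"), 25)$values
  expect_gt(60 / max(abs(resid)), 10)

  # constants unchanged; operator is linear; near-idempotent on smooth input
  cc <- trace(rep(-60, 5000), dt = dt, unit = "mV")
  expect_equal(remove_spikes(cc, 25)$values, cc$values)
  a <- trace(sin(2 * pi * 2 * t[1:20000]), dt, unit = "mV")
  b <- trace(cos(2 * pi * 1 * t[1:20000]), dt, unit = "mV")
  lin <- remove_spikes(trace(2 * a$values + 3 * b$values, dt, unit = "mV"), 25)
  expect_equal(lin$values,
               2 * remove_spikes(a, 25)$values + 3 * remove_spikes(b, 25)$values,
               tolerance = 1e-12)
  once <- remove_spikes(a, 25)
  twice <- remove_spikes(once, 25)
  interior <- 300:(length(t[1:20000]) - 300) # edge windows shrink
  expect_lt(max(abs(twice$values[interior] - once$values[interior])), 0.01)
})

test_that("percent change uses the magnitude of the baseline", {
  expect_equal(percent_change(100, 38), -62)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(-80, -40), 50)
  expect_error(percent_change(0, 10), "zero")
})

test_that("electrochemical utilities match independent evaluation", {
  expect_equal(nernst(10, 10, z = 1), 0)
  # E_Cl for 105 mM out / 12 mM in at 305 K, against a from-scratch formula
  indep <- 1000 * 8.314462618 * 305 / (-1 * 96485.33212) * log(105 / 12)
  expect_equal(nernst(105, 12, z = -1, T_K = 305), indep, tolerance = 1e-12)
  expect_equal(nernst(105, 12, z = -1, T_K = 305), -57.0, tolerance = 0.2)
  expect_error(nernst(-1, 10, z = -1), "positive")
  # LJP correction: command + LJP
  expect_equal(ljp_correct(-60), -68.58)
  expect_equal(ljp_correct(10, -8.58), 1.42)
})

test_that("spot-size tuning tables report the right windows and summaries", {
  d <- c(50, 100, 200, 400, 800, 1200)
  prof <- gen_spot_size_series(d)
  mk <- function(amp, diam, sustained) {
    dt <- 1e-3
    t <- seq(0, 1.199, by = dt)
    shape <- if (sustained) as.numeric(t >= 0.5 & t <= 1) else
      pmax(sin(pi * t / 0.2), 0) * (t <= 0.2)
    trace(amp * shape, dt = dt, unit = "pA", tag = c(diameter_um = diam))
  }
  tr_cat <- lapply(seq_along(d), function(i) mk(prof$inh_pA[i], d[i], FALSE))
  tr_cl <- lapply(seq_along(d), function(i) mk(prof$gj_pA[i], d[i], TRUE))
  st <- size_tuning(tr_cat, tr_cl)
  expect_equal(st$table$peak_Ecat_pA, prof$inh_pA, tolerance = 1e-9)
  expect_equal(st$table$peak_ECl_pA, prof$gj_pA, tolerance = 1e-9)
  expect_true(st$Ecat$argmax_um > 50 && st$Ecat$argmax_um < 1200)
  expect_lt(st$Ecat$suppression_ratio, 1)
  expect_gt(st$ECl$suppression_ratio, 0.95)
  # flat profile -> ratio 1; single diameter -> flagged summaries
  flat <- lapply(d, function(x) mk(100, x, TRUE))
  stf <- size_tuning(flat, flat)
  expect_equal(stf$ECl$suppression_ratio, 1)
  st1 <- size_tuning(list(mk(5, 200, FALSE)), list(mk(5, 200, TRUE)))
  expect_equal(nrow(st1$table), 1)
  expect_true(is.na(st1$Ecat$argmax_um))
})
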