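test_that("morlet phase convention: 0 deg at peaks, +/-180 at troughs, correct slope", {
  fs <- 2000
  dur <- 30
  rec <- sine_rec(4, fs = fs, duration = dur)
  ph <- morlet_phase(rec, freqs = seq(3, 5, 0.5))
  t <- seq(0, dur, by = 1 / fs)
  at4 <- which(abs(ph$freqs - 4) < 1e-9)
  peaks <- which(abs((t * 4) %% 1) < 1e-9 & t > 2 & t < dur - 2)
  expect_true(all(abs(ph$phase_deg[at4, peaks]) < 2))
  troughs <- which(abs((t * 4 + 0.5) %% 1) < 1e-9 & t > 2 & t < dur - 2)
  expect_true(all(abs(abs(ph$phase_deg[at4, troughs]) - 180) < 2))
  # unwrapped phase advances 4 cycles/s
  mid <- seq(5 * fs, 25 * fs)
  unw <- signal::unwrap(ph$phase_deg[at4, mid] * pi / 180)
  slope <- coef(lm(unw ~ t[mid]))[2] / (2 * pi)
  expect_equal(unname(slope), 4, tolerance = 0.01)
  # descending zero-crossing (peak -> trough) maps to +90 deg
  desc <- which(abs((t * 4 - 0.25) %% 1) < 1e-9 & t > 2 & t < dur - 2)
  expect_true(all(abs(ph$phase_deg[at4, desc] - 90) < 2))

  expect_error(morlet_phase(rec, freqs = 1500), "Nyquist")
})

test_that("spike_phases samples the right angles and drops edge spikes", {
  rec <- sine_rec(4, fs = 2000, duration = 30)
  ph <- morlet_phase(rec, freqs = 4)
  peaks <- seq(2, 28, by = 0.25)[seq(2, 28, by = 0.25) %% 0.25 == 0]
  peak_times <- seq(2, 28, by = 0.25)  # every 4 Hz peak
  peak_times <- peak_times[peak_times * 4 %% 1 == 0]
  tr <- spike_train(peak_times, duration = 30)
  sp <- spike_phases(tr, ph)
  expect_true(all(abs(sp$angles[[1]]) < 2))

  edge <- spike_train(c(0.1, 15, 29.9), duration = 30)
  spe <- spike_phases(edge, ph)
  expect_equal(spe$n_dropped, 2)
  expect_equal(spe$n_used, 1)

  none <- spike_train(numeric(), duration = 30)
  expect_equal(spike_phases(none, ph)$n_used, 0)
})

test_that("rayleigh_test: limits, type-I calibration, monotonicity in resultant length", {
  expect_lt(rayleigh_test(rep(37, 30))$p, 1e-10)
  anti <- rep(c(0, 180), 5)
  expect_gt(rayleigh_test(anti)$p, 0.99)
  expect_equal(rayleigh_test(anti)$r_bar, 0, tolerance = 1e-12)
  expect_true(is.na(rayleigh_test(c(1, 2, 3))$p))

  # type-I calibration: p uniform under the null, rejection near nominal
  set.seed(14)
  ps <- replicate(1000, rayleigh_test(runif(500, -180, 180))$p)
  expect_lte(mean(ps <= 0.05), 0.07)   # 0.05 nominal + 3 binomial SD
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)

  # p decreases as concentration grows at fixed n
  set.seed(15)
  ps_k <- sapply(c(0.2, 0.5, 1, 2), function(k)
    rayleigh_test(rvonmises_deg(200, 0, k))$p)
  expect_true(all(diff(ps_k) < 0))
})

test_that("lock_unit recovers generated locking and stays calibrated for kappa = 0", {
  cfg <- quick_cfg(duration = 120, vonmises_kappa = 2, preferred_phase_deg = 90,
                   base_rate_lambda0 = 5, seed = 17)
  lfp <- generate_lfp_pair(cfg)$recA
  tr <- generate_locked_spikes(lfp, cfg)
  ph <- morlet_phase(lfp)
  res <- lock_unit(tr, ph)
  expect_true(res$locked)
  expect_equal(res$threshold, 0.01)
  expect_lt(abs(res$preferred_angle_deg - 90), 10)
  expect_equal(res$best_freq, 4)

  few <- spike_train(c(5, 10, 15), duration = 120)
  rf <- lock_unit(few, ph)
  expect_false(rf$locked)
  expect_equal(rf$reason, "too_few_spikes")
})

test_that("group_summary takes circular means over locked units and handles wrap-around", {
  mk <- function(locked, angle) structure(
    list(unit_id = "x", locked = locked, preferred_angle_deg = angle,
         resultant_length = 0.5), class = "unit_locking_result")
  gs <- group_summary(list(mk(TRUE, 0), mk(TRUE, 90), mk(FALSE, 42)))
  expect_equal(gs$n_locked, 2); expect_equal(gs$n_total, 3)
  expect_equal(gs$group_preferred_angle_deg, 45, tolerance = 1e-9)

  gw <- group_summary(list(mk(TRUE, -170), mk(TRUE, 170)))
  expect_equal(abs(gw$group_preferred_angle_deg), 180, tolerance = 1e-9)

  g0 <- group_summary(list(mk(FALSE, 10)))
  expect_true(is.na(g0$group_preferred_angle_deg))
  expect_equal(g0$n_total, 1)
})

test_that("watson_williams: identical groups give F near 0; offset groups are detected; type I ok", {
  set.seed(19)
  a <- rvonmises_deg(50, 0, 2)
  ww_same <- watson_williams(a, a)
  expect_lt(ww_same$F, 1e-9)
  expect_gt(ww_same$p, 0.99)

  hits <- replicate(40, {
    x <- rvonmises_deg(30, 0, 2); y <- rvonmises_deg(30, 90, 2)
    # 90-degree offsets can drop the pooled resultant below the
    # comparability heuristic; the warning is expected here
    suppressWarnings(watson_williams(x, y)$p < 0.01)
  })
  expect_gte(mean(hits), 0.9)

  false_pos <- replicate(60, {
    x <- rvonmises_deg(50, 45, 2); y <- rvonmises_deg(50, 45, 2)
    watson_williams(x, y)$p < 0.05
  })
  expect_lte(mean(false_pos), 0.12)

  expect_warning(watson_williams(runif(20, -180, 180), runif(20, -180, 180)),
                 "assumption")
  expect_error(watson_williams(1:3, 1:10), "at least 5")
})

test_that("locked_proportion_test reproduces Fisher exact and an enumeration oracle", {
  res <- locked_proportion_test(1, 54, 10, 90)
  expect_equal(res$p, 0.0531, tolerance = 0.0005)
  expect_lt(locked_proportion_test(30, 54, 7, 90)$p, 0.0001)
  expect_lt(locked_proportion_test(20, 31, 3, 55)$p, 0.0001)
  expect_equal(locked_proportion_test(5, 10, 5, 10)$p, 1.0)

  # oracle: exhaustive hypergeometric enumeration for all margins with N <= 60
  fisher_enum <- function(a, na, b, nb) {
    k <- a + b
    xs <- max(0, k - nb):min(na, k)
    pr <- dhyper(xs, na, nb, k)
    sum(pr[pr <= dhyper(a, na, nb, k) * (1 + 1e-7)])
  }
  set.seed(23)
  for (i in 1:25) {
    na <- sample(2:40, 1); nb <- sample(2:(60 - na), 1)
    a <- sample(0:na, 1); b <- sample(0:nb, 1)
    expect_equal(locked_proportion_test(a, na, b, nb)$p,
                 fisher_enum(a, na, b, nb), tolerance = 1e-9)
  }
})

test_that("cross-region locking with identical LFPs reproduces local locking exactly", {
  cfg <- quick_cfg(duration = 60, vonmises_kappa = 1.5, base_rate_lambda0 = 4,
                   seed = 29)
  lfp <- generate_lfp_pair(cfg)$recA
  tr <- generate_locked_spikes(lfp, cfg)
  ph_local <- morlet_phase(lfp)
  other <- recording(lfp$signal, lfp$fs, region = "B")
  ph_cross <- morlet_phase(other)
  r1 <- lock_unit(tr, ph_local)
  r2 <- lock_unit(tr, ph_cross)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$preferred_angle_deg, r2$preferred_angle_deg)
})
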