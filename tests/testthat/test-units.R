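test_that("firing_metrics: rate, deterministic Fano, Poisson Fano, bin-phase stability", {
  tr <- spike_train(seq(0.5, 99.5, by = 1), duration = 100)
  m <- firing_metrics(tr)
  expect_equal(m$mean_rate, 1.0)
  expect_equal(m$fano, 0)  # exactly one spike per bin

  set.seed(10)
  pois <- spike_train(sort(runif(5 * 200, 0.001, 199.999)), duration = 200)
  mp <- firing_metrics(pois)
  expect_gt(mp$fano, 0.8); expect_lt(mp$fano, 1.2)
  mp2 <- firing_metrics(pois, origin_s = 0.5)
  expect_lt(abs(mp2$fano - mp$fano) / mp$fano, 0.10)

  empty <- spike_train(numeric(), duration = 100)
  me <- firing_metrics(empty)
  expect_equal(me$mean_rate, 0)
  expect_false(me$fano_defined)

  expect_error(firing_metrics(spike_train(c(1, 2), duration = 5)), "10 bins")
})

test_that("waveform_features: triangular trough geometry and missing-peak flagging", {
  fs <- 30000
  # symmetric triangular trough, half-width h = 0.3 ms, plus a rebound peak
  h_samp <- 9  # 0.3 ms at 30 kHz
  tri <- c(rep(0, 30), seq(0, -1, length.out = h_samp + 1),
           seq(-1, 0, length.out = h_samp + 1)[-1],
           rep(0, 5), seq(0, 0.4, length.out = 6), seq(0.4, 0, length.out = 6)[-1],
           rep(0, 30))
  ft <- waveform_features(unit_waveform(tri, fs))
  expect_equal(ft$fwhm_ms, 0.3, tolerance = 1e-6)
  expect_true(ft$defined)

  # monotonic decay with no rebound peak -> flagged
  flat <- c(rep(0, 40), seq(0, -1, length.out = 10),
            seq(-1, -0.01, length.out = 70)[-1])
  ff <- waveform_features(unit_waveform(flat, fs))
  expect_false(ff$defined)
  expect_equal(ff$reason, "no_rebound_peak")
})

test_that("generator round-trip recovers waveform features within one sample", {
  cfg <- synth_config(waveform_valley_to_peak_ms = 0.40,
                      waveform_fwhm_ms = 0.27, waveform_snr = Inf)
  ft <- waveform_features(generate_waveforms(cfg, 1)[[1]])
  expect_lt(abs(ft$valley_to_peak_ms - 0.40), 1 / 30)
  expect_lt(abs(ft$fwhm_ms - 0.27), 1 / 30)
  # and classifies regular-spiking downstream (fails the v2p criterion)
  expect_equal(classify_unit(ft$valley_to_peak_ms, ft$fwhm_ms), "regular_spiking")
})

test_that("classify_unit applies the 0.3 ms rule with strict inequalities", {
  expect_equal(classify_unit(0.2, 0.2), "fast_spiking")
  expect_equal(classify_unit(0.40, 0.27), "regular_spiking")
  expect_equal(classify_unit(0.3, 0.3), "regular_spiking")
  expect_equal(classify_unit(0.29, 0.31), "regular_spiking")
  # pure function of the two features over a grid
  grid <- expand.grid(v = seq(0.1, 0.5, 0.05), f = seq(0.1, 0.5, 0.05))
  cls <- mapply(classify_unit, grid$v, grid$f)
  expect_identical(cls == "fast_spiking", grid$v < 0.3 & grid$f < 0.3,
                   ignore_attr = TRUE)
  expect_error(classify_unit(NA, 0.2), "defined")
})

test_that("cluster_quality separates well-isolated clusters", {
  set.seed(21)
  a <- matrix(rnorm(40 * 2), ncol = 2)            # unit cluster at origin
  b <- matrix(rnorm(40 * 2, mean = 10), ncol = 2) # noise cluster 10 sigma away
  q <- cluster_quality(rbind(a, b), rep(c("u", "n"), each = 40), "u")
  expect_gt(q$isolation_distance, 25)
  expect_lt(q$l_ratio, 0.5)
  # overlapping clusters fail separation
  q2 <- cluster_quality(rbind(a, a + 0.5), rep(c("u", "n"), each = 40), "u")
  expect_lt(q2$isolation_distance, 25)
})

test_that("qc_filter matches brute-force predicate evaluation and source thresholds", {
  mk <- function(id, snr, iso, lr, isi) list(unit_id = id,
    qc = list(snr = snr, isolation_distance = iso, l_ratio = lr,
              isi_violation_fraction = isi))
  units <- list(mk("ok", 6, 30, 0.1, 0),
                mk("lowsnr", 4.9, 30, 0.1, 0),
                mk("baciso", 8, 20, 0.1, 0),
                mk("badlr", 8, 30, 0.7, 0),
                mk("refrac", 8, 30, 0.1, 0.01),
                list(unit_id = "unscored"))
  res <- qc_filter(units, source = "openephys")
  expect_equal(res$log$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$log$reason[res$log$unit_id == "unscored"], "unscored")
  # oracle: independent re-evaluation of the four predicates
  oracle <- sapply(units, function(u) {
    q <- u$qc
    !is.null(q) && q$snr >= 5 && q$isolation_distance > 25 &&
      q$l_ratio < 0.5 && q$isi_violation_fraction == 0
  })
  expect_equal(res$log$accepted, oracle, ignore_attr = TRUE)
  # neuralynx threshold is 11
  res_nl <- qc_filter(list(mk("a", 10.9, 30, 0.1, 0), mk("b", 11, 30, 0.1, 0)),
                      source = "neuralynx")
  expect_equal(res_nl$log$accepted, c(FALSE, TRUE))
})

test_that("ISI violations and spike detection behave on constructed trains", {
  tr <- spike_train(c(0.1, 0.1005, 0.3), duration = 1)
  expect_equal(isi_violation_fraction(tr), 0.5)

  set.seed(3)
  fs <- 30000
  x <- rnorm(fs) * 0.1
  at <- c(0.2, 0.5, 0.8)
  for (a in at) x[round(a * fs)] <- -3
  det <- detect_spikes(recording(x, fs), k = 4)
  expect_equal(length(det$spike_times), 3)
  expect_equal(det$spike_times, at, tolerance = 1e-3)
})

test_that("log_rate_histogram bins correctly and resolves generated bimodality", {
  h <- log_rate_histogram(c(1, 10), bin_width = 0.3)
  expect_equal(sum(h$counts), 2)
  occupied <- h$mids[h$counts > 0]
  expect_true(any(abs(occupied - 0.15) < 0.15) && any(abs(occupied - 1.05) < 0.16))

  h1 <- log_rate_histogram(rep(2.5, 7))
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(log_rate_histogram(c(1, 2, 0, -1))$n_excluded, 2)

  set.seed(30)
  rates <- 10^c(rnorm(200, 0, 0.12), rnorm(200, 1, 0.12))
  hb <- log_rate_histogram(rates, bin_width = 0.3)
  pk0 <- which.max(hb$counts * (abs(hb$mids - 0) < 0.4))
  pk1 <- which.max(hb$counts * (abs(hb$mids - 1) < 0.4))
  trough <- min(hb$counts[(pk0 + 1):(pk1 - 1)])
  expect_lt(trough, min(hb$counts[pk0], hb$counts[pk1]))
})

test_that("rate_width_correlation returns exact ranks and flags degenerate input", {
  r <- rate_width_correlation(1:10, 10:1)
  expect_equal(r$rho, -1)
  set.seed(5)
  null_rho <- replicate(40, rate_width_correlation(rnorm(50), rnorm(50))$rho)
  expect_gt(mean(abs(null_rho) < 0.4), 0.95)
  expect_false(rate_width_correlation(1:6, rep(0.3, 6))$defined)
  expect_error(rate_width_correlation(1:3, 1:3), "at least 5")
})
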