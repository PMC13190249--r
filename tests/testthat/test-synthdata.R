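test_that("synth_config validates ranges", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(coupling_c = 1.2), "coupling_c")
  expect_error(synth_config(theta_amp = -1), "theta_amp")
  expect_error(synth_config(fano_shape_k = 0), "fano_shape_k")
  expect_error(synth_config(delta_amp = NaN), "finite")
  expect_error(synth_config(preferred_phase_deg = 200), "preferred_phase_deg")
})

test_that("identical seed gives bit-identical recordings; different seeds differ", {
  cfg <- quick_cfg(seed = 5)
  a <- generate_lfp_pair(cfg)
  b <- generate_lfp_pair(cfg)
  expect_identical(a$recA$signal, b$recA$signal)
  expect_identical(a$recB$signal, b$recB$signal)
  c <- generate_lfp_pair(quick_cfg(seed = 6))
  expect_false(identical(a$recA$signal, c$recA$signal))
})

test_that("theta power in region B is independent of coupling strength", {
  band_power <- function(rec) {
    p <- welch_psd(rec, window_s = 10)
    sel <- p$freqs >= 3 & p$freqs <= 5
    pracma::trapz(p$freqs[sel], p$power[sel])
  }
  pows <- sapply(c(0, 0.5, 1), function(cc) {
    mean(sapply(1:8, function(s) {
      band_power(generate_lfp_pair(quick_cfg(coupling_c = cc, seed = s,
                                             noise_amp = 0, delta_amp = 0))$recB)
    }))
  })
  expect_lt(diff(range(pows)) / mean(pows), 0.05)
})

test_that("fully coupled noiseless theta gives band coherence near 1; band MSC grows with coupling", {
  cfg1 <- quick_cfg(coupling_c = 1, noise_amp = 0, delta_amp = 0, seed = 2)
  p1 <- generate_lfp_pair(cfg1)
  r1 <- msc(p1$recA, p1$recB)
  expect_gt(mean(r1$msc[r1$freqs >= 3 & r1$freqs <= 5]), 0.95)

  band_msc <- function(cc, seed) {
    p <- generate_lfp_pair(quick_cfg(coupling_c = cc, seed = seed))
    r <- msc(p$recA, p$recB)
    mean(r$msc[r$freqs >= 3 & r$freqs <= 5])
  }
  hi <- sapply(1:5, function(s) band_msc(0.8, s))
  lo <- sapply(1:5, function(s) band_msc(0.3, s))
  expect_true(all(hi > lo))
})

test_that("kappa = 0 gamma-shape-1 trains are Poisson-like (Fano near 1) with mean rate lambda0", {
  ff <- sapply(1:6, function(s) {
    cfg <- quick_cfg(duration = 100, vonmises_kappa = 0, base_rate_lambda0 = 5,
                     seed = 100 + s)
    tr <- generate_locked_spikes(generate_lfp_pair(cfg)$recA, cfg)
    m <- firing_metrics(tr)
    c(m$fano, m$mean_rate)
  })
  expect_true(all(abs(ff[1, ] - 1) <= 0.3))
  expect_lt(abs(mean(ff[1, ]) - 1), 0.15)
  expect_equal(mean(ff[2, ]), 5, tolerance = 0.1)
})

test_that("resultant length of generated spike phases matches the Bessel ratio I1(k)/I0(k)", {
  for (kap in c(0.5, 2)) {
    cfg <- quick_cfg(duration = 150, vonmises_kappa = kap,
                     preferred_phase_deg = 0, base_rate_lambda0 = 10,
                     seed = 40 + round(10 * kap))
    lfp <- generate_lfp_pair(cfg)$recA
    tr <- generate_locked_spikes(lfp, cfg)
    expect_gt(length(tr$spike_times), 1000)
    ph <- morlet_phase(lfp, freqs = cfg$theta_freq)
    ang <- spike_phases(tr, ph)$angles[[1]]
    expect_lt(abs(resultant_length(ang) - besselI(kap, 1) / besselI(kap, 0)),
              0.05)
  }
})

test_that("spike trains honour the 1.5 ms dead time", {
  cfg <- quick_cfg(duration = 100, base_rate_lambda0 = 20, seed = 9)
  tr <- generate_locked_spikes(generate_lfp_pair(cfg)$recA, cfg)
  expect_true(all(diff(tr$spike_times) >= 0.0015 - 1e-12))
})

test_that("waveform templates reproduce configured features; noiseless template is exact", {
  cfg <- synth_config(waveform_valley_to_peak_ms = 0.2,
                      waveform_fwhm_ms = 0.2, waveform_snr = Inf)
  wf <- generate_waveforms(cfg, 1)[[1]]
  ft <- waveform_features(wf)
  expect_lt(abs(ft$valley_to_peak_ms - 0.2), 1 / 30)
  expect_lt(abs(ft$fwhm_ms - 0.2), 1 / 30)
  expect_identical(wf$samples, attr(wf, "template"))

  expect_error(generate_waveforms(synth_config(waveform_fwhm_ms = 0.00001),
                                  1),
               "narrower than 2 sample")
})

test_that("cohort generation writes files, a manifest, and group rate structure", {
  dir <- withr::local_tempdir()
  groups <- list(
    list(label = "uni", n = 2, units_per_subject = 30,
         log10_rate_means = 0.5, log10_rate_sd = 0.15),
    list(label = "bi", n = 2, units_per_subject = 30,
         log10_rate_means = c(-0.5, 0.5), log10_rate_sd = 0.12))
  base <- quick_cfg(duration = 30, base_rate_lambda0 = 2)
  man <- generate_cohort(groups, base, dir, seed = 3)
  expect_equal(man$n_subjects, 4)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(all(file.exists(file.path(dir, sapply(man$subjects, `[[`, "regionA")))))

  rates <- unlist(lapply(man$subjects, function(s) s$ground_truth$lambda0))
  grp <- rep(sapply(man$subjects, `[[`, "group"),
             times = sapply(man$subjects, function(s) length(s$ground_truth$lambda0)))
  # unimodal group: one histogram mode; bimodal: modes near the configured centres
  h_bi <- log_rate_histogram(rates[grp == "bi"], bin_width = 0.3)
  expect_gt(sum(h_bi$counts[abs(h_bi$mids + 0.5) < 0.3]), 0)
  expect_gt(sum(h_bi$counts[abs(h_bi$mids - 0.5) < 0.3]), 0)
  h_uni <- log_rate_histogram(rates[grp == "uni"], bin_width = 0.3)
  expect_lt(sum(h_uni$counts[h_uni$mids < -0.2]), 3)

  expect_error(generate_cohort(list(list(label = "x", n = 0)), base, dir),
               "positive")
})
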