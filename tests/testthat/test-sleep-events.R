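# A 20 s test signal at 200 Hz; weak broadband noise keeps filtered traces
# from being degenerate pure tones outside their band.
make_signal <- function(freq, fs = 200, dur = 20, amp = 1, noise = 0.02,
                        seed = 1) {
  set.seed(seed)
  t <- (0:(dur * fs - 1)) / fs
  amp * sin(2 * pi * freq * t) + noise * rnorm(length(t))
}

test_that("slow-wave detection accepts 1 Hz waves and rejects 10 Hz", {
  fs <- 200
  ev <- detect_ssw(make_signal(1, noise = 0), fs)
  expect_gte(nrow(ev), 19); expect_lte(nrow(ev), 20)
  # half-waves of a 1 Hz wave last 500 ms, the full wave 1 s
  expect_equal(median(ev$stop_s - ev$start_s), 1, tolerance = 0.05)
  expect_equal(median(ev$tau_s), 0.5, tolerance = 0.05)
  expect_equal(median(ev$f_tr_hz), 1, tolerance = 0.1)
  expect_equal(nrow(detect_ssw(make_signal(10, noise = 0), fs)), 0L)
  # all-constant signal: no crossings, no events
  expect_equal(nrow(detect_ssw(numeric(4000), fs)), 0L)
})

test_that("detection criteria are amplitude-free", {
  fs <- 200
  x <- make_signal(1, seed = 2)
  e1 <- detect_ssw(x, fs)
  e2 <- detect_ssw(5 * x, fs)
  expect_equal(e1$hyper_peak_s, e2$hyper_peak_s)
  expect_equal(e1$f_tr_hz, e2$f_tr_hz)
})

test_that("gamma suppression identifies the downstate in every event", {
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  slow <- sin(2 * pi * t)            # positive half-waves first
  gam <- 0.25 * sin(2 * pi * 50 * t) * (slow > 0)  # gamma only on positive halves
  ev <- detect_ssw(slow + gam, fs)
  expect_gt(nrow(ev), 10)
  # the gamma-suppressed (negative) half-wave is always the downstate
  expect_true(all(sin(2 * pi * ev$hyper_peak_s) < 0))
  expect_true(all(sin(2 * pi * ev$depol_peak_s) > 0))
})

test_that("region-adaptive conjunction keeps only in-band waves", {
  fs <- 200
  # self-conjunction is the identity
  x1 <- make_signal(1, seed = 3)
  expect_equal(detect_ssw_adaptive(x1, fs, region_band = c(0.5, 4)),
               detect_ssw(x1, fs))
  # a 3.5 Hz rhythm passes the canonical band but not the region band
  x35 <- make_signal(3.5, seed = 4, noise = 0.05)
  expect_gt(nrow(detect_ssw(x35, fs)), 0)
  expect_equal(nrow(detect_ssw_adaptive(x35, fs, region_band = c(0.5, 2.5))), 0L)
  # in a 1 Hz + 3.5 Hz mixture only the 1 Hz events survive
  xm <- make_signal(1, seed = 5, noise = 0.05) + 0.6 * make_signal(3.5, noise = 0)
  evm <- detect_ssw_adaptive(xm, fs, region_band = c(0.5, 2.5))
  expect_gt(nrow(evm), 5)
  expect_true(all(evm$f_tr_hz < 2))
})

test_that("switcher classification recovers a bimodal mixture", {
  set.seed(6)
  ftr <- c(rnorm(100, 1, 0.1), rnorm(100, 2, 0.1))
  truth <- rep(c("slow", "fast"), each = 100)
  ev <- data.frame(f_tr_hz = ftr)
  cl <- classify_switchers(ev, seed = 1)
  expect_gt(cl$threshold_hz, 1.2); expect_lt(cl$threshold_hz, 1.8)
  expect_gte(mean(as.character(cl$labels) == truth), 0.95)
  # class proportions recovered within 5 points
  expect_lt(abs(mean(cl$labels == "slow") - 0.5), 0.05)
  # tau -> transition frequency arithmetic
  expect_equal(1 / (2 * 0.25), 2)
  # degenerate and undersized inputs
  expect_error(classify_switchers(data.frame(f_tr_hz = rep(1, 5))),
               "at least 10")
  d <- classify_switchers(data.frame(f_tr_hz = rep(1.5, 12)))
  expect_true(d$single_class)
  expect_true(is.na(d$threshold_hz))
})

test_that("theta bursts are kept only when transient and suprathreshold", {
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  carrier <- sin(2 * pi * 7 * t)
  backdrop <- (1 + 0.2 * sin(2 * pi * 0.2 * t)) * carrier
  # stationary theta: nothing crosses the duration-limited +3 SD rule
  expect_equal(nrow(detect_theta_bursts(backdrop, fs)), 0L)
  # one 0.6 s burst at 5x the background envelope
  burst_on <- t >= 10 & t < 10.6
  x <- backdrop + 4 * carrier * burst_on
  ev <- detect_theta_bursts(x, fs)
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$duration_s, 0.4); expect_lte(ev$duration_s, 1)
  expect_gte(ev$peak_z, 3)
  expect_equal(ev$peak_s, 10.3, tolerance = 0.35)
  # a 1.5 s burst exceeds the duration ceiling
  long_on <- t >= 8 & t < 9.5
  expect_equal(nrow(detect_theta_bursts(backdrop + 4 * carrier * long_on, fs)),
               0L)
})

test_that("the coupling statistic matches its closed forms", {
  phi <- seq(0, 8 * pi, length.out = 1600 + 1)[-1]   # whole cycles
  expect_equal(pac_modulation(rep(3.7, length(phi)), phi), 0, tolerance = 1e-12)
  expect_equal(pac_modulation(1 + cos(phi), phi), 0.5, tolerance = 1e-10)
  # independent amplitude and phase decouple as T grows
  set.seed(7)
  null_vals <- replicate(200, {
    pac_modulation(abs(rnorm(1024, 1, 0.3)), runif(1024, -pi, pi))
  })
  expect_lt(median(null_vals), 0.05)
})

test_that("band-filtered PAC separates coupled from uncoupled signals", {
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  phi_d <- 2 * pi * 1.5 * t
  coupled <- sin(phi_d) + 0.4 * (1 + 0.8 * cos(phi_d)) * sin(2 * pi * 13 * t)
  set.seed(8)
  uncoupled <- sin(phi_d) + 0.4 * (1 + 0.8 * cos(2 * pi * 0.9 * t + 1)) *
    sin(2 * pi * 13 * t)
  p1 <- compute_pac(coupled, fs, c(0.5, 4), c(10, 16), window = c(2, 18))
  p0 <- compute_pac(uncoupled, fs, c(0.5, 4), c(10, 16), window = c(2, 18))
  expect_gt(p1$value, 3 * p0$value)
  expect_error(compute_pac(coupled, fs, c(0.5, 4), c(10, 16), window = c(0, 1)),
               "two cycles")
})

test_that("uncoupled PAC stays below coupled PAC (null calibration)", {
  fs <- 200; nwin <- 4 * fs
  t <- (0:(nwin - 1)) / fs
  set.seed(9)
  null_pac <- replicate(100, {
    x <- gen_scale_free(1.5, 1024, fs)[1:nwin] +
      0.3 * sin(2 * pi * 13 * t + runif(1, 0, 2 * pi))
    compute_pac(x, fs, c(0.5, 4), c(10, 16))$value
  })
  coupled_pac <- replicate(30, {
    ph <- 2 * pi * 1.5 * t + runif(1, 0, 2 * pi)
    x <- sin(ph) + 0.3 * (1 + 0.8 * cos(ph)) * sin(2 * pi * 13 * t) +
      0.1 * rnorm(nwin)
    compute_pac(x, fs, c(0.5, 4), c(10, 16))$value
  })
  expect_lt(quantile(null_pac, 0.95), median(coupled_pac))
})

test_that("scalograms: phase-locked equals induced for repeated windows only", {
  fs <- 200
  t <- (0:(2 * fs - 1)) / fs
  w <- sin(2 * pi * 12 * t) * exp(-((t - 1) / 0.2)^2)
  one <- event_scalograms(matrix(w, 1), fs)
  pl <- event_scalograms(matrix(w, 1), fs, mode = "phase_locked")
  expect_equal(one$power, pl$power)
  rep5 <- do.call(rbind, replicate(5, w, simplify = FALSE))
  expect_equal(event_scalograms(rep5, fs)$power,
               event_scalograms(rep5, fs, mode = "phase_locked")$power)
  # random per-window phase destroys phase-locked but not induced power
  set.seed(10)
  wins <- do.call(rbind, lapply(1:40, function(i) {
    sin(2 * pi * 12 * t + runif(1, 0, 2 * pi)) * exp(-((t - 1) / 0.2)^2)
  }))
  ind <- event_scalograms(wins, fs)
  plk <- event_scalograms(wins, fs, mode = "phase_locked")
  f12 <- which.min(abs(ind$freq - 12))
  mid <- which.min(abs(ind$time - 1))
  expect_lt(plk$power[f12, mid], 0.2 * ind$power[f12, mid])
  expect_error(event_scalograms(list(w, w[-1]), fs), "ragged")
})

test_that("PAC contrasts and theta-burst co-occurrence tagging", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  phi_d <- 2 * pi * 1 * t
  gate <- ifelse(t < 30, 1 + 0.8 * cos(phi_d), 1)
  set.seed(11)
  x <- sin(phi_d) + 0.4 * gate * sin(2 * pi * 13 * t) + 0.05 * rnorm(length(t))
  ctr_a <- seq(3, 27, by = 1)    # events in the delta-gated half
  ctr_b <- seq(33, 57, by = 1)   # events in the ungated half
  ev_a <- data.frame(hyper_peak_s = ctr_a)
  ev_b <- data.frame(hyper_peak_s = ctr_b)
  pc <- pac_contrast(ev_a, ev_b, x, fs, c(0.5, 4), c(10, 16))
  expect_gt(pc$median_diff, 0)
  expect_lt(pc$p_value, 0.01)
  # identical groups: no difference, p ~ 1
  pc0 <- pac_contrast(ev_a, ev_a, x, fs, c(0.5, 4), c(10, 16))
  expect_equal(pc0$median_diff, 0)
  expect_gt(pc0$p_value, 0.9)
  expect_error(pac_contrast(ev_a[0, , drop = FALSE], ev_b, x, fs,
                            c(0.5, 4), c(10, 16)), "non-empty")
  # co-occurrence threshold at 500 ms
  ssw <- data.frame(hyper_peak_s = c(10, 20))
  tbs <- data.frame(peak_s = c(10.4, 20.6))
  class(tbs) <- c("tb_events", "data.frame")
  tagged <- tag_tb_cooccurrence(ssw, tbs)
  expect_identical(tagged$tb_cooccur, c(TRUE, FALSE))
})

test_that("slow-wave detector contracts on bad inputs", {
  expect_error(detect_ssw(rnorm(100), 200), "4 s")
  expect_error(detect_ssw(rnorm(4000), 100), "gamma band")
  expect_error(detect_ssw_adaptive(make_signal(1), 200,
                                   region_band = c(0.01, 2)), "region_band")
})
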