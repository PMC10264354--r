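# Cardiac, respiratory and electrodermal quantification.

mk_ibi <- function(r_peaks) clean_ibis(r_peaks)

test_that("R-peak detection recovers the generator's beat times", {
  sim <- periphys_session()
  pk <- detect_r_peaks(get_channel(sim$recording, "ecg"))
  tr <- sim$truth$r_peaks
  m <- match_events(data.frame(onset = pk), data.frame(onset = tr),
                    tol = 0.02)
  expect_gte(m$recall, 0.99)
  expect_gte(m$precision, 0.99)
  expect_length(detect_r_peaks(list(data = numeric(5000), rate = 1000)),
                0)
})

test_that("SDNN has its closed-form values and invariances", {
  expect_equal(sdnn(mk_ibi(cumsum(c(0, rep(0.8, 10))))), 0)
  # IBIs 750, 850 ms: sample SD = 70.7107 ms
  s <- mk_ibi(c(0, 0.75, 1.6))
  expect_equal(sdnn(s), 70.7107, tolerance = 1e-4)
  # permutation invariance and linear scaling about the mean
  set.seed(41)
  ib <- runif(50, 700, 900)
  t1 <- cumsum(c(0, ib / 1000))
  t2 <- cumsum(c(0, sample(ib) / 1000))
  expect_equal(sdnn(mk_ibi(t1)), sdnn(mk_ibi(t2)))
  # scaling kept inside the +-25% cleaning envelope
  ib2 <- mean(ib) + 1.2 * (ib - mean(ib))
  expect_equal(sdnn(mk_ibi(cumsum(c(0, ib2 / 1000)))),
               1.2 * sdnn(mk_ibi(t1)), tolerance = 1e-6)
})

test_that("IBI outliers are masked by the rolling-median rule", {
  ib <- rep(800, 40); ib[20] <- 1400       # an ectopic-like interval
  s <- clean_ibis(cumsum(c(0, ib / 1000)))
  expect_true(s$mask[20])
  expect_equal(sum(s$mask), 1)
  expect_equal(sdnn(s), 0)
})

test_that("tachogram band fractions isolate LF and HF sources", {
  # pure 0.25 Hz (HF band) IBI oscillation
  t <- seq(0, 300, by = 0.8)
  ib <- 800 + 50 * sin(2 * pi * 0.25 * t)
  s <- list(r_peak_times = c(0, t + 0.8), ibis = ib, t_ibi = t + 0.8,
            mask = rep(FALSE, length(ib)))
  p <- plf_phf(s)
  expect_gt(p$phf, 0.95)
  expect_lt(p$plf, 0.05)
  # pure 0.08 Hz (LF band) oscillation
  ib2 <- 800 + 50 * sin(2 * pi * 0.08 * t)
  s2 <- s; s2$ibis <- ib2
  p2 <- plf_phf(s2)
  expect_gt(p2$plf, 0.95)
})

test_that("tonic HR averages 60-s windows of instantaneous rate", {
  s <- mk_ibi(seq(0, 240, by = 1))         # constant 1000 ms IBIs
  expect_equal(tonic_hr(s, c(0, 240)), 60)
  # 60 -> 80 bpm step mid-block gives a window-weighted intermediate
  r1 <- seq(0, 120, by = 1)
  r2 <- seq(120.75, 240, by = 0.75)
  s2 <- mk_ibi(c(r1, r2))
  v <- tonic_hr(s2, c(0, 240))
  expect_gt(v, 65); expect_lt(v, 75)
  expect_error(tonic_hr(s, c(0, 30)), "shorter")
})

test_that("phasic HR deltas recover planted stimulus responses", {
  s <- mk_ibi(seq(0, 500, by = 1))
  ev <- data.frame(onset = c(50, 100, 150))
  ph <- phasic_hr(s, ev)
  expect_true(all(abs(ph$delta) < 1e-9))   # constant HR: all deltas 0
  # event at the span edge is skipped
  ph2 <- phasic_hr(s, data.frame(onset = c(1, 50)), span = c(0, 500))
  expect_equal(nrow(ph2), 1)
  # planted phasic bump in the generator
  sim <- periphys_session()
  ser <- mk_ibi(detect_r_peaks(get_channel(sim$recording, "ecg")))
  for (b in c("normal", "enhanced")) {
    ev <- sim$events[sim$events$block == b, ]
    span <- unlist(sim$recording$blocks[
      sim$recording$blocks$label == b, c("start", "end")])
    ph <- phasic_hr(ser, ev, span = span)
    delta <- sim$truth$phasic_hr_delta[[b]]
    expect_lt(abs(mean(ph$delta) - delta),
              2 * sd(ph$delta) / sqrt(nrow(ph)) + 0.6)
    expect_gt(mean(ph$delta), 0.5 * delta)
  }
  # pseudo-events in the stationary baseline: mean delta ~ 0
  base <- block_span(sim$recording, "baseline")
  pseudo <- make_pseudo_events(base, n = 60)
  ph0 <- phasic_hr(ser, pseudo, span = base)
  expect_lt(abs(mean(ph0$delta)),
            3 * sd(ph0$delta) / sqrt(nrow(ph0)) + 0.2)
})

test_that("pseudo-events start 120 s into baseline at 3 s spacing", {
  p <- make_pseudo_events(c(100, 500), n = 60)
  expect_equal(nrow(p), 60)
  expect_equal(p$onset[1], 220)
  expect_true(all(diff(p$onset) == 3))
  expect_error(make_pseudo_events(c(0, 200), n = 60), "too short")
})

test_that("breathing rate is recovered from respiratory sinus arrhythmia", {
  for (br in c(12, 18)) {
    set.seed(50 + br)
    e <- simulate_ecg(70, rsa_depth = 40, br = br, rate = 500,
                      duration = 300, noise_sd = 0.01)
    ser <- mk_ibi(detect_r_peaks(e))
    est <- estimate_br(ser, c(0, 300))
    expect_lt(abs(est - br), 1)
  }
  # no RSA: no qualifying windows, absent value
  set.seed(55)
  e0 <- simulate_ecg(70, rsa_depth = 0, br = 15, rate = 500,
                     duration = 200, noise_sd = 0.005)
  ser0 <- mk_ibi(detect_r_peaks(e0))
  expect_message(v <- estimate_br(ser0, c(0, 200)), "no qualifying")
  expect_true(is.na(v))
})

test_that("phasic SCR deconvolution is linear and thresholded", {
  set.seed(61)
  # drivers of amplitude a and 2a: recovered maxima ratio ~ 2
  s <- simulate_scr(c(40, 100), c(0.1, 0.2), drift = 2, rate = 100,
                    duration = 160, noise_sd = 0)
  ps <- phasic_scr(s, data.frame(onset = c(39.5, 99.5)))
  v <- ps$per_event$max_phasic
  expect_true(all(v > 0.01))
  expect_equal(v[2] / v[1], 2, tolerance = 0.05)
  # drift-only signal: everything below the 0.01 muS threshold
  sd0 <- simulate_scr(numeric(0), numeric(0),
                      drift = function(t) 2 + 0.3 * sin(2 * pi * t / 300),
                      rate = 100, duration = 200, noise_sd = 0)
  p0 <- phasic_scr(sd0, data.frame(onset = c(30, 80, 130)))
  expect_true(all(p0$per_event$max_phasic == 0))
  expect_error(phasic_scr(list(data = c(1, NA, 3), rate = 20),
                          data.frame(onset = 0)), "non-finite")
  # deconvolution + reconvolution reproduces the response shape within
  # regularization tolerance (pointwise mismatch concentrates at the
  # smoothed rise edge, so compare shape and in-window peaks)
  resp <- s$data - 2
  ref <- approx(seq_along(resp) / 100, resp, n = length(ps$phasic))$y
  expect_gt(cor(ps$phasic, ref), 0.97)
  expect_equal(v, c(max(ref[(39 * 20):(43 * 20)]),
                    max(ref[(99 * 20):(103 * 20)])), tolerance = 0.15)
})

test_that("generator SCR contrast is ordered enhanced > baseline", {
  sim <- periphys_session()
  scr <- get_channel(sim$recording, "scr")
  base <- block_span(sim$recording, "baseline")
  pseudo <- make_pseudo_events(base, n = 60)
  v0 <- mean(phasic_scr(scr, pseudo)$per_event$max_phasic)
  ve <- mean(phasic_scr(scr, sim$events[sim$events$block == "enhanced",
  ])$per_event$max_phasic)
  expect_gt(ve, v0)
})
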