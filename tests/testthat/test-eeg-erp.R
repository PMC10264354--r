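# EEG chain: filtering, re-referencing, epoching, artifact rules,
# averaging, and planted-LPP parameter recovery.

sine_channel <- function(freq, fs = 250, dur = 40, amp = 1) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  list(data = amp * sin(2 * pi * freq * tt), rate = fs, units = "muV")
}

mid_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[round(n / 4):round(3 * n / 4)]^2))
}

test_that("preprocessing notches 60 Hz, keeps 10 Hz, removes DC", {
  out60 <- preprocess_eeg(sine_channel(60))
  atten <- 20 * log10(mid_rms(out60$data) / (1 / sqrt(2)))
  expect_lt(atten, -40)
  out10 <- preprocess_eeg(sine_channel(10))
  expect_equal(mid_rms(out10$data), 1 / sqrt(2), tolerance = 0.01)
  dc <- preprocess_eeg(list(data = rep(5, 10000), rate = 250,
                            units = "muV"))
  expect_lt(max(abs(mid_rms(dc$data))), 0.05)
  expect_error(preprocess_eeg(list(data = rnorm(100), rate = 100)),
               "too low")
})

test_that("the downsampler brings 1000 Hz input to 250 Hz intact", {
  ch <- sine_channel(10, fs = 1000, dur = 20)
  out <- preprocess_eeg(ch)
  expect_equal(out$rate, 250)
  expect_equal(length(out$data), length(ch$data) / 4)
  expect_equal(mid_rms(out$data), 1 / sqrt(2), tolerance = 0.01)
})

test_that("mastoid re-referencing is exact and idempotent", {
  set.seed(4)
  x <- matrix(rnorm(1000 * 4), 1000, 4,
              dimnames = list(NULL, c("Cz", "Pz", "TP9", "TP10")))
  ch <- list(data = x, rate = 250, units = "muV")
  # identical signal on all channels cancels completely
  same <- ch; same$data[] <- rep(x[, 1], 4)
  expect_true(all(abs(rereference_mastoids(same)$data) < 1e-12))
  # zero mastoids leave data untouched
  z <- ch; z$data[, c("TP9", "TP10")] <- 0
  expect_equal(rereference_mastoids(z)$data, z$data)
  # double application is a no-op (mastoid mean becomes zero)
  once <- rereference_mastoids(ch)
  twice <- rereference_mastoids(once)
  expect_equal(twice$data, once$data)
  expect_error(rereference_mastoids(list(data = x[, 1:2], rate = 250)),
               "mastoid")
})

test_that("epoching uses a half-open 800-sample window with baseline", {
  fs <- 250
  x <- matrix(rnorm(30 * fs), ncol = 2)
  colnames(x) <- c("Cz", "Pz")
  ch <- list(data = x, rate = fs, units = "muV")
  ev <- data.frame(onset = c(5, 12))
  ep <- epoch_eeg(ch, ev)
  expect_equal(dim(ep$data), c(2, 2, 800))
  expect_equal(sum(ep$times < 0), 50)
  expect_equal(ep$times[51], 0)
  # per-epoch, per-channel baseline mean is zero
  for (e in 1:2) for (c0 in 1:2)
    expect_equal(mean(ep$data[e, c0, 1:50]), 0)
  # constant input is identically zero after baseline correction
  cc <- ch; cc$data[] <- 7
  epc <- epoch_eeg(cc, ev)
  expect_true(all(epc$data == 0))
  # an event too close to the start is skipped and counted
  ep2 <- epoch_eeg(ch, data.frame(onset = c(0.1, 12)))
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$n_skipped_edge, 1L)
})

test_that("artifact rules flag steps, ranges and flatlines", {
  base <- matrix(rnorm(2 * 800, sd = 5), 2, 800)
  step <- base; step[1, 400] <- step[1, 399] + 60       # 60 muV jump
  sine <- matrix(rep(20 * sin(2 * pi * 10 * (0:799) / 250), each = 2),
                 2, 800, byrow = FALSE)                 # 40 muV pk-pk
  flat <- base; flat[2, 301:400] <- 1.23                # 400 ms constant
  # triangle of 10 muV/sample: within the step rule but 500 muV swing
  big <- base
  big[1, 450:499] <- seq_len(50) * 10
  big[1, 500:549] <- seq(490, 0, by = -10)
  ep <- mk_epochs(list(base, step, sine, flat, big))
  ep <- reject_artifacts(ep)
  expect_equal(ep$reject, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(ep$reject_reason[2], "step50")
  expect_equal(ep$reject_reason[4], "flatline")
  expect_equal(ep$reject_reason[5], "range200")
  # conservation: accepted + rejected = extracted
  expect_equal(sum(ep$reject) + sum(!ep$reject), dim(ep$data)[1])
})

test_that("averaging is linear and baseline-invariant", {
  fs <- 250
  set.seed(8)
  x <- matrix(rnorm(20 * fs), ncol = 2,
              dimnames = list(NULL, c("Cz", "Pz")))
  ch <- list(data = x, rate = fs, units = "muV")
  ev <- data.frame(onset = c(4, 9, 14))
  ep <- epoch_eeg(ch, ev)
  shifted <- ch; shifted$data <- x + 3
  eps <- epoch_eeg(shifted, ev)
  # with baseline correction a constant shift cancels
  expect_equal(average_erp(eps)$mean, average_erp(ep)$mean)
  # without it, the shift propagates through the average
  epn <- epoch_eeg(ch, ev, baseline_correct = FALSE)
  epsn <- epoch_eeg(shifted, ev, baseline_correct = FALSE)
  expect_equal(average_erp(epsn)$mean, average_erp(epn)$mean + 3)
  # single accepted epoch: SEM = 0 by convention
  one <- epoch_eeg(ch, data.frame(onset = 4))
  expect_true(all(average_erp(one)$sem == 0))
})

test_that("a noise-free planted deflection is recovered exactly", {
  fs <- 250
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tpl <- lpp_template(tt - 8)              # one event at t = 8 s
  amp <- 6
  x <- matrix(rep(amp * tpl, 9), ncol = 9)
  colnames(x) <- c(lpp_channels(), "Fz")
  x[, "Fz"] <- 0
  ep <- epoch_eeg(list(data = x, rate = fs, units = "muV"),
                  data.frame(onset = 8))
  erp <- average_erp(ep)
  lpp <- lpp_metrics(erp)
  aw <- seq(0.4, 0.72 - 1 / fs, by = 1 / fs)
  # amplitude = planted amplitude x window-mean of the template, scaled
  # by the 8/9 channel average (Fz carries nothing)
  expect_equal(lpp$amplitude, amp * mean(lpp_template(aw)),
               tolerance = 1e-6)
  expect_equal(lpp$latency, 0.6, tolerance = 0.01)
})

test_that("planted LPP amplitudes are recovered from a full session", {
  sim <- erp_session()
  truth <- sim$truth
  for (b in c("normal", "enhanced")) {
    ev <- sim$events[sim$events$block == b, ]
    span <- unlist(sim$recording$blocks[
      sim$recording$blocks$label == b, c("start", "end")])
    sc <- score_block(ev, sim$presses, span)
    ev <- classify_events(ev, sc)
    ep <- reject_artifacts(epoch_eeg(sim$eeg, ev,
                                     class_filter = "true_positive"))
    erp <- average_erp(ep)
    lpp <- lpp_metrics(erp)
    resp <- truth$responded & sim$events$block == b
    expected <- mean(truth$lpp_event_amplitude[resp]) *
      truth$lpp_template_window_mean
    expect_lt(abs(lpp$amplitude - expected) / expected, 0.10)
    # miss-class epochs carry no deflection
    if (any(!sc$per_event$hit)) {
      epm <- epoch_eeg(sim$eeg, ev, class_filter = "miss")
      if (dim(epm$data)[1] >= 5) {
        erpm <- average_erp(reject_artifacts(epm))
        lppm <- lpp_metrics(erpm)
        expect_lt(abs(lppm$amplitude), 0.5 * expected)
      }
    }
  }
  # planted enhanced amplitude is 2x normal and recovered in that order
  lppv <- sapply(c("normal", "enhanced"), function(b) {
    ev <- sim$events[sim$events$block == b, ]
    span <- unlist(sim$recording$blocks[
      sim$recording$blocks$label == b, c("start", "end")])
    sc <- score_block(ev, sim$presses, span)
    ep <- reject_artifacts(epoch_eeg(sim$eeg, classify_events(ev, sc),
                                     class_filter = "true_positive"))
    lpp_metrics(average_erp(ep))$amplitude
  })
  expect_gt(lppv["enhanced"], lppv["normal"])
})
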