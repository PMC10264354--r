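# Signal-detection scoring: A', its normalization, exact binomial
# thresholds, and block scoring against simulated button presses.

test_that("a_prime reproduces closed-form values and handles limits", {
  expect_equal(a_prime(1, 0), 1)
  expect_equal(a_prime(0.5, 0.5), 0.5)
  # hand evaluation: 0.5 + (0.6 * 1.6) / (4 * 0.8 * 0.8)
  expect_equal(a_prime(0.8, 0.2), 0.875)
  expect_equal(a_prime(0, 0), 0.5)
  expect_equal(a_prime(1, 1), 0.5)
  expect_equal(a_prime(0, 1), 0)      # reflection of the perfect case
  expect_error(a_prime(1.2, 0), "\\[0, 1\\]")
})

test_that("a_prime is monotone in TP/FP and reflection-symmetric", {
  g <- seq(0, 1, by = 0.05)
  for (fp in g) {
    v <- a_prime(g, fp)
    expect_true(all(diff(v) >= -1e-12))          # non-decreasing in TP
  }
  for (tp in g) {
    v <- a_prime(tp, g)
    expect_true(all(diff(v) <= 1e-12))           # non-increasing in FP
  }
  for (tp in g) for (fp in g)
    expect_equal(a_prime(tp, fp) + a_prime(fp, tp), 1)
})

test_that("normalization maps A' onto [0, pi] radians", {
  expect_equal(normalize_a_prime(1), pi)
  expect_equal(normalize_a_prime(0.5), pi / 2)
  expect_equal(normalize_a_prime(0), 0)
  expect_equal(normalize_a_prime(0.875), 2 * asin(sqrt(0.875)))
  expect_error(normalize_a_prime(1.01), "\\[0, 1\\]")
})

test_that("binomial threshold matches brute-force exact tails", {
  expect_identical(binomial_threshold(120, 0.5, 0.05), 70L)
  expect_identical(binomial_threshold(114, 0.5, 0.05), 67L)
  # brute force over a range of n: smallest k with sum dbinom(k..n) < alpha
  brute <- function(n, p, alpha) {
    for (k in 0:n) if (sum(dbinom(k:n, n, p)) < alpha) return(k)
    n + 1L
  }
  for (n in c(1, 2, 5, 17, 60, 114, 120, 200))
    for (p in c(0.25, 0.5))
      expect_equal(binomial_threshold(n, p, 0.05), brute(n, p, 0.05),
                   info = sprintf("n=%d p=%g", n, p))
  # degenerate n = 1: unattainable, sentinel n + 1
  expect_identical(binomial_threshold(1, 0.5, 0.05), 2L)
})

test_that("score_block scores hits, false positives, and latencies", {
  ev <- mk_events(c(10, 20, 30, 40))
  span <- c(0, 50)
  # a press 0.5 s after every onset, none elsewhere
  r <- score_block(ev, ev$onset + 0.5, span)
  expect_equal(r$TP, 1)
  expect_equal(r$FP, 0)
  expect_equal(r$latency_mean, 0.5)
  expect_equal(r$a_prime, 1)
  expect_equal(r$n_correct, 8)
  # no presses: valid non-responder, latency absent
  r0 <- score_block(ev, numeric(0), span)
  expect_equal(r0$TP, 0)
  expect_equal(r0$FP, 0)
  expect_true(is.na(r0$latency_mean))
  expect_equal(r0$a_prime, 0.5)
  # presses only in the gaps are false positives
  r1 <- score_block(ev, c(16, 26), span)
  expect_equal(r1$TP, 0)
  expect_equal(r1$FP, 0.5)
  expect_error(score_block(ev[0, ], 1, span), "at least one")
})

test_that("Poisson presses yield the implied false-positive rate", {
  # 60 trials per block, many blocks; presses from a Poisson process of
  # rate L: P(>= 1 press in a non-vib interval of length g) = 1-exp(-Lg)
  set.seed(1)
  L <- 0.05
  fps <- 0; gaps <- 0
  for (rep in 1:20) {
    on <- seq(5, 5 + 59 * 9, by = 9)
    ev <- mk_events(on)
    span <- c(0, max(on) + 9)
    n_press <- rpois(1, L * diff(span))
    r <- score_block(ev, sort(runif(n_press, span[1], span[2])), span)
    # expected FP prob per complementary interval (length 5 s)
    fps <- fps + r$FP * r$n_nonvib_trials
    gaps <- gaps + r$n_nonvib_trials
  }
  p_exp <- 1 - exp(-L * 5)
  ci <- qbinom(c(0.0005, 0.9995), gaps, p_exp) / gaps
  expect_gte(fps / gaps, ci[1])
  expect_lte(fps / gaps, ci[2])
})

test_that("scoring a simulated responder recovers the configured rates", {
  # >= 1000 events across seeds; schedule/responder only (no channels)
  hits <- 0; nev <- 0; lat <- numeric(0)
  for (s in 1:9) {
    cfg <- session_config(
      block_plan = data.frame(label = c("normal", "enhanced"),
                              duration = c(450, 450)),
      n_stims = c(normal = 60, enhanced = 57),
      channels = character(0), seed = 100 + s)
    sim <- simulate_session(cfg)
    for (b in c("normal", "enhanced")) {
      ev <- sim$events[sim$events$block == b, ]
      span <- unlist(sim$recording$blocks[
        sim$recording$blocks$label == b, c("start", "end")])
      r <- score_block(ev, sim$presses, span)
      if (b == "normal") { hits <- hits + sum(r$per_event$hit); nev <- nev + nrow(ev) }
      else lat <- c(lat, r$per_event$latency[r$per_event$hit])
    }
  }
  expect_gte(nev, 500)
  ci <- qbinom(c(0.005, 0.995), nev, 0.80) / nev   # 99% binomial CI
  expect_gte(hits / nev, ci[1])
  expect_lte(hits / nev, ci[2])
  # enhanced latency mean near its configured 0.74 s (2 SE)
  expect_lt(abs(mean(lat) - 0.74), 2 * sd(lat) / sqrt(length(lat)) + 0.02)
})
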