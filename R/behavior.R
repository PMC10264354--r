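#' Nonparametric sensitivity index A'
#'
#' Signal-detection analog of d' suited to low trial counts:
#' `A' = 1/2 + (TP - FP)(1 + TP - FP) / (4 TP (1 - FP))` for `TP >= FP`,
#' with the symmetric reflection
#' `1/2 - (FP - TP)(1 + FP - TP) / (4 FP (1 - TP))` when `FP > TP`, where
#' TP and FP are the true- and false-positive rates. `A' = 0.5` is chance
#' and 1 is perfect discrimination; the reflection makes
#' `a_prime(TP, FP) + a_prime(FP, TP) = 1` hold everywhere.
#'
#' @param TP,FP rates in `[0, 1]`
#' @return A' in `[0, 1]`
#' @export
a_prime <- function(TP, FP) {
  if (any(TP < 0 | TP > 1 | FP < 0 | FP > 1))
    stop("TP and FP must lie in [0, 1]")
  n <- max(length(TP), length(FP))
  TP <- rep_len(TP, n); FP <- rep_len(FP, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tp <- TP[i]; fp <- FP[i]
    out[i] <- if (tp == fp) 0.5
    else if (tp > fp) {
      den <- 4 * tp * (1 - fp)     # > 0 whenever tp > fp
      0.5 + (tp - fp) * (1 + tp - fp) / den
    } else {
      den <- 4 * fp * (1 - tp)
      0.5 - (fp - tp) * (1 + fp - tp) / den
    }
  }
  out
}

#' Arcsine normalization of A'
#'
#' Variance-stabilizing transform `2 * asin(sqrt(a))`, mapping A' in
#' `[0, 1]` to `[0, pi]` radians (chance 0.5 maps to pi/2).
#'
#' @param a A' values in `[0, 1]`
#' @return radians in `[0, pi]`
#' @export
normalize_a_prime <- function(a) {
  if (any(a < 0 | a > 1)) stop("A' must lie in [0, 1]")
  2 * asin(sqrt(a))
}

#' Exact binomial above-chance threshold
#'
#' Smallest number of correct trials `k` such that
#' `P(X >= k) < alpha` for `X ~ Binomial(n_trials, chance)`, computed from
#' the exact binomial tail (no normal approximation). With 60 vibration +
#' 60 non-vibration trials (n = 120, chance 0.5, alpha 0.05) the threshold
#' is 70 correct trials; with 57 + 57 (n = 114) it is 67.
#'
#' @param n_trials total number of trials (>= 1)
#' @param chance success probability under the null, in (0, 1)
#' @param alpha significance level, in (0, 1)
#' @return smallest attaining count, or `n_trials + 1` when even a perfect
#'   score is not below `alpha` (unattainable sentinel)
#' @export
binomial_threshold <- function(n_trials, chance = 0.5, alpha = 0.05) {
  stopifnot(n_trials >= 1, chance > 0, chance < 1, alpha > 0, alpha < 1)
  k <- 0:n_trials
  tail <- pbinom(k - 1, n_trials, chance, lower.tail = FALSE)  # P(X >= k)
  hit <- which(tail < alpha)
  if (length(hit) == 0) return(as.integer(n_trials) + 1L)
  as.integer(k[hit[1]])
}

#' Score button presses against vibration events for one block
#'
#' Each vibration defines a trial window `[onset, offset + grace]`; a press
#' onset inside the window is a hit, and the latency is the (first) press
#' onset minus the vibration onset. Non-vibration trials are the
#' complementary intervals following each trial window (one per vibration,
#' truncated to the block span), so trial counts are matched; a press
#' onset inside one is a false positive. Presses falling in no trial are
#' logged but unscored. A block with no presses at all is valid (TP = 0,
#' latency absent), mirroring non-responders.
#'
#' @param events data.frame with `onset`, `offset` (s), all within
#'   `block_span`
#' @param presses `list(press_times, release_times)` or a numeric vector of
#'   press onsets
#' @param block_span `c(start, end)` of the block (s)
#' @param grace seconds after vibration offset still credited as a hit
#'   (default 1.0 s, on the order of the mean response latency)
#' @param chance,alpha passed to [binomial_threshold()] for the
#'   above-chance flag
#' @return `list` of class `gw_scored_behavior`: trial counts, `TP`, `FP`
#'   rates, `n_correct`, `a_prime`, `a_prime_norm`, `latency_mean`,
#'   `latency_sd` (NA when no hits), `above_chance`, and the `per_event`
#'   table
#' @export
score_block <- function(events, presses, block_span, grace = 1.0,
                        chance = 0.5, alpha = 0.05) {
  if (is.null(events) || nrow(events) == 0)
    stop("score_block requires at least one vibration event")
  press <- if (is.list(presses)) presses$press_times else presses
  press <- sort(press)
  ev <- events[order(events$onset), , drop = FALSE]
  if (any(ev$onset < block_span[1]) || any(ev$offset > block_span[2]))
    stop("events must lie within the block span")
  n <- nrow(ev)
  win_lo <- ev$onset
  win_hi <- pmin(ev$offset + grace, block_span[2])
  # complementary non-vibration intervals, one per vibration
  nv_lo <- win_hi
  nv_hi <- c(win_lo[-1], block_span[2])
  nv_hi <- pmax(nv_hi, nv_lo)

  hit <- logical(n); latency <- rep(NA_real_, n); fp <- logical(n)
  for (i in seq_len(n)) {
    inw <- press >= win_lo[i] & press <= win_hi[i]
    if (any(inw)) {
      hit[i] <- TRUE
      latency[i] <- press[which(inw)[1]] - ev$onset[i]
    }
    fp[i] <- any(press > nv_lo[i] & press <= nv_hi[i])
  }
  scored <- press >= win_lo[1] & press <= max(nv_hi)
  n_unscored <- sum(!scored)

  TP <- mean(hit); FP <- mean(fp)
  n_correct <- sum(hit) + sum(!fp)
  ap <- a_prime(TP, FP)
  thr <- binomial_threshold(2L * n, chance, alpha)
  lat <- latency[hit]
  structure(list(
    n_vib_trials = n, n_nonvib_trials = n,
    TP = TP, FP = FP, n_correct = n_correct,
    a_prime = ap, a_prime_norm = normalize_a_prime(ap),
    latency_mean = if (length(lat)) mean(lat) else NA_real_,
    latency_sd = if (length(lat) > 1) sd(lat) else NA_real_,
    above_chance = n_correct >= thr,
    binomial_threshold = thr,
    n_unscored_presses = n_unscored,
    per_event = data.frame(onset = ev$onset, hit = hit,
                           latency = latency, fp_interval = fp)),
    class = "gw_scored_behavior")
}

#' @export
print.gw_scored_behavior <- function(x, ...) {
  cat(sprintf(
    "<gw_scored_behavior> %d+%d trials TP=%.3f FP=%.3f A'=%.3f (norm %.3f)\n",
    x$n_vib_trials, x$n_nonvib_trials, x$TP, x$FP, x$a_prime,
    x$a_prime_norm))
  if (!is.na(x$latency_mean))
    cat(sprintf("  latency %.3f +- %.3f s; %s chance (>=%d/%d correct)\n",
                x$latency_mean, ifelse(is.na(x$latency_sd), 0, x$latency_sd),
                if (x$above_chance) "above" else "not above",
                x$binomial_threshold, x$n_vib_trials + x$n_nonvib_trials))
  invisible(x)
}
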