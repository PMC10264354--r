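#' Session configuration for the synthetic generator
#'
#' Bundles every tunable of the synthetic multi-modal session. Defaults are
#' the study conditions of the capsule experiment: a 30-min baseline then
#' two 13-min stimulation blocks (counterbalanced normal/enhanced order)
#' with 60 three-second vibrations in the normal block and 57 in the
#' enhanced block, each vibration ramping up over 0.25 s; a behavioural
#' responder with condition-dependent hit rates and latency distributions
#' (means 1.06 s normal / 0.74 s enhanced, SDs 0.46 / 0.28 s); a planted
#' parieto-occipital late positive potential scaled by condition; a 3 cpm
#' gastric slow wave; and condition-dependent tonic/phasic heart rate and
#' electrodermal responses.
#'
#' @param block_plan data.frame `label`, `duration` (s). Order of the two
#'   stimulation blocks encodes the counterbalancing.
#' @param n_stims named vector: vibrations per stimulation block
#' @param stim_duration vibration duration (s)
#' @param ramp_duration amplitude ramp-up at vibration onset (s)
#' @param min_gap minimum silent gap between vibrations (s); guarantees
#'   non-vibration intervals exist for false-positive scoring
#' @param rates named list of sampling rates (Hz); `eeg` defaults to the
#'   250 Hz analysis rate (set 1000 to exercise the downsampler)
#' @param responder list: `hit_rate`, `fp_rate` (per condition),
#'   `latency_mean`, `latency_sd` (s)
#' @param effects list of planted physiological effects, see Details
#' @param channels which channels to synthesize (subset of `eeg`, `ecg`,
#'   `egg`, `scr`, `stetho`); dropping channels speeds up studies that
#'   only exercise part of the pipeline, without changing the schedule,
#'   responder draw, or any other channel (independent RNG streams)
#' @param seed integer seed; identical (config, seed) pairs reproduce
#'   bit-identical sessions
#'
#' @details `effects` fields: `lpp_amplitude` (muV per condition on the
#' eight posterior channels), `lpp_window` (template onset/offset, s),
#' `lpp_peak`, `lpp_tau`, `lpp_jitter` (trial-to-trial multiplicative
#' amplitude SD, default 0.3), `egg_freq` (cpm), `egg_amp` (muV),
#' `tonic_hr` (bpm per block), `phasic_hr_delta` (bpm per condition),
#' `scr_amplitude` (muS per condition), `br` (breaths/min), `rsa_depth`
#' (ms), `stetho_amp` (a.u. per condition), and `noise` levels per channel.
#'
#' @return object of class `gw_session_config`
#' @export
session_config <- function(
    block_plan = data.frame(label = c("baseline", "normal", "enhanced"),
                            duration = c(1800, 780, 780)),
    n_stims = c(normal = 60, enhanced = 57),
    stim_duration = 3.0,
    ramp_duration = 0.25,
    min_gap = 4.0,
    rates = list(eeg = 250, ecg = 1000, egg = 1000, scr = 1000,
                 stetho = 1000),
    responder = list(hit_rate = c(normal = 0.80, enhanced = 0.95),
                     fp_rate = c(normal = 0.10, enhanced = 0.05),
                     latency_mean = c(normal = 1.06, enhanced = 0.74),
                     latency_sd = c(normal = 0.46, enhanced = 0.28)),
    effects = list(),
    channels = c("eeg", "ecg", "egg", "scr", "stetho"),
    seed = 1L) {
  all_ch <- c("eeg", "ecg", "egg", "scr", "stetho")
  if (length(bad_ch <- setdiff(channels, all_ch)))
    stop("unknown channels: ", paste(bad_ch, collapse = ", "))
  stopifnot(all(c("label", "duration") %in% names(block_plan)),
            all(block_plan$duration > 0),
            stim_duration > 0, ramp_duration > 0, min_gap >= 0)
  if (any(responder$hit_rate < 0 | responder$hit_rate > 1) ||
      any(responder$fp_rate < 0 | responder$fp_rate > 1))
    stop("responder probabilities must lie in [0, 1]")
  if (any(responder$latency_mean <= 0))
    stop("latency_mean must be positive")
  eff <- utils::modifyList(list(
    lpp_amplitude = c(normal = 5, enhanced = 10),
    lpp_window = c(0.4, 3.0), lpp_peak = 0.6, lpp_tau = 0.8,
    lpp_jitter = 0.3,
    egg_freq = 3.0, egg_amp = 100,
    tonic_hr = c(baseline = 70, normal = 74, enhanced = 75),
    phasic_hr_delta = c(baseline = 0, normal = 2, enhanced = 2),
    scr_amplitude = c(baseline = 0, normal = 0.02, enhanced = 0.10),
    br = 15, rsa_depth = 40,
    stetho_amp = c(normal = 1, enhanced = 2),
    noise = list(eeg = 10, alpha = 3, stetho = 0.05, ecg = 0.02,
                 egg = 20, scr = 0.005)), effects)
  if (eff$egg_freq < 0.5 || eff$egg_freq > 11)
    stop("egg_freq must lie in the 0.5-11 cpm physiological range")
  if (any(eff$lpp_amplitude < 0) || any(eff$scr_amplitude < 0) ||
      eff$egg_amp < 0)
    stop("planted amplitudes must be >= 0")
  # feasibility: every stimulation block must hold its vibrations
  for (b in seq_len(nrow(block_plan))) {
    lab <- block_plan$label[b]
    if (lab %in% names(n_stims)) {
      need <- n_stims[[lab]] * (stim_duration + min_gap) + min_gap
      if (need > block_plan$duration[b])
        stop("block '", lab, "' too short for ", n_stims[[lab]],
             " stimulations")
    }
  }
  structure(list(block_plan = block_plan, n_stims = n_stims,
                 stim_duration = stim_duration,
                 ramp_duration = ramp_duration, min_gap = min_gap,
                 rates = rates, responder = responder, effects = eff,
                 channels = channels, seed = as.integer(seed)),
            class = "gw_session_config")
}

# pseudorandom stimulation schedule: n windows of length dur inside
# [start, end], gaps >= min_gap (also before the first / after the last)
schedule_stims <- function(start, end, n, dur, min_gap) {
  slack <- (end - start) - n * dur - (n + 1) * min_gap
  if (slack < 0) stop("block too short for requested stimulation count")
  cuts <- sort(runif(n)) * slack
  onsets <- start + min_gap + cuts + (seq_len(n) - 1) * (dur + min_gap)
  data.frame(onset = onsets, offset = onsets + dur)
}

#' Simulate a complete synthetic session
#'
#' Generates all channels (31-channel EEG, ECG, EGG, SCR, digital
#' stethoscope), the vibration event schedule, the behavioural button
#' presses, and a ground-truth record sufficient to verify every
#' downstream analysis stage by parameter recovery.
#'
#' @param config a [session_config()]
#' @return list with elements
#'   \describe{
#'     \item{recording}{[new_recording()] with channels `eeg` (samples x 31
#'       matrix, 10-20 labels incl. TP9/TP10), `ecg`, `egg`, `scr`,
#'       `stetho`}
#'     \item{events}{data.frame `onset`, `offset`, `block`, `condition`,
#'       `kind`}
#'     \item{presses}{`list(press_times, release_times)`}
#'     \item{truth}{ground truth: per-event responded flags and latencies,
#'       planted LPP amplitudes and the template mean over the 0.4-0.72 s
#'       analysis window, per-block tonic HR, breathing rate, R-peak
#'       times, SCR driver times/amplitudes, EGG frequency}
#'   }
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "gw_session_config"))
  bp <- config$block_plan
  bp$start <- cumsum(c(0, head(bp$duration, -1)))
  bp$end <- bp$start + bp$duration
  total <- sum(bp$duration)
  eff <- config$effects
  resp <- config$responder

  ## --- 1. schedule -------------------------------------------------------
  set.seed(derive_seed(config$seed, 1))
  events <- NULL
  for (b in seq_len(nrow(bp))) {
    lab <- bp$label[b]
    if (!lab %in% names(config$n_stims)) next
    s <- schedule_stims(bp$start[b], bp$end[b], config$n_stims[[lab]],
                        config$stim_duration, config$min_gap)
    s$block <- lab; s$condition <- lab; s$kind <- "vibration"
    events <- rbind(events, s)
  }
  if (is.null(events))
    events <- data.frame(onset = numeric(0), offset = numeric(0),
                         block = character(0), condition = character(0),
                         kind = character(0))
  events <- events[order(events$onset), ]
  rownames(events) <- NULL

  ## --- 2. responder ------------------------------------------------------
  set.seed(derive_seed(config$seed, 2))
  nev <- nrow(events)
  responded <- logical(nev); latency <- rep(NA_real_, nev)
  for (i in seq_len(nev)) {
    cond <- events$condition[i]
    if (runif(1) < resp$hit_rate[[cond]]) {
      responded[i] <- TRUE
      l <- rnorm(1, resp$latency_mean[[cond]], resp$latency_sd[[cond]])
      latency[i] <- min(max(l, 0.1), config$stim_duration + 0.9)
    }
  }
  press <- events$onset[responded] + latency[responded]
  # false positives: at most one per inter-stimulus interval
  for (b in unique(events$block)) {
    ev <- events[events$block == b, ]
    span <- c(bp$start[bp$label == b], bp$end[bp$label == b])
    gaps_lo <- c(ev$offset)
    gaps_hi <- c(ev$onset[-1], span[2])
    for (g in seq_along(gaps_lo)) {
      if (gaps_hi[g] - gaps_lo[g] < 1) next
      if (runif(1) < resp$fp_rate[[b]])
        press <- c(press, runif(1, gaps_lo[g] + 0.3, gaps_hi[g] - 0.3))
    }
  }
  press <- sort(press)
  hold <- runif(length(press), 0.5, 2.0)
  release <- press + hold
  if (length(press) > 1)  # clip holds so presses never overlap
    release[-length(press)] <- pmin(release[-length(press)],
                                    press[-1] - 0.05)
  presses <- list(press_times = press, release_times = release)

  chans <- list()
  want <- function(nm) nm %in% config$channels

  ## --- 3. stethoscope ----------------------------------------------------
  if (want("stetho")) {
    set.seed(derive_seed(config$seed, 3))
    fs <- config$rates$stetho
    n <- round(total * fs)
    stetho <- rnorm(n, sd = eff$noise$stetho)
    carrier_f <- 80
    for (i in seq_len(nev)) {
      i0 <- round(events$onset[i] * fs) + 1
      i1 <- min(n, round(events$offset[i] * fs))
      tt <- (seq(i0, i1) - i0) / fs
      env <- pmin(1, tt / config$ramp_duration) *
        pmin(1, pmax(0, (max(tt) - tt) / 0.05))
      amp <- eff$stetho_amp[[events$condition[i]]]
      stetho[i0:i1] <- stetho[i0:i1] +
        amp * env * sin(2 * pi * carrier_f * tt)
    }
    chans$stetho <- list(data = stetho, rate = fs, units = "a.u.")
  }

  ## --- 4. ECG ------------------------------------------------------------
  ecg <- NULL
  if (want("ecg")) {
    set.seed(derive_seed(config$seed, 4))
    tonic_fun <- if (nrow(bp) > 1)
      stats::stepfun(bp$start[-1], eff$tonic_hr[bp$label])
    else function(t) eff$tonic_hr[[bp$label[1]]]
    stim_on <- events$onset; stim_off <- events$offset
    stim_delta <- eff$phasic_hr_delta[events$condition]
    hr_fun <- function(t) {
      h <- tonic_fun(t)
      k <- findInterval(t, stim_on)
      if (k > 0 && t < stim_off[k]) h <- h + stim_delta[[k]]
      h
    }
    ecg <- simulate_ecg(hr_fun, rsa_depth = eff$rsa_depth, br = eff$br,
                        rate = config$rates$ecg, duration = total,
                        noise_sd = eff$noise$ecg)
    chans$ecg <- list(data = ecg$data, rate = ecg$rate, units = "mV")
  }

  ## --- 5. EGG ------------------------------------------------------------
  if (want("egg")) {
    set.seed(derive_seed(config$seed, 5))
    fs <- config$rates$egg
    n <- round(total * fs)
    tt <- (seq_len(n) - 1) / fs
    egg <- eff$egg_amp * sin(2 * pi * eff$egg_freq / 60 * tt) +
      noise_oneoverf(n, fs, sd = eff$noise$egg)
    chans$egg <- list(data = egg, rate = fs, units = "muV")
  }

  ## --- 6. SCR ------------------------------------------------------------
  drv_t <- events$onset[responded] + 0.5
  drv_a <- eff$scr_amplitude[events$condition[responded]]
  keep <- logical(length(drv_t))
  if (want("scr")) {
    set.seed(derive_seed(config$seed, 6))
    drv_a <- drv_a * runif(sum(responded), 0.8, 1.2)
    keep <- drv_a > 0
    scr <- simulate_scr(drv_t[keep], drv_a[keep],
                        drift = function(t) 2 + 0.2 * sin(2 * pi * t / 600),
                        rate = config$rates$scr, duration = total,
                        noise_sd = eff$noise$scr)
    chans$scr <- list(data = scr$data, rate = scr$rate, units = "muS")
  }

  ## --- 7. EEG ------------------------------------------------------------
  w <- eff$lpp_window
  ev_amp <- rep(NA_real_, nev)
  if (want("eeg")) {
    set.seed(derive_seed(config$seed, 7))
    fs <- config$rates$eeg
    n <- round(total * fs)
    labs <- montage_1020()$label
    eeg <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
    tt_alpha <- (seq_len(n) - 1) / fs
    occ <- labs %in% c("O1", "Oz", "O2", "POz", "P3", "Pz", "P4")
    for (j in seq_along(labs)) {
      ch <- noise_oneoverf(n, fs, sd = eff$noise$eeg)
      a <- eff$noise$alpha * (if (occ[j]) 1.5 else 1)
      if (a > 0)
        ch <- ch + a * sin(2 * pi * 10 * tt_alpha + runif(1, 0, 2 * pi))
      eeg[, j] <- ch
    }
    # plant the LPP on the posterior midline channels, locked to vibration
    # onset for responded (true-positive) events only
    tpl_t <- seq(0, w[2], by = 1 / fs)
    tpl <- lpp_template(tpl_t, onset = w[1], peak = eff$lpp_peak,
                        offset = w[2], tau = eff$lpp_tau)
    cluster_idx <- match(lpp_channels(), labs)
    for (i in which(responded)) {
      amp <- eff$lpp_amplitude[[events$condition[i]]] *
        max(0, 1 + eff$lpp_jitter * rnorm(1))
      ev_amp[i] <- amp
      i0 <- round(events$onset[i] * fs) + 1
      idx <- i0:min(n, i0 + length(tpl) - 1)
      eeg[idx, cluster_idx] <- eeg[idx, cluster_idx] +
        amp * tpl[seq_along(idx)]
    }
    chans$eeg <- list(data = eeg, rate = fs, units = "muV")
  }

  ## --- assemble ----------------------------------------------------------
  rec <- new_recording(
    channels = chans,
    blocks = bp[, c("label", "start", "end")],
    meta = list(seed = config$seed))

  # template mean over the 0.4-0.72 s LPP analysis window: the factor
  # linking planted amplitude to the measured window-average amplitude
  aw <- seq(0.4, 0.72 - 1 / config$rates$eeg, by = 1 / config$rates$eeg)
  tpl_mean <- mean(lpp_template(aw, onset = w[1], peak = eff$lpp_peak,
                                offset = w[2], tau = eff$lpp_tau))
  truth <- list(
    events = events, responded = responded, latency = latency,
    lpp_amplitude = eff$lpp_amplitude, lpp_event_amplitude = ev_amp,
    lpp_template_window_mean = tpl_mean, lpp_channels = lpp_channels(),
    tonic_hr = eff$tonic_hr, phasic_hr_delta = eff$phasic_hr_delta,
    br = eff$br, egg_freq = eff$egg_freq,
    r_peaks = if (is.null(ecg)) numeric(0) else ecg$r_peaks,
    scr_driver_times = drv_t[keep], scr_driver_amps = drv_a[keep])

  list(recording = rec, events = events, presses = presses, truth = truth)
}
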