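# Shared synthetic sessions, generated once per test run. Scaled-down
# block plans keep the suite fast; stimulation density, SNRs and effect
# sizes are the generator defaults.

.gw_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gw_test_cache))
    assign(key, force(expr), envir = .gw_test_cache)
  get(key, envir = .gw_test_cache)
}

# full multi-channel session, small blocks (vibration/behavior/io tests)
tiny_session <- function() cached("tiny", {
  cfg <- session_config(
    block_plan = data.frame(label = c("baseline", "normal", "enhanced"),
                            duration = c(200, 160, 160)),
    n_stims = c(normal = 12, enhanced = 11), seed = 42)
  c(simulate_session(cfg), list(config = cfg))
})

# EEG-only session with the full per-block trial counts (ERP tests)
erp_session <- function() cached("erp", {
  cfg <- session_config(
    block_plan = data.frame(label = c("normal", "enhanced"),
                            duration = c(480, 480)),
    n_stims = c(normal = 60, enhanced = 57),
    channels = "eeg", seed = 7)
  sim <- simulate_session(cfg)
  eeg <- rereference_mastoids(preprocess_eeg(get_channel(sim$recording,
                                                         "eeg")))
  c(sim, list(config = cfg, eeg = eeg))
})

# peripheral-channel session (EGG / cardiac / SCR tests)
periphys_session <- function() cached("periphys", {
  cfg <- session_config(
    block_plan = data.frame(label = c("baseline", "normal", "enhanced"),
                            duration = c(400, 400, 400)),
    n_stims = c(normal = 30, enhanced = 28),
    channels = c("ecg", "egg", "scr"), seed = 11)
  c(simulate_session(cfg), list(config = cfg))
})

# events data.frame helper
mk_events <- function(onsets, dur = 3, condition = "normal") {
  data.frame(onset = onsets, offset = onsets + dur,
             block = condition, condition = condition, kind = "vibration")
}

# raw epochs object from a list of channels x time matrices
mk_epochs <- function(mats, rate = 250, labels = NULL, t0_samples = 50) {
  n_ep <- length(mats)
  nc <- nrow(mats[[1]]); nt <- ncol(mats[[1]])
  arr <- array(0, c(n_ep, nc, nt))
  for (e in seq_len(n_ep)) arr[e, , ] <- mats[[e]]
  structure(list(data = arr,
                 times = (seq_len(nt) - 1 - t0_samples) / rate,
                 rate = rate,
                 labels = if (is.null(labels)) paste0("ch", seq_len(nc))
                 else labels,
                 meta = NULL, reject = rep(FALSE, n_ep),
                 reject_reason = rep(NA_character_, n_ep),
                 n_skipped_edge = 0L),
            class = "gw_epochs")
}

# cycle table with prescribed durations and a strictly monotone phase
mk_cycle_table <- function(durations, rate = 10) {
  bounds <- cumsum(c(5, durations))
  total <- bounds[length(bounds)] + 5
  tt <- seq(0, total, by = 1 / rate)
  ph <- numeric(length(tt))
  for (i in seq_along(durations)) {
    sel <- tt >= bounds[i] & tt < bounds[i + 1]
    ph[sel] <- -pi + 2 * pi * (tt[sel] - bounds[i]) / durations[i]
  }
  structure(list(boundaries = bounds, durations = durations,
                 flag = rep(FALSE, length(durations)),
                 flag_reason = rep(NA_character_, length(durations)),
                 phase = ph, times = tt, rate = rate,
                 envelope = rep(1, length(tt))),
            class = "gw_cycle_table")
}
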