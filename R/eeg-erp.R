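#' EEG preprocessing: downsample, notch, bandpass
#'
#' Brings raw EEG to the 250 Hz analysis rate and removes line noise and
#' out-of-band activity: (1) anti-aliased decimation to 250 Hz (FIR
#' low-pass at 100 Hz before sample picking; skipped when already at
#' 250 Hz), (2) a 4th-order Butterworth band-rejection filter with 1 Hz
#' bandwidth around 60 Hz, (3) a 0.1-80 Hz Butterworth bandpass realised
#' as a 4th-order high-pass plus 4th-order low-pass cascade. All filters
#' are applied forward-backward (zero phase), which doubles the effective
#' order - so the cascade has the nominal 48 dB/octave band edges.
#'
#' @param eeg channel: `list(data, rate, units)`, `data` a samples x
#'   channels matrix (or vector)
#' @param line_freq mains frequency (Hz)
#' @return channel list at 250 Hz
#' @export
preprocess_eeg <- function(eeg, line_freq = 60) {
  fs <- eeg$rate
  if (fs < 2 * 80) stop("sampling rate too low for a 80 Hz passband")
  x <- eeg$data
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  target <- 250
  if (fs > target) {
    if (abs(fs / target - round(fs / target)) > 1e-9)
      stop("input rate must be an integer multiple of 250 Hz")
    k <- round(fs / target)
    aa <- signal::fir1(96, (0.8 * target / 2) / (fs / 2))
    x <- apply(x, 2, function(v) signal::filtfilt(aa, v))
    x <- x[seq(1, nrow(x), by = k), , drop = FALSE]
    fs <- target
  }
  notch <- signal::butter(2, c(line_freq - 0.5, line_freq + 0.5) / (fs / 2),
                          type = "stop")
  hp <- signal::butter(4, 0.1 / (fs / 2), type = "high")
  lp <- signal::butter(4, 80 / (fs / 2), type = "low")
  for (j in seq_len(ncol(x))) {
    v <- signal::filtfilt(notch, x[, j])
    v <- signal::filtfilt(hp, v)
    x[, j] <- signal::filtfilt(lp, v)
  }
  list(data = if (vec) x[, 1] else x, rate = fs, units = eeg$units)
}

#' Re-reference to the mastoid average
#'
#' Subtracts the per-sample mean of TP9 and TP10 from every channel.
#' Applying it twice is a no-op because the mastoid mean is zero after the
#' first pass.
#'
#' @param eeg channel with matrix data whose columns include `TP9`, `TP10`
#' @return re-referenced channel
#' @export
rereference_mastoids <- function(eeg) {
  x <- eeg$data
  if (!is.matrix(x) || !all(c("TP9", "TP10") %in% colnames(x)))
    stop("mastoid channels TP9/TP10 not found")
  ref <- (x[, "TP9"] + x[, "TP10"]) / 2
  eeg$data <- x - ref
  eeg
}

#' Epoch continuous EEG around vibration onsets
#'
#' Cuts half-open `[-0.2, 3.0)` s windows (800 samples at 250 Hz) around
#' event onsets and baseline-corrects each epoch channel to the mean of
#' the 200 ms preceding the onset. Only events of the requested class are
#' used - the primary analysis epochs correctly detected vibrations
#' (true positives); false-positive presses and misses can be epoched for
#' control analyses. Events too close to the recording edge are skipped
#' and counted.
#'
#' @param eeg preprocessed, re-referenced channel (matrix data, 250 Hz)
#' @param events data.frame with `onset` (s) and optionally `class` and
#'   `condition` columns
#' @param window epoch window in seconds, half-open
#' @param class_filter keep only events whose `class` matches (one of
#'   `"true_positive"`, `"false_positive"`, `"miss"`); `NULL` keeps all
#' @param baseline_correct subtract the pre-onset mean (default TRUE)
#' @return object of class `gw_epochs`: `data` (epochs x channels x time
#'   array), `times`, `rate`, `labels`, `meta` (per-epoch event info),
#'   `reject` (logical, filled by [reject_artifacts()]), `reject_reason`,
#'   `n_skipped_edge`
#' @export
epoch_eeg <- function(eeg, events, window = c(-0.2, 3.0),
                      class_filter = NULL, baseline_correct = TRUE) {
  x <- eeg$data
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  fs <- eeg$rate
  ev <- events
  if (!is.null(class_filter)) {
    if (!"class" %in% names(ev)) stop("events have no 'class' column")
    ev <- ev[ev$class %in% class_filter, , drop = FALSE]
  }
  n_pre <- round(-window[1] * fs)
  n_post <- round(window[2] * fs)
  len <- n_pre + n_post
  times <- (seq_len(len) - 1 - n_pre) / fs
  keep <- list(); meta <- NULL; skipped <- 0L
  for (i in seq_len(nrow(ev))) {
    i0 <- round(ev$onset[i] * fs) + 1L      # sample at t = 0
    a <- i0 - n_pre; b <- i0 + n_post - 1L
    if (a < 1 || b > nrow(x)) { skipped <- skipped + 1L; next }
    ep <- x[a:b, , drop = FALSE]
    if (baseline_correct) {
      bl <- colMeans(ep[seq_len(n_pre), , drop = FALSE])
      ep <- sweep(ep, 2, bl)
    }
    keep[[length(keep) + 1]] <- ep
    meta <- rbind(meta, ev[i, , drop = FALSE])
  }
  n_ep <- length(keep)
  arr <- array(0, dim = c(n_ep, ncol(x), len))
  for (e in seq_len(n_ep)) arr[e, , ] <- t(keep[[e]])
  structure(list(data = arr, times = times, rate = fs,
                 labels = colnames(x), meta = meta,
                 reject = rep(FALSE, n_ep),
                 reject_reason = rep(NA_character_, n_ep),
                 n_skipped_edge = skipped),
            class = "gw_epochs")
}

# rolling (max - min) over win-sample windows for each row of a
# channels x time matrix; returns channels x (time - win + 1)
rolling_range <- function(m, win) {
  nt <- ncol(m); k <- nt - win + 1L
  mx <- m[, 1:k, drop = FALSE]; mn <- mx
  for (s in 1:(win - 1L)) {
    sh <- m[, (1 + s):(k + s), drop = FALSE]
    mx <- pmax(mx, sh); mn <- pmin(mn, sh)
  }
  mx - mn
}

#' Threshold-based epoch artifact rejection
#'
#' Flags an epoch when any channel shows (a) a sample-to-sample step
#' larger than `step` muV, (b) a peak-to-peak range above `range` muV
#' within any sliding 200 ms window, or (c) a flat line - a range below
#' `flat` muV within any 200 ms window. Flagged epochs are excluded from
#' all averages; reasons are recorded as `step50`, `range200`,
#' `flatline` (first rule hit wins).
#'
#' @param epochs a `gw_epochs` object
#' @param step,range,flat thresholds in muV
#' @param window_s sliding window length (s)
#' @return the epochs object with `reject` / `reject_reason` filled
#' @export
reject_artifacts <- function(epochs, step = 50, range = 200, flat = 0.5,
                             window_s = 0.2) {
  win <- round(window_s * epochs$rate)
  n_ep <- dim(epochs$data)[1]
  for (e in seq_len(n_ep)) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (max(abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])) >
        step) {
      epochs$reject[e] <- TRUE; epochs$reject_reason[e] <- "step50"
      next
    }
    rr <- rolling_range(m, win)
    if (max(rr) > range) {
      epochs$reject[e] <- TRUE; epochs$reject_reason[e] <- "range200"
    } else if (min(rr) < flat) {
      epochs$reject[e] <- TRUE; epochs$reject_reason[e] <- "flatline"
    }
  }
  epochs
}

#' Average accepted epochs into an ERP
#'
#' Arithmetic mean and SEM over accepted (non-rejected) epochs. With a
#' single accepted epoch the SEM is 0 by convention.
#'
#' @param epochs `gw_epochs`
#' @return object of class `gw_erp`: `mean` and `sem` (channels x time
#'   matrices), `times`, `labels`, `n_epochs`
#' @export
average_erp <- function(epochs) {
  acc <- which(!epochs$reject)
  if (length(acc) == 0) stop("no accepted epochs to average")
  d <- epochs$data[acc, , , drop = FALSE]
  mu <- apply(d, c(2, 3), mean)
  sem <- if (length(acc) > 1)
    apply(d, c(2, 3), sd) / sqrt(length(acc))
  else mu * 0
  dimnames(mu) <- dimnames(sem) <- list(epochs$labels, NULL)
  structure(list(mean = mu, sem = sem, times = epochs$times,
                 labels = epochs$labels, n_epochs = length(acc)),
            class = "gw_erp")
}

#' Late positive potential metrics
#'
#' Amplitude: time-mean over the analysis window of the channel-mean
#' waveform across the posterior cluster channels. Latency: time of the
#' maximum of that waveform within the search window.
#'
#' @param erp `gw_erp`
#' @param window analysis window (s), default the 400-720 ms LPP window
#' @param channels channels to average, default [lpp_channels()]
#' @param latency_window search window for the peak, default = `window`
#' @return `list(amplitude, latency)` (muV, s)
#' @export
lpp_metrics <- function(erp, window = c(0.4, 0.72),
                        channels = lpp_channels(),
                        latency_window = window) {
  miss <- setdiff(channels, erp$labels)
  if (length(miss)) stop("channels not in ERP: ", paste(miss, collapse = ","))
  wave <- colMeans(erp$mean[channels, , drop = FALSE])
  sel <- erp$times >= window[1] & erp$times < window[2]
  lsel <- erp$times >= latency_window[1] & erp$times < latency_window[2]
  list(amplitude = mean(wave[sel]),
       latency = erp$times[lsel][which.max(wave[lsel])])
}

#' Classify vibration events against button presses for epoching
#'
#' Adds a `class` column (`true_positive` / `miss`) to vibration events
#' and appends the unmatched press onsets as `false_positive` events, so
#' that [epoch_eeg()] can select the epoch population.
#'
#' @param events vibration events (`onset`, `offset`, plus any metadata)
#' @param scored a [score_block()] result for the same block
#' @return events data.frame with `class` column
#' @export
classify_events <- function(events, scored) {
  ev <- events[order(events$onset), , drop = FALSE]
  ev$class <- ifelse(scored$per_event$hit, "true_positive", "miss")
  ev
}
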