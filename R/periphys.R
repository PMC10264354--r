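#' R-peak detection from the ECG channel
#'
#' Pan-Tompkins style detector: 5-25 Hz bandpass, squaring,
#' moving-window integration (150 ms), adaptive thresholding at a
#' fraction of the rolling signal level, a 250 ms refractory period, and
#' final refinement to the local maximum of the raw signal near each
#' candidate.
#'
#' @param ecg channel `list(data, rate)` at >= 250 Hz
#' @return numeric vector of R-peak times (s); empty for a flat channel
#' @export
detect_r_peaks <- function(ecg) {
  fs <- ecg$rate
  if (fs < 250) stop("ECG must be sampled at >= 250 Hz")
  x <- ecg$data
  if (sd(x) < 1e-12) return(numeric(0))
  bf <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  sq <- xf^2
  w <- round(0.15 * fs)
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.3 * quantile(integ, 0.99)
  if (thr <= 0) return(numeric(0))
  above <- integ > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(integ[seg])])
  }
  # refine to raw maximum within +-60 ms, then apply refractory
  half <- round(0.06 * fs)
  peaks <- vapply(cand, function(i) {
    a <- max(1, i - half); b <- min(length(x), i + half)
    as.integer(a + which.max(x[a:b]) - 1L)
  }, 0L)
  peaks <- sort(unique(peaks))
  refr <- round(0.25 * fs)
  keep <- logical(length(peaks)); last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= refr) { keep[i] <- TRUE; last <- peaks[i] }
    else if (x[peaks[i]] > x[last]) { # taller peak wins inside refractory
      keep[which(peaks == last)] <- FALSE
      keep[i] <- TRUE; last <- peaks[i]
    }
  }
  (peaks[keep] - 1) / fs
}

#' Interbeat-interval series with outlier masking
#'
#' IBIs are successive differences of the R-peak times (ms); an IBI is
#' masked when it deviates more than 25% from the rolling median
#' (11-beat window), the standard artifact family for normal-to-normal
#' interval cleaning. Masked IBIs are excluded from every downstream
#' statistic.
#'
#' @param r_peaks R-peak times (s)
#' @param tol fractional deviation from the rolling median (default 0.25)
#' @param window rolling window in beats (odd)
#' @return object of class `gw_ibi`: `r_peak_times`, `ibis` (ms),
#'   `t_ibi` (s, time of the later beat), `mask` (TRUE = outlier),
#'   `reason`
#' @export
clean_ibis <- function(r_peaks, tol = 0.25, window = 11) {
  if (length(r_peaks) < 3) stop("need at least 3 R peaks")
  ibis <- diff(r_peaks) * 1000
  n <- length(ibis)
  half <- floor(window / 2)
  med <- vapply(seq_len(n), function(i)
    median(ibis[max(1, i - half):min(n, i + half)]), 0)
  mask <- ibis < (1 - tol) * med | ibis > (1 + tol) * med
  structure(list(r_peak_times = r_peaks, ibis = ibis,
                 t_ibi = r_peaks[-1], mask = mask,
                 reason = ifelse(mask, "median25", NA_character_)),
            class = "gw_ibi")
}

ibi_clean_values <- function(series, span = NULL) {
  sel <- !series$mask
  if (!is.null(span))
    sel <- sel & series$t_ibi >= span[1] & series$t_ibi <= span[2]
  series$ibis[sel]
}

#' SDNN heart-rate variability
#'
#' Sample standard deviation (n-1 denominator) of the clean
#' normal-to-normal interbeat intervals in the span.
#'
#' @param series a [clean_ibis()] object
#' @param span optional `c(start, end)` seconds
#' @return SDNN in ms (NA with a message if fewer than 2 clean IBIs)
#' @export
sdnn <- function(series, span = NULL) {
  v <- ibi_clean_values(series, span)
  if (length(v) < 2) { message("sdnn: fewer than 2 clean IBIs"); return(NA_real_) }
  sd(v)
}

#' Relative LF/HF spectral power of the IBI tachogram
#'
#' The clean IBI series is interpolated onto an even 4 Hz grid (cubic
#' spline), linearly detrended, and its Hann-taper power integrated over
#' the low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz)
#' bands; each is reported as a fraction of (LF + HF).
#'
#' @param series a [clean_ibis()] object
#' @param span optional block span (s), must cover >= 120 s
#' @param resample_rate tachogram resampling rate (Hz)
#' @return `list(plf, phf)` fractions summing to 1
#' @export
plf_phf <- function(series, span = NULL, resample_rate = 4) {
  sel <- !series$mask
  if (!is.null(span))
    sel <- sel & series$t_ibi >= span[1] & series$t_ibi <= span[2]
  tt <- series$t_ibi[sel]; v <- series$ibis[sel]
  if (length(v) < 8 || diff(range(tt)) < 120) {
    message("plf_phf: need >= 120 s of clean IBIs")
    return(list(plf = NA_real_, phf = NA_real_))
  }
  g <- seq(min(tt), max(tt), by = 1 / resample_rate)
  y <- spline(tt, v, xout = g)$y
  y <- stats::resid(lm(y ~ g))
  sp <- hann_power(y, resample_rate)
  lf <- sum(sp$power[sp$freq >= 0.04 & sp$freq < 0.15])
  hf <- sum(sp$power[sp$freq >= 0.15 & sp$freq <= 0.4])
  tot <- lf + hf
  if (tot == 0) return(list(plf = NA_real_, phf = NA_real_))
  list(plf = lf / tot, phf = hf / tot)
}

#' Tonic heart rate over a block
#'
#' Mean over non-overlapping 60-s windows of the heart rate implied by
#' the clean IBIs in each window (60000 / mean IBI).
#'
#' @param series a [clean_ibis()] object
#' @param span block span `c(start, end)` (s), >= 60 s
#' @param window_s window length (s)
#' @return bpm
#' @export
tonic_hr <- function(series, span, window_s = 60) {
  if (diff(span) < window_s) stop("block shorter than one window")
  edges <- seq(span[1], span[2], by = window_s)
  if (length(edges) < 2) stop("block shorter than one window")
  vals <- numeric(0)
  for (k in seq_len(length(edges) - 1)) {
    v <- ibi_clean_values(series, c(edges[k], edges[k + 1]))
    if (length(v)) vals <- c(vals, 60000 / mean(v))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# instantaneous HR over [a, b) as 60 / (overlap-weighted mean IBI in s)
hr_in_window <- function(series, a, b) {
  t0 <- series$r_peak_times[-length(series$r_peak_times)]
  t1 <- series$r_peak_times[-1]
  ov <- pmin(t1, b) - pmax(t0, a)
  sel <- ov > 0 & !series$mask
  if (!any(sel)) return(NA_real_)
  w <- ov[sel]
  60 / (sum(w * (series$ibis[sel] / 1000)) / sum(w))
}

#' Phasic (event-locked) heart-rate responses
#'
#' For each event, the instantaneous HR during the 3-s stimulation window
#' minus the HR during the immediately preceding 3-s window, both
#' computed as overlap-weighted means of the clean IBIs. Events closer
#' than the window length to the span edges are skipped.
#'
#' @param series a [clean_ibis()] object
#' @param events data.frame with `onset` (s) and optionally `condition`
#' @param window_s stimulation/pre-stimulation window length (s)
#' @param span optional span for edge checking
#' @return data.frame `onset`, `delta` (bpm), `condition`
#' @export
phasic_hr <- function(series, events, window_s = 3, span = NULL) {
  out <- NULL
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    if (!is.null(span) && (on - window_s < span[1] ||
                           on + window_s > span[2])) next
    d <- hr_in_window(series, on, on + window_s) -
      hr_in_window(series, on - window_s, on)
    out <- rbind(out, data.frame(
      onset = on, delta = d,
      condition = if ("condition" %in% names(events))
        events$condition[i] else NA_character_))
  }
  out
}

#' Pseudo-events in the baseline block
#'
#' Sixty 3-s-spaced onsets starting 120 s into the baseline span (the
#' first two minutes are discarded to let physiology reach steady state),
#' providing a no-stimulation reference distribution for the phasic
#' measures.
#'
#' @param baseline_span `c(start, end)` of the baseline block (s)
#' @param n number of pseudo-events
#' @param spacing_s spacing between onsets (s)
#' @param skip_s settle-in period to skip (s)
#' @return data.frame `onset`, `offset`, `condition = "baseline"`,
#'   `kind = "pseudo"`
#' @export
make_pseudo_events <- function(baseline_span, n = 60, spacing_s = 3,
                               skip_s = 120) {
  onsets <- baseline_span[1] + skip_s + (seq_len(n) - 1) * spacing_s
  if (onsets[n] + spacing_s > baseline_span[2])
    stop("baseline span too short for ", n, " pseudo-events")
  data.frame(onset = onsets, offset = onsets + spacing_s,
             condition = "baseline", kind = "pseudo")
}

#' Breathing-rate estimation from the IBI tachogram
#'
#' Respiratory sinus arrhythmia imprints the breathing rhythm on the IBI
#' series. Per 60-s window: the clean tachogram is evenly resampled,
#' linearly detrended and autocorrelated; the first dominant positive-lag
#' peak whose rate lies in the 6-30 breaths/min physiological band - and
#' whose harmonic at twice the lag is also a local maximum - gives
#' BR = 60/lag. Block BR is the mean over qualifying windows; windows
#' without a qualifying peak are skipped.
#'
#' @param series a [clean_ibis()] object
#' @param span block span (s), >= 120 s
#' @param resample_rate tachogram grid (Hz)
#' @param min_peak_r minimum autocorrelation at the peak (default 0.25, above chance-level ripples of jitter-only tachograms)
#' @return breaths/min (NA when no window qualifies)
#' @export
estimate_br <- function(series, span, resample_rate = 4,
                        min_peak_r = 0.25) {
  if (diff(span) < 120) stop("block too short for BR estimation (< 120 s)")
  edges <- seq(span[1], span[2], by = 60)
  brs <- numeric(0)
  for (k in seq_len(length(edges) - 1)) {
    sel <- !series$mask & series$t_ibi >= edges[k] &
      series$t_ibi <= edges[k + 1]
    if (sum(sel) < 20) next
    tt <- series$t_ibi[sel]; v <- series$ibis[sel]
    g <- seq(min(tt), max(tt), by = 1 / resample_rate)
    if (length(g) < 40) next
    y <- spline(tt, v, xout = g)$y
    y <- stats::resid(lm(y ~ g))
    # below ~2 ms the tachogram is dominated by R-peak sampling
    # quantization, whose ripple is itself periodic; no usable RSA
    if (sd(y) < 2) next
    ac <- stats::acf(y, lag.max = length(y) - 1, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    lags <- (seq_along(ac) - 1) / resample_rate
    band <- which(lags >= 2 & lags <= 10)       # 6-30 breaths/min
    pk <- local_max(ac)
    cand <- intersect(band, pk)
    cand <- cand[ac[cand] >= min_peak_r]
    if (!length(cand)) next
    i <- cand[which.max(ac[cand])]
    # harmonic confirmation: a local max within 15% of twice the lag
    l2 <- 2 * lags[i]
    if (l2 <= max(lags)) {
      near <- pk[abs(lags[pk] - l2) <= 0.15 * l2]
      if (!length(near)) next
    }
    # parabolic interpolation refines the lag below grid resolution
    lag <- lags[i]
    if (i > 1 && i < length(ac)) {
      den <- ac[i - 1] - 2 * ac[i] + ac[i + 1]
      if (den < 0)
        lag <- lag + 0.5 * (ac[i - 1] - ac[i + 1]) / den / resample_rate
    }
    brs <- c(brs, 60 / lag)
  }
  if (!length(brs)) { message("estimate_br: no qualifying windows"); return(NA_real_) }
  mean(brs)
}

local_max <- function(x) {
  n <- length(x)
  which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
            x[2:(n - 1)] >= x[3:n], FALSE))
}

#' Phasic skin conductance responses by deconvolution
#'
#' Continuous-deconvolution quantification of event-locked electrodermal
#' activity: the SCR channel is downsampled to 20 Hz, smoothed with a
#' 200 ms moving average, detrended with a rolling-median (20 s) tonic
#' estimate, and deconvolved with the canonical bi-exponential impulse
#' response (rise 0.75 s, decay 2 s) via Tikhonov-regularized inverse
#' filtering; negative driver values are clipped to zero and the phasic
#' conductance is the non-negative driver reconvolved with the impulse
#' response (so it carries muS units). The per-event score is the maximum
#' phasic value in the `[onset, onset + 3 s)` window; values below the
#' 0.01 muS threshold are recorded as 0.
#'
#' @param scr channel `list(data, rate)` in muS
#' @param events data.frame with `onset` and optionally `condition`
#' @param irf_params `list(tau_rise, tau_decay)` (s)
#' @param lambda regularization weight relative to the IRF spectral peak
#' @param threshold reporting threshold (muS)
#' @param window_s response window (s), mirrors the 3-s stimulation period
#' @return `list(per_event = data.frame(onset, max_phasic, condition),
#'   phasic = driver series, rate)`
#' @export
phasic_scr <- function(scr, events,
                       irf_params = list(tau_rise = 0.75, tau_decay = 2),
                       lambda = 0.02, threshold = 0.01, window_s = 3) {
  if (any(!is.finite(scr$data))) stop("SCR channel contains non-finite samples")
  fs <- scr$rate; target <- 20
  x <- scr$data
  if (fs > target) {
    k <- floor(fs / target)
    lp <- signal::butter(4, (0.4 * target) / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, x)[seq(1, length(x), by = k)]
    fs <- fs / k
  }
  sm <- round(0.2 * fs)
  x <- as.numeric(stats::filter(x, rep(1 / sm, sm), sides = 2))
  x[is.na(x)] <- 0
  n <- length(x)
  # tonic level: rolling median over 20 s (robust to the ~3 s responses)
  k <- round(20 * fs); if (k %% 2 == 0) k <- k + 1L
  tonic <- stats::runmed(x, k, endrule = "median")
  xp <- x - tonic
  ht <- seq(0, 12, by = 1 / fs)
  h <- scr_irf(ht, irf_params$tau_rise, irf_params$tau_decay)
  hpad <- c(h, numeric(n - length(h)))
  H <- fft(hpad); X <- fft(xp)
  reg <- lambda * max(Mod(H)^2)
  drv <- Re(fft(Conj(H) * X / (Mod(H)^2 + reg), inverse = TRUE)) / n
  drv[drv < 0] <- 0
  phasic <- Re(fft(fft(drv) * H, inverse = TRUE)) / n
  out <- NULL
  for (i in seq_len(nrow(events))) {
    a <- floor(events$onset[i] * fs) + 1
    b <- min(n, floor((events$onset[i] + window_s) * fs))
    if (a >= b || a < 1) next
    m <- max(phasic[a:b])
    if (m < threshold) m <- 0
    out <- rbind(out, data.frame(
      onset = events$onset[i], max_phasic = m,
      condition = if ("condition" %in% names(events))
        events$condition[i] else NA_character_))
  }
  list(per_event = out, phasic = phasic, driver = drv, rate = fs)
}
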