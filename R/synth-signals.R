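# Signal-level generators shared by the session simulator. All of them are
# deterministic given the calling RNG state; simulate_* entry points that
# take an explicit seed set it themselves.

#' 1/f ("pink") noise
#'
#' Spectral synthesis: white Gaussian Fourier coefficients shaped by
#' f^(-alpha/2), inverse transformed and rescaled to the requested standard
#' deviation. alpha = 1 gives the canonical EEG-like background.
#'
#' @param n number of samples
#' @param rate sampling rate (Hz)
#' @param sd target standard deviation of the output
#' @param alpha spectral slope (power ~ 1/f^alpha)
#' @return numeric vector of length `n`
#' @export
noise_oneoverf <- function(n, rate, sd = 1, alpha = 1) {
  if (sd == 0) return(numeric(n))
  nf <- 2 * nextn(n, 2)
  f <- seq(0, rate / 2, length.out = nf / 2 + 1)
  shape <- c(0, f[-1]^(-alpha / 2))            # kill DC
  half <- complex(real = rnorm(nf / 2 + 1), imaginary = rnorm(nf / 2 + 1)) *
    shape
  half[1] <- 0
  half[nf / 2 + 1] <- complex(real = Re(half[nf / 2 + 1]), imaginary = 0)
  spec <- c(half, Conj(rev(half[2:(nf / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Late positive potential template
#'
#' Unit-peak waveform used to plant the gastric evoked potential: zero
#' before `onset`, half-sine rise from `onset` to the `peak` time, then
#' exponential decay with time constant `tau`, truncated at `offset`.
#' Defaults follow the observed morphology: deflection emerging around
#' 400 ms, peaking around 600 ms and lasting up to 3000 ms.
#'
#' @param times numeric vector of times (s) relative to stimulation onset
#' @param onset,peak,offset template support (s)
#' @param tau decay time constant (s)
#' @return numeric vector, unit peak
#' @export
lpp_template <- function(times, onset = 0.4, peak = 0.6, offset = 3.0,
                         tau = 0.8) {
  stopifnot(peak > onset, offset > onset, tau > 0)
  y <- numeric(length(times))
  rise <- times >= onset & times < peak
  y[rise] <- sin(pi / 2 * (times[rise] - onset) / (peak - onset))
  dec <- times >= peak & times < offset
  y[dec] <- exp(-(times[dec] - peak) / tau)
  y
}

#' Synthetic electrocardiogram
#'
#' R-peak times are generated by iterating interbeat intervals
#' `60 / hr(t) + rsa * sin(2 pi br/60 t)`, i.e. a (possibly time-varying)
#' tonic heart-rate profile modulated sinusoidally at the breathing rate
#' (respiratory sinus arrhythmia). A stylized PQRST-free waveform (narrow
#' Gaussian R wave + broader T wave) is rendered at `rate`.
#'
#' @param hr_profile beats/min: a single number or a `function(t)`
#' @param rsa_depth peak RSA modulation of the IBI, in ms
#' @param br breathing rate, breaths/min (must lie in 6..30)
#' @param rate output sampling rate (Hz)
#' @param duration seconds
#' @param noise_sd additive white noise (mV)
#' @return `list(data, rate, units = "mV", r_peaks)` where `r_peaks` are the
#'   ground-truth R-wave times in seconds
#' @export
simulate_ecg <- function(hr_profile, rsa_depth = 40, br = 15, rate = 1000,
                         duration = 300, noise_sd = 0.02) {
  stopifnot(br >= 6, br <= 30, duration > 0)
  hr <- if (is.function(hr_profile)) hr_profile else function(t) hr_profile
  t <- 0.5
  peaks <- numeric(0)
  while (t < duration - 0.5) {
    h <- hr(t)
    if (!is.finite(h) || h <= 0) stop("hr_profile must be positive")
    ibi <- 60 / h + rsa_depth / 1000 * sin(2 * pi * br / 60 * t)
    if (ibi <= 0.2)
      stop("rsa_depth produces non-physiological interbeat intervals")
    peaks <- c(peaks, t)
    t <- t + ibi
  }
  n <- round(duration * rate)
  x <- numeric(n)
  # templates: R wave (12 ms sd, 1 mV), T wave (60 ms sd, 0.15 mV at +250 ms)
  span_r <- round(0.05 * rate); span_t <- round(0.2 * rate)
  for (p in peaks) {
    i0 <- round(p * rate) + 1
    idx <- max(1, i0 - span_r):min(n, i0 + span_r)
    x[idx] <- x[idx] + exp(-((idx - i0) / rate)^2 / (2 * 0.012^2))
    it <- round((p + 0.25) * rate) + 1
    idx <- max(1, it - span_t):min(n, it + span_t)
    x[idx] <- x[idx] + 0.15 * exp(-((idx - it) / rate)^2 / (2 * 0.06^2))
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  list(data = x, rate = rate, units = "mV", r_peaks = peaks)
}

#' Bi-exponential skin conductance impulse response
#'
#' Unit-peak difference of exponentials, the canonical electrodermal
#' response shape used both to plant and to deconvolve phasic activity.
#'
#' @param times nonnegative times (s)
#' @param tau_rise,tau_decay time constants (s); both must be positive and
#'   `tau_decay > tau_rise`
#' @export
scr_irf <- function(times, tau_rise = 0.75, tau_decay = 2) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be positive")
  if (tau_decay <= tau_rise) stop("tau_decay must exceed tau_rise")
  h <- exp(-times / tau_decay) - exp(-times / tau_rise)
  h[times < 0] <- 0
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  h / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

#' Synthetic skin conductance channel
#'
#' Tonic drift plus driver impulses convolved with the bi-exponential
#' impulse response, plus white noise.
#'
#' @param driver_times impulse times (s)
#' @param driver_amps impulse amplitudes (muS), all >= 0
#' @param irf_params `list(tau_rise=, tau_decay=)` in seconds
#' @param drift tonic level: a number or `function(t)` (muS)
#' @param rate sampling rate (Hz)
#' @param duration seconds
#' @param noise_sd additive white noise (muS)
#' @return `list(data, rate, units = "muS")`
#' @export
simulate_scr <- function(driver_times, driver_amps,
                         irf_params = list(tau_rise = 0.75, tau_decay = 2),
                         drift = 2, rate = 1000, duration = 300,
                         noise_sd = 0.005) {
  if (length(driver_times) != length(driver_amps))
    stop("driver_times and driver_amps must have equal length")
  if (any(driver_amps < 0)) stop("driver amplitudes must be >= 0")
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  base <- if (is.function(drift)) drift(tt) else rep(drift, n)
  x <- base
  if (length(driver_times)) {
    ht <- seq(0, 12, by = 1 / rate)       # 12 s support covers the decay
    h <- scr_irf(ht, irf_params$tau_rise, irf_params$tau_decay)
    for (k in seq_along(driver_times)) {
      i0 <- round(driver_times[k] * rate) + 1
      idx <- i0:min(n, i0 + length(h) - 1)
      if (i0 <= n)
        x[idx] <- x[idx] + driver_amps[k] * h[seq_along(idx)]
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  list(data = x, rate = rate, units = "muS")
}
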