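#' Double-gamma haemodynamic response function
#'
#' Canonical double-gamma HRF: a positive gamma density peaking at `peak_s`
#' minus a scaled gamma density peaking at `undershoot_s`. The kernel is
#' sampled at `dt` and normalised to unit sum, so convolving a sustained
#' (boxcar) neural state of amplitude 1 yields a plateau of 1.
#'
#' @param dt sampling interval in seconds (typically the TR).
#' @param peak_s time-to-peak of the response (default 6 s).
#' @param undershoot_s time-to-peak of the undershoot (default 16 s).
#' @param dispersion_peak,dispersion_undershoot gamma dispersions (default 1).
#' @param ratio peak-to-undershoot amplitude ratio (default 6).
#' @param length_s kernel duration in seconds (default 32 s).
#' @return numeric vector of kernel weights summing to 1.
#' @export
double_gamma_hrf <- function(dt = 1.5, peak_s = 6, undershoot_s = 16,
                             dispersion_peak = 1, dispersion_undershoot = 1,
                             ratio = 6, length_s = 32) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak_s / dispersion_peak, scale = dispersion_peak) -
    stats::dgamma(t, shape = undershoot_s / dispersion_undershoot,
                  scale = dispersion_undershoot) / ratio
  h / sum(h)
}

# causal convolution of a time series with a kernel, truncated to the input length
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out
}

# analytic-signal amplitude (envelope) via FFT Hilbert transform
analytic_amplitude <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for an analytic amplitude")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}
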