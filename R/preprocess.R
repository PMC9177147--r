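#' Discard initial volumes of a run
#'
#' The first five volumes of encoding runs and the first three volumes of
#' recall runs are excluded from analyses. Event times are unchanged (the run
#' clock is preserved); `trim_offset_s` records the discarded span so that
#' window arithmetic stays correct.
#'
#' @param run a [run_data] object.
#' @param n_volumes number of initial volumes to drop; default 5 for encoding
#'   runs and 3 for recall runs.
#' @return the trimmed [run_data].
#' @export
trim_initial_volumes <- function(run, n_volumes = NULL) {
  if (isTRUE(run$trimmed)) stop("run has already been trimmed (trim_offset_s > 0)")
  if (is.null(n_volumes)) n_volumes <- if (run$phase == "encoding") 5L else 3L
  if (ncol(run$data) <= n_volumes) {
    stop("run has only ", ncol(run$data), " TRs; cannot trim ", n_volumes)
  }
  run$data <- run$data[, -seq_len(n_volumes), drop = FALSE]
  run$trim_offset_s <- run$trim_offset_s + n_volumes * run$tr_s
  run$trimmed <- TRUE
  run
}

#' High-pass filter a run by discrete-cosine basis regression
#'
#' Removes slow drifts by regressing out a DCT basis containing all
#' frequencies up to `1 / cutoff_s` (plus the constant term), per vertex.
#' The output is orthogonal to the removed basis.
#'
#' @param run a [run_data] object.
#' @param cutoff_s high-pass cutoff period in seconds (default 140).
#' @return the filtered [run_data].
#' @export
highpass_dct <- function(run, cutoff_s = 140) {
  if (cutoff_s <= 2 * run$tr_s) stop("cutoff_s must exceed 2 * tr_s")
  n <- ncol(run$data)
  if (n < 8L) stop("run too short to filter (n_trs < 8)")
  j_max <- floor(2 * n * run$tr_s / cutoff_s)
  k <- seq_len(n) - 0.5
  basis <- matrix(1 / sqrt(n), n, 1)
  if (j_max >= 1L) {
    basis <- cbind(basis, sapply(seq_len(j_max), function(j) cos(pi * k * j / n)))
  }
  q <- qr.Q(qr(basis))
  run$data <- run$data - (run$data %*% q) %*% t(q)
  run
}

#' z-score each vertex's time series within a run
#'
#' @param run a [run_data] object; every vertex must have nonzero temporal SD.
#' @return the normalised [run_data] (per-vertex mean 0, SD 1).
#' @export
zscore_run <- function(run) {
  mu <- rowMeans(run$data)
  sdv <- sqrt(rowSums((run$data - mu)^2) / (ncol(run$data) - 1))
  zero <- which(sdv == 0)
  if (length(zero) > 0L) {
    stop("zero-variance vertex(es): ", paste(utils::head(zero, 10), collapse = ", "))
  }
  run$data <- (run$data - mu) / sdv
  run
}

#' Standard preprocessing for one run
#'
#' Trim initial volumes, high-pass filter (140 s cutoff), and z-score, in
#' that order.
#'
#' @param run a [run_data] object.
#' @param cutoff_s high-pass cutoff period in seconds.
#' @param trim whether to trim initial volumes first.
#' @return the preprocessed [run_data].
#' @export
preprocess_run <- function(run, cutoff_s = 140, trim = TRUE) {
  if (trim) run <- trim_initial_volumes(run)
  zscore_run(highpass_dct(run, cutoff_s = cutoff_s))
}

#' Preprocess every run of an experiment
#'
#' @param experiment a `boundary_experiment` (see [generate_experiment]).
#' @param cutoff_s high-pass cutoff period in seconds.
#' @return the experiment with all runs trimmed, filtered, and z-scored.
#' @export
preprocess_experiment <- function(experiment, cutoff_s = 140) {
  for (i in seq_along(experiment$runs)) {
    experiment$runs[[i]] <- preprocess_run(experiment$runs[[i]], cutoff_s = cutoff_s)
  }
  experiment$preprocessed <- TRUE
  experiment
}

#' Audio-amplitude regressor for an encoding run
#'
#' Builds the per-TR audio amplitude regressor used by the silence controls:
#' take the amplitude of the analytic signal (Hilbert transform) of the audio
#' waveform, average it within each TR bin, convolve with the double-gamma
#' HRF, and z-score across time points. A precomputed per-TR envelope may be
#' supplied instead of a waveform, in which case binning is skipped; if the
#' envelope was computed for the untrimmed run, the leading trimmed entries
#' are dropped first.
#'
#' @param x audio waveform (with `sr`) or per-TR amplitude envelope.
#' @param run the [run_data] the regressor must align with.
#' @param sr sampling rate of the waveform in Hz (required for waveforms;
#'   `NULL` means `x` is already a per-TR envelope). The waveform's sample 1
#'   is taken to coincide with run-clock time 0.
#' @param hrf HRF kernel sampled at the TR (default [double_gamma_hrf]).
#' @param zscore whether to z-score the convolved regressor (default TRUE).
#' @return numeric vector of length `ncol(run$data)`.
#' @export
audio_envelope_regressor <- function(x, run, sr = NULL,
                                     hrf = double_gamma_hrf(dt = run$tr_s),
                                     zscore = TRUE) {
  n <- ncol(run$data)
  if (!is.null(sr)) {
    if (sr <= 0) stop("sampling rate must be positive")
    amp <- analytic_amplitude(x)
    env <- vapply(seq_len(n), function(k) {
      t0 <- run$trim_offset_s + (k - 1) * run$tr_s
      i0 <- floor(t0 * sr) + 1
      i1 <- min(floor((t0 + run$tr_s) * sr), length(amp))
      if (i0 > length(amp)) return(0)
      mean(amp[i0:i1])
    }, numeric(1))
  } else {
    env <- as.numeric(x)
    if (length(env) > n) env <- env[-seq_len(length(env) - n)]
    if (length(env) != n) {
      stop("envelope length (", length(env), ") shorter than run TR count (", n, ")")
    }
  }
  reg <- convolve_hrf(env, hrf)
  if (zscore) {
    s <- stats::sd(reg)
    if (s == 0) stop("audio regressor has zero variance; cannot z-score")
    reg <- (reg - mean(reg)) / s
  }
  reg
}
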