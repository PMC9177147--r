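#' Time-locked pattern time series around movie onsets or offsets
#'
#' Extracts, for one subject, the time series of spatial activation patterns
#' from `from_s` before to `to_s` after the onset or offset of each movie
#' (watched or recalled), then averages across movies per grid point. Times
#' are true stimulus/behaviour times: no haemodynamic shift is applied, so
#' the HRF lag is visible in the dynamics. Grid points falling outside a
#' movie's run are skipped for that movie and `valid_counts` records how many
#' movies contributed.
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param subject subject id.
#' @param lock `"onset"` or `"offset"`.
#' @param phase `"encoding"` or `"recall"`.
#' @param region optional parcel labels; `vertices` overrides.
#' @param vertices optional vertex indices.
#' @param from_s,to_s grid bounds in seconds relative to the locking event
#'   (defaults -30 and +60; 61 grid points at TR 1.5 s).
#' @return list of class `"timelocked_series"` with `times_s`, `patterns`
#'   (vertices x grid matrix, NA columns where no movie contributed),
#'   `valid_counts`, `lock`, `phase`, `subject`.
#' @export
timelocked_pattern_series <- function(experiment, subject,
                                      lock = c("offset", "onset"),
                                      phase = c("recall", "encoding"),
                                      region = NULL, vertices = NULL,
                                      from_s = -30, to_s = 60) {
  lock <- match.arg(lock)
  phase <- match.arg(phase)
  run1 <- experiment$runs[[1]]
  if (is.null(vertices)) {
    vertices <- if (is.null(region)) seq_len(nrow(run1$data)) else parcel_vertices(run1, region)
  }
  tr <- run1$tr_s
  times <- seq(from_s, to_s, by = tr)
  ev <- subject_events(experiment$events, subject, phase)
  mv <- ev[ev$kind == "movie", , drop = FALSE]
  if (nrow(mv) == 0L) stop("no movies for subject ", subject, " in phase ", phase)
  acc <- matrix(0, length(vertices), length(times))
  counts <- integer(length(times))
  for (i in seq_len(nrow(mv))) {
    run <- get_run(experiment, subject, phase, mv$run[i])
    anchor <- if (lock == "onset") mv$onset_s[i] else mv$offset_s[i]
    for (gi in seq_along(times)) {
      trs <- seconds_to_tr_range(anchor + times[gi], anchor + times[gi] + tr, run)
      if (length(trs) == 0L) next
      acc[, gi] <- acc[, gi] + run$data[vertices, trs[1]]
      counts[gi] <- counts[gi] + 1L
    }
  }
  patterns <- sweep(acc, 2, counts, "/")
  patterns[, counts == 0L] <- NA_real_
  structure(list(times_s = times, patterns = patterns, valid_counts = counts,
                 lock = lock, phase = phase, subject = subject, vertices = vertices),
            class = "timelocked_series")
}

#' Time-time pattern correlation matrix
#'
#' Cell (i, j) is the Pearson correlation between the pattern of `series_a`
#' at grid time i and the pattern of `series_b` at grid time j. Cells
#' involving invalid grid points are NA.
#'
#' @param series_a,series_b [timelocked_pattern_series] results over the same
#'   vertex set.
#' @return numeric grid x grid matrix with time labels.
#' @export
timetime_matrix <- function(series_a, series_b = series_a) {
  if (nrow(series_a$patterns) != nrow(series_b$patterns)) {
    stop("series have different vertex dimensions")
  }
  M <- suppressWarnings(stats::cor(series_a$patterns, series_b$patterns))
  dimnames(M) <- list(series_a$times_s, series_b$times_s)
  M
}

#' Group significance mask for time-time matrices
#'
#' Two-tailed one-sample t-test against zero per cell across subjects,
#' Bonferroni-corrected over all testable cells (cells that are finite for
#' every subject; the full 61 x 61 grid gives a denominator of 3721).
#'
#' @param matrices list of per-subject [timetime_matrix] results.
#' @param alpha family-wise error level (default 0.05).
#' @return logical matrix (untestable cells FALSE) with attributes `t`, `p`,
#'   `n_tested`.
#' @export
group_timetime_significance <- function(matrices, alpha = 0.05) {
  n <- length(matrices)
  if (n < 2L) stop("need >= 2 subjects")
  arr <- simplify2array(matrices)            # grid x grid x subjects
  testable <- apply(is.finite(arr), c(1, 2), all)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  t_stat <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  m <- sum(testable)
  if (m == 0L) stop("no testable cells")
  mask <- testable & is.finite(p) & (p < alpha / m)
  dimnames(mask) <- dimnames(matrices[[1]])
  structure(mask, t = t_stat, p = p, n_tested = m)
}
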