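#' Ground-truth configuration for a synthetic experiment
#'
#' Describes a complete synthetic movie-encoding / free-recall experiment:
#' 15 subjects watch 10 movies (2.15-7.75 min, each preceded by a 6-s silent
#' title scene) across 2 encoding runs, then freely recall them in one run in
#' a subject-chosen order with lognormal inter-movie pauses (mean 9.3 s,
#' SD 16.8 s, truncated at `pause_max_s`). Latent spatial patterns are planted
#' in disjoint parcel sets: a shared between-movie boundary pattern active for
#' `boundary_dwell_s` after every movie offset (both phases), per-movie
#' content patterns (subject-specific), a within-movie event-boundary pattern
#' whose correlation with the boundary pattern is `corr_event_boundary`, and a
#' silence-locked pattern in auditory-like parcels active whenever the audio
#' envelope is silent (titles, planted within-movie dips, recall pauses).
#' Latent states are convolved with a double-gamma HRF, white noise is added,
#' and each run is z-scored per vertex.
#'
#' Amplitudes are per-vertex RMS signal strengths in z units, so
#' `amp_boundary / noise_sd` is the planted signal-to-noise ratio.
#'
#' @param n_subjects number of subjects (default 15).
#' @param n_parcels number of cortical parcels (default 40).
#' @param vertices_per_parcel vertices per parcel (default 20).
#' @param movie_durations_s the 10 movie durations in seconds.
#' @param title_s title-scene duration (6 s).
#' @param tr_s repetition time (1.5 s).
#' @param stim_lead_s encoding stimulus onset relative to the first volume (3 s).
#' @param recall_lead_s start of the first recalled movie on the recall run clock.
#' @param run_end_pad_s silent padding after the last movie of each run.
#' @param recall_frac_range range of the per-movie recall-duration fraction
#'   (recall is compressed relative to viewing).
#' @param pause_mean_s,pause_sd_s,pause_max_s recall pause distribution
#'   (lognormal matched to the mean/SD, truncated to `[0, pause_max_s]`).
#' @param amp_boundary,amp_content,amp_event,amp_silence_aud signal amplitudes
#'   (z units; all >= 0).
#' @param corr_event_boundary target Pearson correlation between the
#'   within-movie event pattern and the between-movie boundary pattern.
#' @param noise_sd white-noise SD.
#' @param boundary_parcels,aud_parcels disjoint parcel label sets carrying the
#'   boundary/event effects and the silence effect respectively.
#' @param boundary_dwell_s duration of the latent boundary state (15 s).
#' @param event_boundary_fracs list of within-movie boundary positions as
#'   fractions of each movie's duration (encoding only). The default plants 17
#'   boundaries of which 15 survive the 45-s exclusion rule.
#' @param dip_frac,dip_s position (fraction of duration) and length of the
#'   planted silent audio dip inside each movie.
#' @param hrf_params named list passed to [double_gamma_hrf].
#' @param seed master RNG seed; all randomness derives from it.
#' @return list of class `"ground_truth_config"`.
#' @export
ground_truth_config <- function(n_subjects = 15,
                                n_parcels = 40,
                                vertices_per_parcel = 20,
                                movie_durations_s = round(seq(129, 465, length.out = 10), 1),
                                title_s = 6,
                                tr_s = 1.5,
                                stim_lead_s = 3,
                                recall_lead_s = 15,
                                run_end_pad_s = 24,
                                recall_frac_range = c(0.3, 0.5),
                                pause_mean_s = 9.3,
                                pause_sd_s = 16.8,
                                pause_max_s = 60,
                                amp_boundary = 0.5,
                                amp_content = 0.5,
                                amp_event = 0.5,
                                amp_silence_aud = 0.5,
                                corr_event_boundary = -0.3,
                                noise_sd = 1,
                                boundary_parcels = 1:4,
                                aud_parcels = 5:6,
                                boundary_dwell_s = 15,
                                event_boundary_fracs = NULL,
                                dip_frac = 0.9,
                                dip_s = 9,
                                hrf_params = list(),
                                seed = 1) {
  if (length(movie_durations_s) != 10L) stop("exactly 10 movie durations are required")
  if (any(movie_durations_s <= 0)) stop("movie durations must be positive")
  amps <- c(amp_boundary, amp_content, amp_event, amp_silence_aud)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (abs(corr_event_boundary) > 1) stop("|corr_event_boundary| must be <= 1")
  if (length(intersect(boundary_parcels, aud_parcels)) > 0L) {
    stop("boundary_parcels and aud_parcels must be disjoint")
  }
  if (any(c(boundary_parcels, aud_parcels) > n_parcels)) {
    stop("planted parcel labels exceed n_parcels")
  }
  if (is.null(event_boundary_fracs)) {
    event_boundary_fracs <- c(lapply(1:7, function(i) c(0.25, 0.7)),
                              lapply(8:10, function(i) 0.7))
  }
  if (length(event_boundary_fracs) != 10L) {
    stop("event_boundary_fracs must list positions for all 10 movies")
  }
  structure(
    list(n_subjects = n_subjects, n_parcels = n_parcels,
         vertices_per_parcel = vertices_per_parcel,
         movie_durations_s = movie_durations_s, title_s = title_s, tr_s = tr_s,
         stim_lead_s = stim_lead_s, recall_lead_s = recall_lead_s,
         run_end_pad_s = run_end_pad_s, recall_frac_range = recall_frac_range,
         pause_mean_s = pause_mean_s, pause_sd_s = pause_sd_s,
         pause_max_s = pause_max_s,
         amp_boundary = amp_boundary, amp_content = amp_content,
         amp_event = amp_event, amp_silence_aud = amp_silence_aud,
         corr_event_boundary = corr_event_boundary, noise_sd = noise_sd,
         boundary_parcels = as.integer(boundary_parcels),
         aud_parcels = as.integer(aud_parcels),
         boundary_dwell_s = boundary_dwell_s,
         event_boundary_fracs = event_boundary_fracs,
         dip_frac = dip_frac, dip_s = dip_s, hrf_params = hrf_params,
         seed = as.integer(seed)),
    class = "ground_truth_config"
  )
}

unit_norm <- function(x) x / sqrt(sum(x^2))

# unit-norm vector with exact (centred) Pearson correlation rho to p
correlated_pattern <- function(p, rho) {
  pc <- p - mean(p)
  pc <- unit_norm(pc)
  g <- stats::rnorm(length(p))
  g <- g - mean(g)
  g <- g - sum(g * pc) * pc
  g <- unit_norm(g)
  unit_norm(rho * pc + sqrt(1 - rho^2) * g)
}

# truncated-lognormal recall pauses matched to the target mean/SD scale
draw_pauses <- function(n, mean_s, sd_s, max_s) {
  sigma2 <- log(1 + (sd_s / mean_s)^2)
  mu <- log(mean_s) - sigma2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, mu, sqrt(sigma2))
    out <- c(out, x[x <= max_s])
  }
  out[seq_len(n)]
}

run_id <- function(subject, phase, run) sprintf("%s_%s%d", subject, phase, run)

# encoding timeline shared by all subjects: two runs of five movies each
encoding_timeline <- function(config) {
  runs <- list()
  for (r in 1:2) {
    movies <- if (r == 1) 1:5 else 6:10
    t <- config$stim_lead_s
    rows <- list()
    for (m in movies) {
      d <- config$movie_durations_s[m]
      rows[[length(rows) + 1]] <- data.frame(
        run = r, movie_id = m, kind = "title", onset_s = t, offset_s = t + config$title_s)
      on <- t + config$title_s
      rows[[length(rows) + 1]] <- data.frame(
        run = r, movie_id = m, kind = "movie", onset_s = on, offset_s = on + d)
      for (f in config$event_boundary_fracs[[m]]) {
        rows[[length(rows) + 1]] <- data.frame(
          run = r, movie_id = m, kind = "within_event_boundary",
          onset_s = on + f * d, offset_s = NA_real_)
      }
      t <- on + d
    }
    ev <- do.call(rbind, rows)
    n_trs <- ceiling((max(ev$offset_s, na.rm = TRUE) + config$run_end_pad_s) / config$tr_s)
    runs[[r]] <- list(events = ev, n_trs = as.integer(n_trs))
  }
  runs
}

# recall timeline for one subject (single run, subject-chosen order, pauses)
recall_timeline <- function(config, order, fracs, pauses) {
  t <- config$recall_lead_s
  rows <- list()
  for (i in seq_along(order)) {
    m <- order[i]
    d <- fracs[i] * config$movie_durations_s[m]
    rows[[length(rows) + 1]] <- data.frame(
      run = 1L, movie_id = m, kind = "movie", onset_s = t, offset_s = t + d)
    t <- t + d
    if (i < length(order)) {
      rows[[length(rows) + 1]] <- data.frame(
        run = 1L, movie_id = NA_integer_, kind = "pause",
        onset_s = t, offset_s = t + pauses[i])
      t <- t + pauses[i]
    }
  }
  ev <- do.call(rbind, rows)
  n_trs <- ceiling((t + config$run_end_pad_s) / config$tr_s)
  list(events = ev, n_trs = as.integer(n_trs))
}

#' Per-TR audio amplitude envelope for an encoding run
#'
#' The envelope is 0 during the pre-stimulus lead, title scenes, and run-end
#' padding, and 1 during movies, except for one planted silent dip per movie
#' (position `dip_frac` of the movie duration, length `dip_s`). A TR takes the
#' amplitude at its acquisition onset.
#'
#' @param config a [ground_truth_config].
#' @param events event rows of one encoding run (columns `movie_id`, `kind`,
#'   `onset_s`, `offset_s`).
#' @param n_trs number of TRs of the (untrimmed) run.
#' @return numeric vector of length `n_trs` (all values >= 0).
#' @export
generate_audio_envelope <- function(config, events, n_trs) {
  t_on <- (seq_len(n_trs) - 1) * config$tr_s
  env <- numeric(n_trs)
  mv <- events[events$kind == "movie", , drop = FALSE]
  for (i in seq_len(nrow(mv))) {
    inside <- t_on >= mv$onset_s[i] & t_on < mv$offset_s[i]
    env[inside] <- 1
    d <- mv$offset_s[i] - mv$onset_s[i]
    dip0 <- mv$onset_s[i] + config$dip_frac * d
    dip1 <- min(dip0 + config$dip_s, mv$offset_s[i])
    env[t_on >= dip0 & t_on < dip1] <- 0
  }
  env
}

# indicator time course (per TR onset) for a union of [start, end) intervals
interval_indicator <- function(starts, ends, n_trs, tr_s) {
  t_on <- (seq_len(n_trs) - 1) * tr_s
  ind <- numeric(n_trs)
  for (i in seq_along(starts)) ind[t_on >= starts[i] & t_on < ends[i]] <- 1
  ind
}

#' Generate a complete synthetic experiment
#'
#' Builds timelines, plants latent spatial patterns, convolves the latent
#' state time courses with the HRF, adds white noise, and z-scores each run
#' per vertex (skipped when `noise_sd = 0`, where constant vertices would be
#' degenerate). Regenerating with the same config yields bit-identical output.
#'
#' @param config a [ground_truth_config].
#' @return list of class `"boundary_experiment"` with fields `runs` (named
#'   list of [run_data], untrimmed), `events` ([event_table] for all
#'   subjects), `envelopes` (raw per-TR audio envelope per encoding run),
#'   `truth` (planted patterns, parcel/ROI sets, per-run latent designs), and
#'   `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "ground_truth_config"))
  set.seed(config$seed)
  V <- config$n_parcels * config$vertices_per_parcel
  vertex_parcel <- rep(seq_len(config$n_parcels), each = config$vertices_per_parcel)
  bound_v <- which(vertex_parcel %in% config$boundary_parcels)
  aud_v <- which(vertex_parcel %in% config$aud_parcels)
  hrf <- do.call(double_gamma_hrf, c(list(dt = config$tr_s), config$hrf_params))

  # shared (group-consistent) patterns; zero off their carrier vertices
  embed <- function(v, idx) { out <- numeric(V); out[idx] <- v; out }
  p_bound_c <- unit_norm(stats::rnorm(length(bound_v)))
  p_evt_c <- correlated_pattern(p_bound_c, config$corr_event_boundary)
  p_sil_c <- unit_norm(stats::rnorm(length(aud_v)))
  truth <- list(
    p_bound = embed(p_bound_c, bound_v),
    p_evt = embed(p_evt_c, bound_v),
    p_sil = embed(p_sil_c, aud_v),
    realized_corr_event_boundary = stats::cor(p_bound_c, p_evt_c),
    roi = list(boundary = config$boundary_parcels, aud = config$aud_parcels,
               null = setdiff(seq_len(config$n_parcels),
                              c(config$boundary_parcels, config$aud_parcels))),
    content = list(), design = list())

  # weighted pattern columns: amp is per-vertex RMS within the carrier
  col_bound <- config$amp_boundary * sqrt(length(bound_v)) * truth$p_bound
  col_evt <- config$amp_event * sqrt(length(bound_v)) * truth$p_evt
  col_sil <- config$amp_silence_aud * sqrt(length(aud_v)) * truth$p_sil

  enc <- encoding_timeline(config)
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  runs <- list()
  envelopes <- list()
  all_events <- list()

  build_run <- function(subject, phase, r, ev, n_trs, content_cols, envelope) {
    mv <- ev[ev$kind == "movie", , drop = FALSE]
    design <- list()
    cols <- list()
    design$bound <- interval_indicator(mv$offset_s, mv$offset_s + config$boundary_dwell_s,
                                       n_trs, config$tr_s)
    cols$bound <- col_bound
    if (phase == "encoding") {
      wb <- ev[ev$kind == "within_event_boundary", , drop = FALSE]
      if (nrow(wb) > 0L) {
        design$evt <- interval_indicator(wb$onset_s, wb$onset_s + config$boundary_dwell_s,
                                         n_trs, config$tr_s)
        cols$evt <- col_evt
      }
      design$sil <- as.numeric(envelope == 0)
    } else {
      # silence during recall = lead, pauses, and post-recall padding
      design$sil <- 1 - interval_indicator(mv$onset_s, mv$offset_s, n_trs, config$tr_s)
    }
    cols$sil <- col_sil
    for (m in mv$movie_id) {
      key <- paste0("content_", m)
      design[[key]] <- interval_indicator(mv$onset_s[mv$movie_id == m],
                                          mv$offset_s[mv$movie_id == m],
                                          n_trs, config$tr_s)
      cols[[key]] <- content_cols[, m]
    }
    D <- do.call(rbind, lapply(design, convolve_hrf, kernel = hrf))
    P <- do.call(cbind, cols[names(design)])
    X <- P %*% D + matrix(stats::rnorm(V * n_trs, sd = config$noise_sd), V, n_trs)
    if (config$noise_sd > 0) {
      mu <- rowMeans(X)
      X <- (X - mu) / sqrt(rowSums((X - mu)^2) / (n_trs - 1))
    }
    list(run = run_data(X, subject = subject, phase = phase, run = r,
                        tr_s = config$tr_s, vertex_parcel = vertex_parcel,
                        vertex_area_mm2 = rep(2.2, V)),
         design = D)
  }

  for (s in subjects) {
    order_s <- sample.int(10)
    fracs <- stats::runif(10, config$recall_frac_range[1], config$recall_frac_range[2])
    pauses <- draw_pauses(9, config$pause_mean_s, config$pause_sd_s, config$pause_max_s)
    content_s <- config$amp_content * sqrt(V) *
      apply(matrix(stats::rnorm(V * 10), V, 10), 2, unit_norm)
    truth$content[[s]] <- content_s
    for (r in 1:2) {
      id <- run_id(s, "encoding", r)
      envelope <- generate_audio_envelope(config, enc[[r]]$events, enc[[r]]$n_trs)
      built <- build_run(s, "encoding", r, enc[[r]]$events, enc[[r]]$n_trs,
                         content_s, envelope)
      runs[[id]] <- built$run
      truth$design[[id]] <- built$design
      envelopes[[id]] <- envelope
      all_events[[id]] <- cbind(subject = s, phase = "encoding", enc[[r]]$events)
    }
    rec <- recall_timeline(config, order_s, fracs, pauses)
    id <- run_id(s, "recall", 1)
    built <- build_run(s, "recall", 1L, rec$events, rec$n_trs, content_s, NULL)
    runs[[id]] <- built$run
    truth$design[[id]] <- built$design
    all_events[[id]] <- cbind(subject = s, phase = "recall", rec$events)
  }

  events <- event_table(do.call(rbind, all_events))
  rownames(events) <- NULL
  structure(list(runs = runs, events = events, envelopes = envelopes,
                 truth = truth, config = config, preprocessed = FALSE),
            class = "boundary_experiment")
}

#' @export
print.boundary_experiment <- function(x, ...) {
  cat(sprintf("<boundary_experiment> %d subjects, %d runs, %d vertices (%d parcels)%s\n",
              x$config$n_subjects, length(x$runs), nrow(x$runs[[1]]$data),
              x$config$n_parcels, if (isTRUE(x$preprocessed)) ", preprocessed" else ""))
  invisible(x)
}

#' Subjects present in an experiment
#' @param experiment a `boundary_experiment`.
#' @return character vector of subject ids.
#' @export
experiment_subjects <- function(experiment) {
  unique(vapply(experiment$runs, function(r) r$subject, character(1)))
}

#' Retrieve one run of an experiment
#' @param experiment a `boundary_experiment`.
#' @param subject subject id.
#' @param phase `"encoding"` or `"recall"`.
#' @param run run number.
#' @return a [run_data].
#' @export
get_run <- function(experiment, subject, phase, run = 1) {
  id <- run_id(subject, phase, run)
  if (is.null(experiment$runs[[id]])) stop("no such run: ", id)
  experiment$runs[[id]]
}

# event rows for one subject and phase
subject_events <- function(events, subject, phase) {
  events[events$subject == subject & events$phase == phase, , drop = FALSE]
}
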