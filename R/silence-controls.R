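#' Classify silent time points of an encoding run
#'
#' The silence threshold is the mean envelope value over title-scene TRs
#' (titles are silent between-movie periods). Silent TRs are the within-movie
#' TRs - excluding the first `exclusion_s` seconds of each movie - whose
#' envelope value is equal to or lower than that threshold.
#'
#' @param envelope per-TR amplitude values aligned to the columns of `run`
#'   (typically the HRF-convolved, z-scored regressor from
#'   [audio_envelope_regressor]; a raw envelope may be used instead).
#' @param events an [event_table] (rows for this run's subject are used).
#' @param run the [run_data] the envelope aligns with.
#' @param exclusion_s seconds excluded from the start of each movie (45).
#' @return list of class `"silence_mask"`: `tr_idx` (silent TR columns),
#'   `threshold`, `candidates` (all within-movie TRs considered), `run`.
#' @export
silence_timepoints <- function(envelope, events, run, exclusion_s = 45) {
  if (length(envelope) != ncol(run$data)) {
    stop("envelope length (", length(envelope),
         ") does not match run TR count (", ncol(run$data), ")")
  }
  ev <- events[events$subject == run$subject & events$phase == run$phase &
                 events$run == run$run, , drop = FALSE]
  titles <- ev[ev$kind == "title", , drop = FALSE]
  if (nrow(titles) == 0L) stop("no title events; silence threshold undefined")
  title_trs <- unique(unlist(lapply(seq_len(nrow(titles)), function(i) {
    seconds_to_tr_range(titles$onset_s[i], titles$offset_s[i], run)
  })))
  if (length(title_trs) == 0L) stop("no title TRs within the run; threshold undefined")
  threshold <- mean(envelope[title_trs])
  mv <- ev[ev$kind == "movie", , drop = FALSE]
  candidates <- unique(unlist(lapply(seq_len(nrow(mv)), function(i) {
    if (mv$offset_s[i] - mv$onset_s[i] <= exclusion_s) return(integer(0))
    seconds_to_tr_range(mv$onset_s[i] + exclusion_s, mv$offset_s[i], run)
  })))
  silent <- candidates[envelope[candidates] <= threshold]
  structure(list(tr_idx = sort(silent), threshold = threshold,
                 candidates = sort(candidates),
                 subject = run$subject, phase = run$phase, run = run$run),
            class = "silence_mask")
}

# silence masks for every encoding run of a subject, from the experiment's
# stored raw envelopes; processed = HRF-convolved + z-scored regressor
subject_silence_masks <- function(experiment, subject, exclusion_s = 45,
                                  processed = TRUE) {
  enc_ids <- names(experiment$envelopes)
  enc_ids <- enc_ids[startsWith(enc_ids, paste0(subject, "_encoding"))]
  lapply(enc_ids, function(id) {
    run <- experiment$runs[[id]]
    env <- experiment$envelopes[[id]]
    env <- if (processed) {
      audio_envelope_regressor(env, run)
    } else {
      if (length(env) > ncol(run$data)) env[-seq_len(length(env) - ncol(run$data))] else env
    }
    silence_timepoints(env, experiment$events, run, exclusion_s)
  })
}

#' Silence-pattern versus recall-boundary-template correlation
#'
#' For each subject, averages the activation patterns over all within-movie
#' silent TRs of the encoding runs (see [silence_timepoints]) and correlates
#' the result with the subject's recall between-movie boundary template
#' (mean pattern 4.5-19.5 s after each recalled movie's offset). A positive
#' group correlation indicates that the region's boundary pattern is
#' reproduced by mere silence.
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec] for the boundary template.
#' @param region optional parcel labels; `vertices` overrides.
#' @param vertices optional vertex indices.
#' @param exclusion_s seconds excluded from the start of each movie (45).
#' @param processed_envelope use the HRF-convolved z-scored regressor for the
#'   silence threshold (default) or the raw envelope.
#' @return list with `per_subject` (data.frame `r`, `n_silent_trs`) and
#'   `test` (group one-sample t).
#' @export
silence_pattern_correlation <- function(experiment, spec = window_spec(),
                                        region = NULL, vertices = NULL,
                                        exclusion_s = 45,
                                        processed_envelope = TRUE) {
  run1 <- experiment$runs[[1]]
  if (is.null(vertices)) {
    vertices <- if (is.null(region)) seq_len(nrow(run1$data)) else parcel_vertices(run1, region)
  }
  subjects <- experiment_subjects(experiment)
  rows <- lapply(subjects, function(s) {
    masks <- subject_silence_masks(experiment, s, exclusion_s, processed_envelope)
    total <- 0
    acc <- numeric(length(vertices))
    n <- 0L
    for (mk in masks) {
      if (length(mk$tr_idx) == 0L) next
      run <- get_run(experiment, s, "encoding", mk$run)
      acc <- acc + rowSums(run$data[vertices, mk$tr_idx, drop = FALSE])
      n <- n + length(mk$tr_idx)
    }
    if (n == 0L) stop("empty silence mask for subject ", s)
    silent_mean <- acc / n
    template <- build_templates(experiment, s, spec, vertices = vertices,
                                exclusion_s = exclusion_s)$between$recall
    data.frame(subject = s, r = stats::cor(silent_mean, template), n_silent_trs = n)
  })
  df <- do.call(rbind, rows)
  list(per_subject = df, test = one_sample_t(df$r))
}

#' Audio amplitude versus pattern-similarity time-course correlation
#'
#' For each subject, correlates the recall between-movie boundary template
#' with the encoding activation pattern at every within-movie TR (beyond the
#' first `exclusion_s` seconds of each movie), producing a similarity time
#' course; then correlates that time course with the audio-amplitude
#' regressor. A negative group correlation indicates that the boundary-like
#' pattern appears when the audio is quiet.
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec] for the boundary template.
#' @param region optional parcel labels; `vertices` overrides.
#' @param vertices optional vertex indices.
#' @param exclusion_s seconds excluded from the start of each movie (45).
#' @return list with `per_subject` (data.frame `r`, `n_trs`) and `test`.
#' @export
amplitude_similarity_correlation <- function(experiment, spec = window_spec(),
                                             region = NULL, vertices = NULL,
                                             exclusion_s = 45) {
  run1 <- experiment$runs[[1]]
  if (is.null(vertices)) {
    vertices <- if (is.null(region)) seq_len(nrow(run1$data)) else parcel_vertices(run1, region)
  }
  subjects <- experiment_subjects(experiment)
  rows <- lapply(subjects, function(s) {
    template <- build_templates(experiment, s, spec, vertices = vertices,
                                exclusion_s = exclusion_s)$between$recall
    masks <- subject_silence_masks(experiment, s, exclusion_s, processed = TRUE)
    sim <- amp <- numeric(0)
    for (mk in masks) {
      run <- get_run(experiment, s, "encoding", mk$run)
      reg <- audio_envelope_regressor(experiment$envelopes[[run_id(s, "encoding", mk$run)]], run)
      trs <- mk$candidates
      if (length(trs) == 0L) next
      sim <- c(sim, suppressWarnings(stats::cor(template, run$data[vertices, trs, drop = FALSE])))
      amp <- c(amp, reg[trs])
    }
    if (length(sim) < 3L) stop("fewer than 3 usable TRs for subject ", s)
    data.frame(subject = s, r = stats::cor(sim, amp), n_trs = length(sim))
  })
  df <- do.call(rbind, rows)
  list(per_subject = df, test = one_sample_t(df$r))
}
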