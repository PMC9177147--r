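#' Select within-movie event boundaries surviving the carry-over exclusion
#'
#' Within-movie boundaries that occur within the first `exclusion_s` seconds
#' of their movie are excluded to avoid carry-over from the preceding
#' between-movie boundary. A boundary at exactly `exclusion_s` is retained.
#'
#' @param events an [event_table] (encoding phase rows are used).
#' @param exclusion_s exclusion window from movie onset (default 45).
#' @return data.frame of retained `within_event_boundary` rows with an added
#'   `rel_s` column (time into the movie).
#' @export
select_within_boundaries <- function(events, exclusion_s = 45) {
  wb <- events[events$kind == "within_event_boundary", , drop = FALSE]
  if (nrow(wb) == 0L) return(cbind(wb, rel_s = numeric(0)))
  mv <- events[events$kind == "movie", , drop = FALSE]
  key <- function(df) paste(df$subject, df$phase, df$run, df$movie_id)
  onset <- mv$onset_s[match(key(wb), key(mv))]
  if (anyNA(onset)) stop("within-movie boundary without a matching movie interval")
  wb$rel_s <- wb$onset_s - onset
  wb[wb$rel_s >= exclusion_s, , drop = FALSE]
}

#' Build boundary templates for one subject
#'
#' The between-movie boundary template of a phase is the mean over the 10
#' movies' boundary-period patterns (each pattern first averaged over the TRs
#' of its window, then across movies). The within-movie event-boundary
#' template is built the same way from the retained within-movie boundaries
#' of the encoding phase, using windows of `spec$duration_s` starting
#' `spec$shift_s` after each boundary.
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param subject subject id.
#' @param spec a [window_spec] (default 4.5-19.5 s windows; pass
#'   `window_spec(4.5, 4.5)` for the short-window variant).
#' @param region optional parcel labels; `vertices` overrides.
#' @param vertices optional vertex indices.
#' @param exclusion_s within-movie boundary exclusion (default 45).
#' @return list of class `"template_set"`: `between` (list `encoding`,
#'   `recall`), `within`, `retained` (boundary rows), `vertices`.
#' @export
build_templates <- function(experiment, subject, spec = window_spec(),
                            region = NULL, vertices = NULL, exclusion_s = 45) {
  run1 <- experiment$runs[[1]]
  if (is.null(vertices)) {
    vertices <- if (is.null(region)) seq_len(nrow(run1$data)) else parcel_vertices(run1, region)
  }
  between <- list()
  for (phase in c("encoding", "recall")) {
    ev <- subject_events(experiment$events, subject, phase)
    mv <- ev[ev$kind == "movie", , drop = FALSE]
    pats <- vapply(seq_len(nrow(mv)), function(i) {
      run <- get_run(experiment, subject, phase, mv$run[i])
      window_pattern(run, boundary_window(mv$offset_s[i], spec),
                     label = paste0(phase, " boundary M", mv$movie_id[i]))[vertices]
    }, numeric(length(vertices)))
    between[[phase]] <- rowMeans(pats)
  }
  enc_ev <- subject_events(experiment$events, subject, "encoding")
  retained <- select_within_boundaries(enc_ev, exclusion_s)
  within <- NULL
  if (nrow(retained) > 0L) {
    pats <- vapply(seq_len(nrow(retained)), function(i) {
      run <- get_run(experiment, subject, "encoding", retained$run[i])
      window_pattern(run, boundary_window(retained$onset_s[i], spec),
                     label = paste0("within-boundary M", retained$movie_id[i]))[vertices]
    }, numeric(length(vertices)))
    within <- rowMeans(pats)
  }
  structure(list(between = between, within = within, retained = retained,
                 vertices = vertices, subject = subject),
            class = "template_set")
}

#' Template similarity for one subject
#'
#' `orange`: correlation between the encoding and recall between-movie
#' boundary templates. `green`: correlation between the encoding within-movie
#' event-boundary template and the recall between-movie boundary template.
#'
#' @param ts a [build_templates] result.
#' @return named list `orange`, `green` (green is NA without retained
#'   within-movie boundaries).
#' @export
template_similarity <- function(ts) {
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant template; correlation undefined")
    stats::cor(x, y)
  }
  list(orange = safe_cor(ts$between$encoding, ts$between$recall),
       green = if (is.null(ts$within)) NA_real_ else safe_cor(ts$within, ts$between$recall))
}

#' Group-level template similarity
#'
#' Per-subject orange/green template correlations (see [template_similarity])
#' with two-tailed one-sample t-tests against zero, Cohen's d_z, and 95% CIs.
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec].
#' @param region optional parcel labels; `vertices` overrides.
#' @param vertices optional vertex indices.
#' @param exclusion_s within-movie boundary exclusion (default 45).
#' @return list with `per_subject` (data.frame) and `tests` (`orange`, `green`).
#' @export
template_similarity_stats <- function(experiment, spec = window_spec(),
                                      region = NULL, vertices = NULL,
                                      exclusion_s = 45) {
  subjects <- experiment_subjects(experiment)
  rows <- lapply(subjects, function(s) {
    sim <- template_similarity(build_templates(experiment, s, spec, region = region,
                                               vertices = vertices,
                                               exclusion_s = exclusion_s))
    data.frame(subject = s, orange = sim$orange, green = sim$green)
  })
  df <- do.call(rbind, rows)
  list(per_subject = df,
       tests = list(orange = one_sample_t(df$orange),
                    green = one_sample_t(df$green)))
}

# do two half-open intervals intersect with positive measure?
intervals_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

#' Consistency of within-movie event-boundary patterns
#'
#' Per subject: (i) the mean between-movie correlation among the retained
#' within-movie boundary patterns (pairs from the same movie are excluded);
#' (ii) the mean between-movie correlation between within-movie boundary
#' patterns and non-boundary (mid-movie) patterns, where non-boundary periods
#' whose window overlaps any retained within-movie boundary window are
#' excluded. Group inference: one-sample t on (i) and paired t of (i) vs (ii).
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec].
#' @param region optional parcel labels; `vertices` overrides.
#' @param vertices optional vertex indices.
#' @param exclusion_s within-movie boundary exclusion (default 45).
#' @param inference run the group tests (default); disable for degenerate
#'   noiseless data where the per-subject values have zero spread.
#' @return list with `per_subject` (data.frame `within_r`, `cross_r`,
#'   `n_excluded_nonboundary`) and `tests` (`within`, `within_vs_cross`).
#' @export
within_movie_consistency <- function(experiment, spec = window_spec(),
                                     region = NULL, vertices = NULL,
                                     exclusion_s = 45, inference = TRUE) {
  run1 <- experiment$runs[[1]]
  if (is.null(vertices)) {
    vertices <- if (is.null(region)) seq_len(nrow(run1$data)) else parcel_vertices(run1, region)
  }
  subjects <- experiment_subjects(experiment)
  rows <- lapply(subjects, function(s) {
    ev <- subject_events(experiment$events, s, "encoding")
    retained <- select_within_boundaries(ev, exclusion_s)
    if (nrow(retained) < 2L) stop("fewer than 2 retained within-movie boundaries")
    bwins <- lapply(retained$onset_s, boundary_window, spec = spec)
    bpat <- vapply(seq_len(nrow(retained)), function(i) {
      run <- get_run(experiment, s, "encoding", retained$run[i])
      window_pattern(run, bwins[[i]])[vertices]
    }, numeric(length(vertices)))
    # (i) pairwise correlations among boundary patterns, different movies only
    C <- stats::cor(bpat)
    pair <- which(upper.tri(C), arr.ind = TRUE)
    diff_movie <- retained$movie_id[pair[, 1]] != retained$movie_id[pair[, 2]]
    if (!any(diff_movie)) stop("no between-movie pairs among retained boundaries")
    within_r <- mean(C[pair[diff_movie, , drop = FALSE]])
    # (ii) boundary vs non-boundary patterns, excluding overlapping non-boundary windows
    mv <- ev[ev$kind == "movie", , drop = FALSE]
    keep <- logical(nrow(mv))
    npat <- matrix(NA_real_, length(vertices), nrow(mv))
    for (i in seq_len(nrow(mv))) {
      mw <- middle_window(mv$onset_s[i], mv$offset_s[i], spec,
                          label = paste0("M", mv$movie_id[i]))
      overlaps <- any(vapply(bwins, intervals_overlap, logical(1), b = mw))
      if (!overlaps) {
        run <- get_run(experiment, s, "encoding", mv$run[i])
        npat[, i] <- window_pattern(run, mw)[vertices]
        keep[i] <- TRUE
      }
    }
    if (!any(keep)) stop("all non-boundary periods excluded by overlap")
    Cx <- stats::cor(bpat, npat[, keep, drop = FALSE])
    diff_movie_x <- outer(retained$movie_id, mv$movie_id[keep], "!=")
    if (!any(diff_movie_x)) stop("no valid boundary/non-boundary pairs after exclusions")
    cross_r <- mean(Cx[diff_movie_x])
    data.frame(subject = s, within_r = within_r, cross_r = cross_r,
               n_excluded_nonboundary = sum(!keep))
  })
  df <- do.call(rbind, rows)
  tests <- if (inference) {
    list(within = one_sample_t(df$within_r),
         within_vs_cross = paired_t(df$within_r, df$cross_r))
  }
  list(per_subject = df, tests = tests)
}
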