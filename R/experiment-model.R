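#' Event table constructor and validator
#'
#' An event table is a plain `data.frame` describing the timeline of one or
#' more runs: movie presentations (or recall periods), 6-s title scenes,
#' within-movie coarse event boundaries, and inter-movie recall pauses. All
#' times are in seconds on the *run clock*, where the acquisition of the first
#' volume of the run defines time 0. Point events (within-movie boundaries)
#' have `offset_s = NA`.
#'
#' @param df data.frame with columns `subject`, `phase` (`"encoding"` or
#'   `"recall"`), `run` (integer >= 1), `movie_id` (integer 1..n or NA),
#'   `kind` (`"movie"`, `"title"`, `"within_event_boundary"`, `"pause"`),
#'   `onset_s`, `offset_s`.
#' @return the validated data.frame with class `c("event_table", "data.frame")`.
#' @export
event_table <- function(df) {
  required <- c("subject", "phase", "run", "movie_id", "kind", "onset_s", "offset_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required]
  bad_phase <- setdiff(unique(df$phase), c("encoding", "recall"))
  if (length(bad_phase) > 0L) {
    stop("unknown phase value(s): ", paste(bad_phase, collapse = ", "))
  }
  known_kinds <- c("movie", "title", "within_event_boundary", "pause")
  bad <- which(!df$kind %in% known_kinds)
  if (length(bad) > 0L) {
    stop("unknown event kind '", df$kind[bad[1]], "' in row ", bad[1])
  }
  interval <- df$kind %in% c("movie", "title", "pause")
  if (any(is.na(df$onset_s)) || any(interval & is.na(df$offset_s))) {
    stop("interval events must have finite onset_s and offset_s")
  }
  if (any(df$offset_s[interval] <= df$onset_s[interval])) {
    stop("interval events must have offset_s > onset_s")
  }
  # movie intervals must not overlap within a (subject, phase, run)
  mv <- df[df$kind == "movie", , drop = FALSE]
  if (nrow(mv) > 1L) {
    for (key in split(seq_len(nrow(mv)), paste(mv$subject, mv$phase, mv$run))) {
      o <- order(mv$onset_s[key])
      on <- mv$onset_s[key][o]
      off <- mv$offset_s[key][o]
      if (any(on[-1] < off[-length(off)])) {
        stop("movie intervals overlap within a (subject, phase, run)")
      }
    }
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Window specification for boundary and non-boundary periods
#'
#' Boundary and non-boundary periods are fixed-length windows shifted forward
#' in time to account for the haemodynamic response delay. The study default
#' is a 15-s window shifted by 4.5 s; a shorter 4.5-s variant is used in
#' control analyses.
#'
#' @param shift_s haemodynamic delay in seconds (default 4.5).
#' @param duration_s window length in seconds (default 15; alternate 4.5).
#' @return list of class `"window_spec"`.
#' @export
window_spec <- function(shift_s = 4.5, duration_s = 15) {
  if (!is.finite(shift_s) || !is.finite(duration_s)) {
    stop("shift_s and duration_s must be finite")
  }
  if (shift_s < 0) stop("shift_s must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  structure(list(shift_s = shift_s, duration_s = duration_s), class = "window_spec")
}

#' One run of vertex-by-time BOLD data
#'
#' @param data numeric matrix, vertices x TRs, no missing values.
#' @param subject subject identifier.
#' @param phase `"encoding"` or `"recall"`.
#' @param run run number (>= 1).
#' @param tr_s repetition time in seconds (default 1.5).
#' @param trim_offset_s seconds of discarded initial acquisition represented by
#'   column 1 of `data`; must be a non-negative multiple of `tr_s`.
#' @param vertex_parcel integer parcel label per vertex.
#' @param vertex_area_mm2 optional per-vertex surface area (defaults to 1).
#' @return list of class `"run_data"`.
#' @export
run_data <- function(data, subject, phase, run, tr_s = 1.5, trim_offset_s = 0,
                     vertex_parcel = NULL, vertex_area_mm2 = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("run data must not contain missing values")
  if (!phase %in% c("encoding", "recall")) stop("phase must be 'encoding' or 'recall'")
  if (tr_s <= 0) stop("tr_s must be positive")
  if (trim_offset_s < 0 || abs(trim_offset_s / tr_s - round(trim_offset_s / tr_s)) > 1e-9) {
    stop("trim_offset_s must be a non-negative multiple of tr_s")
  }
  if (is.null(vertex_parcel)) vertex_parcel <- rep(1L, nrow(data))
  if (length(vertex_parcel) != nrow(data)) {
    stop("vertex_parcel length (", length(vertex_parcel),
         ") does not match n_vertices (", nrow(data), ")")
  }
  if (is.null(vertex_area_mm2)) vertex_area_mm2 <- rep(1, nrow(data))
  if (length(vertex_area_mm2) != nrow(data)) {
    stop("vertex_area_mm2 length does not match n_vertices")
  }
  structure(
    list(subject = subject, phase = phase, run = as.integer(run), tr_s = tr_s,
         data = data, trim_offset_s = trim_offset_s,
         vertex_parcel = as.integer(vertex_parcel),
         vertex_area_mm2 = as.numeric(vertex_area_mm2),
         trimmed = trim_offset_s > 0),
    class = "run_data"
  )
}

#' @export
print.run_data <- function(x, ...) {
  cat(sprintf("<run_data> subject %s, %s run %d: %d vertices x %d TRs (TR %.2g s, trim %.3g s)\n",
              x$subject, x$phase, x$run, nrow(x$data), ncol(x$data), x$tr_s, x$trim_offset_s))
  invisible(x)
}

#' Map a time interval in seconds to TR column indices
#'
#' A TR belongs to the window iff its acquisition onset time
#' (`trim_offset_s + (k - 1) * tr_s` for column `k`) falls in the half-open
#' interval `[start_s, end_s)`. The result is clipped to the columns present
#' in the run; an empty window yields `integer(0)`.
#'
#' @param start_s,end_s window bounds in seconds on the run clock.
#' @param run a [run_data] object.
#' @return integer vector of 1-based column indices (possibly empty).
#' @export
seconds_to_tr_range <- function(start_s, end_s, run) {
  if (!is.finite(start_s) || !is.finite(end_s)) stop("window bounds must be finite")
  if (start_s >= end_s) stop("start_s must be < end_s")
  tr <- run$tr_s
  n <- ncol(run$data)
  # onset of column k is trim_offset_s + (k - 1) * tr
  k_first <- ceiling((start_s - run$trim_offset_s) / tr - 1e-9) + 1
  k_last <- ceiling((end_s - run$trim_offset_s) / tr - 1e-9)  # last k with onset < end_s
  k_first <- max(k_first, 1L)
  k_last <- min(k_last, n)
  if (k_first > k_last) return(integer(0))
  seq.int(k_first, k_last)
}

#' Boundary-period window following a movie offset
#'
#' The boundary period is the first `duration_s` seconds following the offset
#' of a watched or recalled movie, shifted forward by `shift_s` to account for
#' the haemodynamic delay.
#'
#' @param offset_s movie offset in seconds (run clock).
#' @param spec a [window_spec].
#' @return numeric `c(start, end)` of the half-open window in seconds.
#' @export
boundary_window <- function(offset_s, spec = window_spec()) {
  if (!is.finite(offset_s)) stop("offset_s must be finite")
  c(offset_s + spec$shift_s, offset_s + spec$shift_s + spec$duration_s)
}

#' Non-boundary (mid-movie) window
#'
#' A window of length `duration_s` centred on the temporal midpoint of the
#' movie, then shifted forward by `shift_s`. The movie must be at least
#' `duration_s` long.
#'
#' @param onset_s,offset_s movie onset/offset in seconds (run clock).
#' @param spec a [window_spec].
#' @param label optional movie label used in error messages.
#' @return numeric `c(start, end)` in seconds.
#' @export
middle_window <- function(onset_s, offset_s, spec = window_spec(), label = NULL) {
  if (!is.finite(onset_s) || !is.finite(offset_s)) stop("onset_s and offset_s must be finite")
  if (offset_s - onset_s < spec$duration_s) {
    stop("movie ", if (is.null(label)) "" else paste0("'", label, "' "),
         "is shorter (", offset_s - onset_s, " s) than the window duration (",
         spec$duration_s, " s)")
  }
  mid <- (onset_s + offset_s) / 2
  c(mid - spec$duration_s / 2 + spec$shift_s, mid + spec$duration_s / 2 + spec$shift_s)
}

#' Mean spatial pattern over a set of TRs
#'
#' @param run a [run_data] object.
#' @param tr_range integer vector of column indices (see [seconds_to_tr_range]).
#' @param label optional event label used in error messages.
#' @return numeric vector of length `n_vertices`.
#' @export
extract_mean_pattern <- function(run, tr_range, label = NULL) {
  if (length(tr_range) == 0L) {
    stop("empty TR range", if (is.null(label)) "" else paste0(" for event '", label, "'"))
  }
  rowMeans(run$data[, tr_range, drop = FALSE])
}

# mean pattern for a seconds window; internal convenience
window_pattern <- function(run, win, label = NULL) {
  extract_mean_pattern(run, seconds_to_tr_range(win[1], win[2], run), label = label)
}

#' Convert encoding stimulus-clock time to run-clock time
#'
#' Stimulus presentation began 3 s after the first volume of each encoding
#' run; the conversion is explicit everywhere in this package.
#'
#' @param t_s time in seconds on the stimulus clock.
#' @param lead_s delay of stimulus onset relative to the first volume (3 s).
#' @return time in seconds on the run clock.
#' @export
stim_to_run_clock <- function(t_s, lead_s = 3) t_s + lead_s

#' Vertices belonging to a set of parcels
#'
#' @param run a [run_data] object (or anything with `$vertex_parcel`).
#' @param parcels integer parcel labels.
#' @return integer vector of vertex indices.
#' @export
parcel_vertices <- function(run, parcels) {
  v <- which(run$vertex_parcel %in% parcels)
  if (length(v) == 0L) stop("no vertices in parcel set: ", paste(parcels, collapse = ", "))
  v
}

#' Read / write event tables as TSV
#'
#' Columns `subject`, `phase`, `run`, `movie_id`, `kind`, `onset_s`,
#' `offset_s`; UTF-8, one header row, seconds written with 3 decimals.
#'
#' @param events an [event_table].
#' @param path file path.
#' @return `read_events_tsv` returns a validated [event_table];
#'   `write_events_tsv` returns `path` invisibly.
#' @export
write_events_tsv <- function(events, path) {
  df <- as.data.frame(events)
  df$onset_s <- sprintf("%.3f", df$onset_s)
  df$offset_s <- ifelse(is.na(df$offset_s), "NA", sprintf("%.3f", as.numeric(df$offset_s)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", fileEncoding = "UTF-8")
  df$onset_s <- as.numeric(df$onset_s)
  df$offset_s <- as.numeric(df$offset_s)
  event_table(df)
}
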