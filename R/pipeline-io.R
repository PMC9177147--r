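#' Write an experiment to a dataset directory
#'
#' Stores each run's vertex x TR matrix as a parquet file (via the arrow
#' package) with a JSON sidecar of run metadata and a schema version, the
#' event table as TSV, raw audio envelopes as TSV, and the ground truth
#' (planted patterns, parcel assignments, seed) as JSON.
#'
#' @param experiment a `boundary_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required to write dataset containers")
  }
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema_version = 1L, preprocessed = isTRUE(experiment$preprocessed),
               runs = list())
  for (id in names(experiment$runs)) {
    run <- experiment$runs[[id]]
    arrow::write_parquet(as.data.frame(run$data), file.path(dir, "runs", paste0(id, ".parquet")))
    meta$runs[[id]] <- list(subject = run$subject, phase = run$phase, run = run$run,
                            tr_s = run$tr_s, trim_offset_s = run$trim_offset_s,
                            n_vertices = nrow(run$data), n_trs = ncol(run$data),
                            vertex_parcel = run$vertex_parcel,
                            vertex_area_mm2 = run$vertex_area_mm2)
  }
  jsonlite::write_json(meta, file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA)
  write_events_tsv(experiment$events, file.path(dir, "events.tsv"))
  if (length(experiment$envelopes) > 0L) {
    env_df <- do.call(rbind, lapply(names(experiment$envelopes), function(id) {
      data.frame(run_id = id, tr = seq_along(experiment$envelopes[[id]]),
                 amplitude = experiment$envelopes[[id]])
    }))
    utils::write.table(env_df, file.path(dir, "envelopes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(experiment$truth)) {
    truth <- experiment$truth
    jsonlite::write_json(
      list(p_bound = truth$p_bound, p_evt = truth$p_evt, p_sil = truth$p_sil,
           roi = truth$roi, seed = experiment$config$seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an experiment from a dataset directory
#'
#' Validates the schema version, run metadata (TR, trim offsets, label
#' lengths), and the absence of missing values, then reconstructs a
#' `boundary_experiment` (without ground truth).
#'
#' @param dir directory written by [write_experiment].
#' @return a `boundary_experiment`.
#' @export
read_experiment <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required to read dataset containers")
  }
  meta_path <- file.path(dir, "dataset.json")
  if (!file.exists(meta_path)) stop("not a dataset directory (missing dataset.json)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L) {
    stop("unsupported schema_version: ", meta$schema_version)
  }
  runs <- list()
  for (id in names(meta$runs)) {
    m <- meta$runs[[id]]
    X <- as.matrix(arrow::read_parquet(file.path(dir, "runs", paste0(id, ".parquet"))))
    dimnames(X) <- NULL
    if (anyNA(X)) stop("run ", id, " contains missing values")
    if (ncol(X) != m$n_trs || nrow(X) != m$n_vertices) {
      stop("run ", id, ": data dimensions do not match field n_vertices/n_trs")
    }
    runs[[id]] <- run_data(X, subject = m$subject, phase = m$phase, run = m$run,
                           tr_s = m$tr_s, trim_offset_s = m$trim_offset_s,
                           vertex_parcel = m$vertex_parcel,
                           vertex_area_mm2 = m$vertex_area_mm2)
  }
  events <- read_events_tsv(file.path(dir, "events.tsv"))
  envelopes <- list()
  env_path <- file.path(dir, "envelopes.tsv")
  if (file.exists(env_path)) {
    env_df <- utils::read.delim(env_path)
    envelopes <- lapply(split(env_df, env_df$run_id),
                        function(d) d$amplitude[order(d$tr)])
  }
  structure(list(runs = runs, events = events, envelopes = envelopes,
                 truth = NULL, config = NULL,
                 preprocessed = isTRUE(meta$preprocessed)),
            class = "boundary_experiment")
}

#' Run the full boundary-pattern pipeline on a synthetic experiment
#'
#' Executes simulate, preprocess, univariate, similarity (parcel-wise
#' conjunctions + ROI summary), temporal dynamics, boundary templates, and
#' silence controls, and returns all stage results together with a summary.
#' Stages can be switched off; later stages that need an earlier stage's
#' output fail with the stage name.
#'
#' @param config a [ground_truth_config] (its `seed` drives all randomness).
#' @param spec a [window_spec].
#' @param alpha Bonferroni family-wise level for parcel-wise maps.
#' @param q FDR level for the univariate map.
#' @param stages character vector of stages to run.
#' @param out_dir optional directory; per-stage TSV/JSON outputs and a
#'   `summary.json` (seed, package version, config hash) are written there.
#' @return list of class `"pipeline_result"`.
#' @export
run_pipeline <- function(config = ground_truth_config(),
                         spec = window_spec(), alpha = 0.05, q = 0.05,
                         stages = c("univariate", "similarity", "temporal",
                                    "templates", "silence"),
                         out_dir = NULL) {
  experiment <- preprocess_experiment(generate_experiment(config))
  roi <- experiment$truth$roi
  res <- list(config = config)
  if ("univariate" %in% stages) {
    contrasts <- boundary_contrasts(experiment, spec)
    res$univariate <- group_univariate_map(
      contrasts, q = q, vertex_parcel = experiment$runs[[1]]$vertex_parcel,
      vertex_area_mm2 = experiment$runs[[1]]$vertex_area_mm2)
  }
  if ("similarity" %in% stages) {
    sims <- parcelwise_similarity(experiment, spec)
    res$similarity <- list(
      parcelwise = sims,
      conjunction_recall = conjunction_map(sims$a, sims$b, alpha),
      conjunction_cross_phase = conjunction_map(sims$c, sims$d, alpha),
      visual_control = visual_control_contrast(sims, alpha),
      roi = similarity_result(experiment, spec, region = roi$boundary))
  }
  if ("temporal" %in% stages) {
    subjects <- experiment_subjects(experiment)
    mats <- lapply(subjects, function(s) {
      enc <- timelocked_pattern_series(experiment, s, "offset", "encoding",
                                       region = roi$boundary)
      rec <- timelocked_pattern_series(experiment, s, "offset", "recall",
                                       region = roi$boundary)
      timetime_matrix(enc, rec)
    })
    res$temporal <- list(matrices = mats,
                         significance = group_timetime_significance(mats, alpha))
  }
  if ("templates" %in% stages) {
    res$templates <- list(
      similarity = template_similarity_stats(experiment, spec, region = roi$boundary),
      consistency = within_movie_consistency(experiment, spec, region = roi$boundary))
  }
  if ("silence" %in% stages) {
    res$silence <- list(
      aud = silence_pattern_correlation(experiment, spec, region = roi$aud),
      boundary_roi = silence_pattern_correlation(experiment, spec, region = roi$boundary),
      amplitude = amplitude_similarity_correlation(experiment, spec, region = roi$aud))
  }
  res$summary <- pipeline_summary(res)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  class(res) <- "pipeline_result"
  res
}

group_test_fields <- function(g) {
  list(t = g$t_stat, df = g$df, p = g$p_two_tailed, d_z = g$d_z,
       ci95 = g$ci95, mean = g$mean, n = g$n)
}

pipeline_summary <- function(res) {
  s <- list(seed = res$config$seed)
  if (!is.null(res$univariate)) {
    s$univariate_significant_fraction <- mean(res$univariate$significant)
  }
  if (!is.null(res$similarity)) {
    s$conjunction_recall_parcels <- which(as.logical(res$similarity$conjunction_recall))
    s$conjunction_cross_phase_parcels <-
      which(as.logical(res$similarity$conjunction_cross_phase))
    s$roi_boundary_similarity <- lapply(res$similarity$roi$tests, group_test_fields)
  }
  if (!is.null(res$temporal)) {
    s$timetime_significant_cells <- sum(res$temporal$significance)
    s$timetime_tested_cells <- attr(res$temporal$significance, "n_tested")
  }
  if (!is.null(res$templates)) {
    s$template_orange <- group_test_fields(res$templates$similarity$tests$orange)
    s$template_green <- group_test_fields(res$templates$similarity$tests$green)
  }
  if (!is.null(res$silence)) {
    s$silence_aud <- group_test_fields(res$silence$aud$test)
    s$silence_boundary_roi <- group_test_fields(res$silence$boundary_roi$test)
    s$amplitude_similarity_aud <- group_test_fields(res$silence$amplitude$test)
  }
  s
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$univariate)) {
    utils::write.table(res$univariate, file.path(out_dir, "univariate_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$similarity)) {
    utils::write.table(res$similarity$roi$per_subject,
                       file.path(out_dir, "roi_similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$similarity$visual_control,
                       file.path(out_dir, "visual_control.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$temporal)) {
    utils::write.table(attr(res$temporal$significance, "t"),
                       file.path(out_dir, "timetime_t.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
  }
  summary <- res$summary
  summary$package_version <- as.character(utils::packageVersion("boundarypattern"))
  summary$config_hash <- config_hash(res$config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# stable hash of the configuration (serialised field by field)
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(as.character(txt))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:", paste(setdiff(names(x), c("config", "summary")),
                                         collapse = ", "), "\n")
  if (!is.null(x$similarity)) {
    cat("  cross-phase conjunction parcels:",
        paste(x$summary$conjunction_cross_phase_parcels, collapse = ", "), "\n")
  }
  invisible(x)
}
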