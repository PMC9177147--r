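#' Build the boundary / non-boundary pattern set for one subject
#'
#' Extracts, for each movie and each phase, the mean spatial activation
#' pattern of the boundary period (the `duration_s` window following the
#' movie offset) and the non-boundary period (the `duration_s` window in the
#' middle of the movie), both shifted forward by `shift_s`. A complete
#' subject yields 10 movies x 2 conditions x 2 phases = 40 patterns; movies
#' missing from the recall are recorded as missing.
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param subject subject id.
#' @param spec a [window_spec].
#' @param region optional parcel labels restricting the patterns; `vertices`
#'   overrides with explicit vertex indices. Default: all vertices.
#' @param vertices optional integer vertex indices.
#' @return list of class `"pattern_set"`: `patterns[[phase]][[condition]]` is
#'   a vertices x 10 matrix (NA columns for missing movies), plus `subject`,
#'   `vertices`, and `n_patterns`.
#' @export
build_pattern_set <- function(experiment, subject, spec = window_spec(),
                              region = NULL, vertices = NULL) {
  run1 <- experiment$runs[[1]]
  if (is.null(vertices)) {
    vertices <- if (is.null(region)) seq_len(nrow(run1$data)) else parcel_vertices(run1, region)
  }
  if (length(vertices) == 0L) stop("region contains 0 vertices")
  patterns <- list()
  n_patterns <- 0L
  for (phase in c("encoding", "recall")) {
    ev <- subject_events(experiment$events, subject, phase)
    mv <- ev[ev$kind == "movie", , drop = FALSE]
    bmat <- matrix(NA_real_, length(vertices), 10)
    nmat <- matrix(NA_real_, length(vertices), 10)
    colnames(bmat) <- colnames(nmat) <- paste0("M", 1:10)
    for (i in seq_len(nrow(mv))) {
      m <- mv$movie_id[i]
      run <- get_run(experiment, subject, phase, mv$run[i])
      bw <- boundary_window(mv$offset_s[i], spec)
      mw <- middle_window(mv$onset_s[i], mv$offset_s[i], spec, label = paste0("M", m))
      bmat[, m] <- window_pattern(run, bw, label = paste0(phase, " boundary M", m))[vertices]
      nmat[, m] <- window_pattern(run, mw, label = paste0(phase, " middle M", m))[vertices]
      n_patterns <- n_patterns + 2L
    }
    patterns[[phase]] <- list(boundary = bmat, nonboundary = nmat)
  }
  structure(list(subject = subject, vertices = vertices, patterns = patterns,
                 n_patterns = n_patterns),
            class = "pattern_set")
}

# restrict a full-cortex pattern set to a vertex subset
subset_pattern_set <- function(ps, vertices) {
  idx <- match(vertices, ps$vertices)
  if (anyNA(idx)) stop("requested vertices are not part of the pattern set")
  ps$vertices <- vertices
  for (phase in names(ps$patterns)) {
    for (cond in names(ps$patterns[[phase]])) {
      ps$patterns[[phase]][[cond]] <- ps$patterns[[phase]][[cond]][idx, , drop = FALSE]
    }
  }
  ps
}

# mean between-movie correlation. A (and optionally B) are vertices x 10
# matrices with NA columns for missing movies. With B = NULL: mean over
# unordered pairs of distinct available movies (45 when complete). With B:
# mean over ordered cross-set pairs i != j (90 when complete).
between_movie_mean_r <- function(A, B = NULL) {
  avail_a <- which(colSums(is.na(A)) == 0L)
  if (is.null(B)) {
    if (length(avail_a) < 2L) stop("need >= 2 movies for between-movie similarity")
    X <- A[, avail_a, drop = FALSE]
    if (any(apply(X, 2, stats::sd) == 0)) stop("constant pattern vector; correlation undefined")
    C <- stats::cor(X)
    vals <- C[upper.tri(C)]
  } else {
    avail_b <- which(colSums(is.na(B)) == 0L)
    if (length(avail_a) < 1L || length(avail_b) < 1L) stop("no movies available")
    Xa <- A[, avail_a, drop = FALSE]
    Xb <- B[, avail_b, drop = FALSE]
    if (any(apply(Xa, 2, stats::sd) == 0) || any(apply(Xb, 2, stats::sd) == 0)) {
      stop("constant pattern vector; correlation undefined")
    }
    C <- stats::cor(Xa, Xb)
    keep <- outer(avail_a, avail_b, "!=")
    vals <- C[keep]
    if (length(vals) == 0L) stop("no between-movie pairs available")
  }
  structure(mean(vals), n_pairs = length(vals))
}

#' Mean between-movie pattern similarity for one subject
#'
#' Pearson correlations between the patterns of different movies, averaged.
#' Within one phase this is the mean over all unordered pairs of movies (45
#' when all 10 are present); across phases it is the mean over all ordered
#' (encoding movie i, recall movie j) pairs with i != j (90 when complete).
#'
#' @param ps a [build_pattern_set] result.
#' @param phases length-2 character vector, e.g. `c("recall", "recall")` or
#'   `c("encoding", "recall")`.
#' @param condition `"boundary"` or `"nonboundary"`.
#' @return mean correlation (scalar) with attribute `n_pairs`.
#' @export
mean_between_movie_similarity <- function(ps, phases = c("recall", "recall"),
                                          condition = c("boundary", "nonboundary")) {
  condition <- match.arg(condition)
  stopifnot(length(phases) == 2L, all(phases %in% c("encoding", "recall")))
  A <- ps$patterns[[phases[1]]][[condition]]
  B <- if (phases[1] == phases[2]) NULL else ps$patterns[[phases[2]]][[condition]]
  between_movie_mean_r(A, B)
}

#' The four headline similarity quantities for one subject
#'
#' `a`: within-recall between-movie boundary similarity; `b`: same for
#' non-boundary patterns; `c`: encoding-recall between-movie boundary
#' similarity; `d`: same for non-boundary patterns.
#'
#' @param ps a [build_pattern_set] result.
#' @return named list `a`, `b`, `c`, `d`.
#' @export
similarity_summary <- function(ps) {
  list(a = mean_between_movie_similarity(ps, c("recall", "recall"), "boundary"),
       b = mean_between_movie_similarity(ps, c("recall", "recall"), "nonboundary"),
       c = mean_between_movie_similarity(ps, c("encoding", "recall"), "boundary"),
       d = mean_between_movie_similarity(ps, c("encoding", "recall"), "nonboundary"))
}

#' Group-level boundary-similarity result for a region
#'
#' Computes the per-subject quantities of [similarity_summary] and the group
#' statistics reported with them: one-sample t-tests of each mean correlation
#' against zero and paired t-tests of boundary vs. non-boundary similarity,
#' all two-tailed, on raw mean r (not Fisher-z).
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec].
#' @param region optional parcel labels (see [build_pattern_set]).
#' @param vertices optional vertex indices.
#' @return list of class `"similarity_result"` with `per_subject` (data.frame
#'   subject/a/b/c/d) and `tests` (`a`, `b`, `c`, `d`, `a_vs_b`, `c_vs_d`).
#' @export
similarity_result <- function(experiment, spec = window_spec(), region = NULL,
                              vertices = NULL) {
  subjects <- experiment_subjects(experiment)
  rows <- lapply(subjects, function(s) {
    ps <- build_pattern_set(experiment, s, spec, region = region, vertices = vertices)
    sm <- similarity_summary(ps)
    data.frame(subject = s, a = as.numeric(sm$a), b = as.numeric(sm$b),
               c = as.numeric(sm$c), d = as.numeric(sm$d))
  })
  df <- do.call(rbind, rows)
  tests <- list(a = one_sample_t(df$a), b = one_sample_t(df$b),
                c = one_sample_t(df$c), d = one_sample_t(df$d),
                a_vs_b = paired_t(df$a, df$b), c_vs_d = paired_t(df$c, df$d))
  structure(list(per_subject = df, tests = tests), class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Between-movie pattern similarity (group means):\n")
  cat(sprintf("  a (recall-recall, boundary)     = %.4f\n", mean(x$per_subject$a)))
  cat(sprintf("  b (recall-recall, non-boundary) = %.4f\n", mean(x$per_subject$b)))
  cat(sprintf("  c (encoding-recall, boundary)   = %.4f\n", mean(x$per_subject$c)))
  cat(sprintf("  d (encoding-recall, non-bound.) = %.4f\n", mean(x$per_subject$d)))
  cat("  boundary > 0 (a): "); print(x$tests$a)
  cat("  boundary > non-boundary (a vs b): "); print(x$tests$a_vs_b)
  invisible(x)
}

#' Parcel-wise per-subject similarity matrices
#'
#' One pass over subjects computing, for every parcel, the five mean
#' between-movie correlations used by the whole-brain analyses: `a`, `b`
#' (within recall), `c`, `d` (encoding-recall), and `e` (encoding boundary vs.
#' recall non-boundary, the visual-feature control comparison).
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec].
#' @return list of subjects x parcels matrices `a`, `b`, `c`, `d`, `e`, plus
#'   `subjects` and `parcels`.
#' @export
parcelwise_similarity <- function(experiment, spec = window_spec()) {
  run1 <- experiment$runs[[1]]
  parcels <- sort(unique(run1$vertex_parcel))
  subjects <- experiment_subjects(experiment)
  vert_by_parcel <- lapply(parcels, function(p) which(run1$vertex_parcel == p))
  out <- lapply(1:5, function(i) matrix(NA_real_, length(subjects), length(parcels),
                                        dimnames = list(subjects, parcels)))
  names(out) <- c("a", "b", "c", "d", "e")
  for (si in seq_along(subjects)) {
    ps <- build_pattern_set(experiment, subjects[si], spec)
    for (pi in seq_along(parcels)) {
      sub <- subset_pattern_set(ps, vert_by_parcel[[pi]])
      eb <- sub$patterns$encoding$boundary
      en <- sub$patterns$encoding$nonboundary
      rb <- sub$patterns$recall$boundary
      rn <- sub$patterns$recall$nonboundary
      out$a[si, pi] <- between_movie_mean_r(rb)
      out$b[si, pi] <- between_movie_mean_r(rn)
      out$c[si, pi] <- between_movie_mean_r(eb, rb)
      out$d[si, pi] <- between_movie_mean_r(en, rn)
      out$e[si, pi] <- between_movie_mean_r(eb, rn)
    }
  }
  out$subjects <- subjects
  out$parcels <- parcels
  out
}

#' Parcel-wise conjunction map
#'
#' A parcel is marked iff (1) the one-sample t-test of its mean boundary
#' correlation against zero is significant and positive, and (2) the paired
#' t-test of boundary vs. non-boundary correlation is significant and
#' positive, both two-tailed and Bonferroni-corrected across parcels.
#'
#' @param r_boundary subjects x parcels matrix of mean boundary correlations
#'   (`a` for the within-recall map, `c` for the encoding-recall map).
#' @param r_nonboundary matching non-boundary matrix (`b` or `d`).
#' @param alpha family-wise error level (default 0.05).
#' @return logical vector over parcels with attributes `p_positive`,
#'   `p_paired`, `t_positive`, `t_paired`.
#' @export
conjunction_map <- function(r_boundary, r_nonboundary, alpha = 0.05) {
  if (nrow(r_boundary) < 2L) stop("need >= 2 subjects for a conjunction map")
  stopifnot(all(dim(r_boundary) == dim(r_nonboundary)))
  n_parcels <- ncol(r_boundary)
  t1 <- p1 <- t2 <- p2 <- numeric(n_parcels)
  for (p in seq_len(n_parcels)) {
    g1 <- one_sample_t(r_boundary[, p])
    g2 <- paired_t(r_boundary[, p], r_nonboundary[, p])
    t1[p] <- g1$t_stat; p1[p] <- g1$p_two_tailed
    t2[p] <- g2$t_stat; p2[p] <- g2$p_two_tailed
  }
  mask <- bonferroni_mask(p1, alpha) & bonferroni_mask(p2, alpha) & t1 > 0 & t2 > 0
  structure(mask, p_positive = p1, p_paired = p2, t_positive = t1, t_paired = t2)
}

#' Full 40 x 40 condition-by-condition similarity matrix
#'
#' Correlation matrix over all (phase, condition, movie) cells, computed per
#' subject and averaged across subjects that have both patterns of a cell.
#' Rows/columns are ordered encoding-boundary M1-10, encoding-non-boundary
#' M1-10, recall-boundary M1-10, recall-non-boundary M1-10.
#'
#' @param pattern_sets list of [build_pattern_set] results (one per subject).
#' @return symmetric 40 x 40 matrix with unit diagonal.
#' @export
full_condition_matrix <- function(pattern_sets) {
  labels <- as.vector(outer(paste0("M", 1:10), c("enc_boundary", "enc_nonboundary",
                                                 "rec_boundary", "rec_nonboundary"),
                            function(m, c) paste(c, m, sep = "_")))
  acc <- matrix(0, 40, 40, dimnames = list(labels, labels))
  cnt <- matrix(0L, 40, 40)
  for (ps in pattern_sets) {
    X <- cbind(ps$patterns$encoding$boundary, ps$patterns$encoding$nonboundary,
               ps$patterns$recall$boundary, ps$patterns$recall$nonboundary)
    C <- suppressWarnings(stats::cor(X))
    ok <- is.finite(C)
    acc[ok] <- acc[ok] + C[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Visual-feature control contrast
#'
#' Tests, per parcel, whether encoding boundary patterns are more similar to
#' recall boundary patterns than to recall non-boundary patterns (between
#' movies in both cases). Visual input is identical across recall boundary
#' and non-boundary periods, so a positive contrast cannot be explained by
#' shared visual features. Paired two-tailed t-tests, Bonferroni-corrected
#' across parcels.
#'
#' @param sims a [parcelwise_similarity] result.
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame with one row per parcel: `parcel`, `mean_diff`, `t`,
#'   `p`, `significant`.
#' @export
visual_control_contrast <- function(sims, alpha = 0.05) {
  n_parcels <- ncol(sims$c)
  t_stat <- p <- diff <- numeric(n_parcels)
  for (pi in seq_len(n_parcels)) {
    g <- paired_t(sims$c[, pi], sims$e[, pi])
    t_stat[pi] <- g$t_stat; p[pi] <- g$p_two_tailed; diff[pi] <- g$mean
  }
  data.frame(parcel = sims$parcels, mean_diff = diff, t = t_stat, p = p,
             significant = bonferroni_mask(p, alpha) & t_stat > 0)
}
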