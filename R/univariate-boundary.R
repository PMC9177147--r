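#' Per-subject univariate boundary contrast
#'
#' For each recalled movie, averages the preprocessed BOLD signal over the
#' TRs of the boundary period and of the non-boundary (mid-movie) period,
#' then averages over movies, and returns the per-vertex difference
#' (boundary minus non-boundary).
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param subject subject id.
#' @param spec a [window_spec].
#' @param phase phase to contrast (default `"recall"`).
#' @return numeric vector of per-vertex differences.
#' @export
subject_boundary_contrast <- function(experiment, subject, spec = window_spec(),
                                      phase = "recall") {
  ev <- subject_events(experiment$events, subject, phase)
  mv <- ev[ev$kind == "movie", , drop = FALSE]
  if (nrow(mv) == 0L) stop("subject ", subject, " has no recalled movies")
  bsum <- nsum <- 0
  for (i in seq_len(nrow(mv))) {
    run <- get_run(experiment, subject, phase, mv$run[i])
    label <- paste0("M", mv$movie_id[i])
    bw <- boundary_window(mv$offset_s[i], spec)
    mw <- middle_window(mv$onset_s[i], mv$offset_s[i], spec, label = label)
    bsum <- bsum + window_pattern(run, bw, label = label)
    nsum <- nsum + window_pattern(run, mw, label = label)
  }
  (bsum - nsum) / nrow(mv)
}

#' Boundary contrasts for all subjects
#'
#' @param experiment a preprocessed `boundary_experiment`.
#' @param spec a [window_spec].
#' @param phase phase to contrast (default `"recall"`).
#' @return vertices x subjects matrix.
#' @export
boundary_contrasts <- function(experiment, spec = window_spec(), phase = "recall") {
  subjects <- experiment_subjects(experiment)
  out <- vapply(subjects, function(s) subject_boundary_contrast(experiment, s, spec, phase),
                numeric(nrow(experiment$runs[[1]]$data)))
  colnames(out) <- subjects
  out
}

#' Group-level univariate boundary map
#'
#' Vertex-wise two-tailed one-sample t-tests of the boundary contrast against
#' zero, Benjamini-Hochberg corrected across vertices (FDR `q`). Surviving
#' vertices are grouped into connected components and components whose summed
#' surface area falls below `min_area_mm2` are removed. Connectivity is given
#' either by `vertex_parcel` (each parcel treated as a clique, the synthetic
#' default where no mesh exists) or by an explicit two-column edge matrix
#' `adjacency`.
#'
#' @param contrasts vertices x subjects matrix from [boundary_contrasts].
#' @param q false discovery rate (default 0.05).
#' @param min_area_mm2 minimum component surface area (default 16); 0 disables
#'   the filter.
#' @param vertex_parcel per-vertex parcel labels (clique connectivity).
#' @param adjacency two-column integer matrix of vertex-vertex edges.
#' @param vertex_area_mm2 per-vertex surface area (default 1).
#' @return data.frame of class `"group_stat_map"` with columns `vertex`,
#'   `effect`, `t`, `p`, `significant`.
#' @export
group_univariate_map <- function(contrasts, q = 0.05, min_area_mm2 = 16,
                                 vertex_parcel = NULL, adjacency = NULL,
                                 vertex_area_mm2 = NULL) {
  if (ncol(contrasts) < 2L) stop("need >= 2 subjects")
  nv <- nrow(contrasts)
  if (is.null(vertex_area_mm2)) vertex_area_mm2 <- rep(1, nv)
  st <- rowwise_t(contrasts)
  sig <- bh_mask(st$p, q)
  if (min_area_mm2 > 0 && any(sig)) {
    comp <- if (!is.null(adjacency)) {
      g <- igraph::graph_from_edgelist(cbind(as.integer(adjacency[, 1]),
                                             as.integer(adjacency[, 2])),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
      membership <- igraph::components(igraph::induced_subgraph(g, which(sig)))$membership
      split(which(sig), membership)
    } else if (!is.null(vertex_parcel)) {
      split(which(sig), vertex_parcel[sig])
    } else {
      stop("min_area_mm2 > 0 requires vertex_parcel or adjacency connectivity")
    }
    for (idx in comp) {
      if (sum(vertex_area_mm2[idx]) < min_area_mm2) sig[idx] <- FALSE
    }
  }
  out <- data.frame(vertex = seq_len(nv), effect = st$effect, t = st$t, p = st$p,
                    significant = sig)
  class(out) <- c("group_stat_map", "data.frame")
  out
}
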