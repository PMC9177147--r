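test_that("a complete subject yields 40 patterns; missing recalls are bookkept", {
  exp <- tiny_experiment()
  ps <- build_pattern_set(exp, "s01")
  expect_equal(ps$n_patterns, 40L)
  expect_false(anyNA(ps$patterns$recall$boundary))
  # a subject who recalled only 8 movies: 36 patterns, NA columns for the rest
  exp2 <- exp
  drop <- exp2$events$phase == "recall" & exp2$events$kind == "movie" &
    exp2$events$movie_id %in% c(4, 9)
  exp2$events <- exp2$events[!drop, ]
  ps2 <- build_pattern_set(exp2, "s01")
  expect_equal(ps2$n_patterns, 36L)
  expect_true(all(is.na(ps2$patterns$recall$boundary[, c(4, 9)])))
  a <- mean_between_movie_similarity(ps2, c("recall", "recall"), "boundary")
  expect_equal(attr(a, "n_pairs"), choose(8, 2))
  cc <- mean_between_movie_similarity(ps2, c("encoding", "recall"), "boundary")
  expect_equal(attr(cc, "n_pairs"), 10 * 8 - 8)
})

test_that("pair counts are 45 within phase and 90 across phases when complete", {
  exp <- tiny_experiment()
  ps <- build_pattern_set(exp, "s02")
  sm <- similarity_summary(ps)
  expect_equal(attr(sm$a, "n_pairs"), 45L)
  expect_equal(attr(sm$b, "n_pairs"), 45L)
  expect_equal(attr(sm$c, "n_pairs"), 90L)
  expect_equal(attr(sm$d, "n_pairs"), 90L)
})

test_that("similarity means equal the brute-force double loop", {
  exp <- tiny_experiment()
  ps <- build_pattern_set(exp, "s01")
  A <- ps$patterns$recall$boundary
  vals <- c()
  for (i in 1:9) for (j in (i + 1):10) vals <- c(vals, cor(A[, i], A[, j]))
  expect_equal(as.numeric(mean_between_movie_similarity(ps, c("recall", "recall"), "boundary")),
               mean(vals), tolerance = 1e-12)
  B <- ps$patterns$encoding$boundary
  vals <- c()
  for (i in 1:10) for (j in 1:10) if (i != j) vals <- c(vals, cor(B[, i], A[, j]))
  expect_equal(as.numeric(mean_between_movie_similarity(ps, c("encoding", "recall"), "boundary")),
               mean(vals), tolerance = 1e-12)
})

test_that("identical planted patterns give r = 1 and constants are rejected", {
  ps <- structure(list(subject = "x", vertices = 1:6, n_patterns = 40L,
                       patterns = list(recall = list(
                         boundary = matrix(rep(c(1, 4, 2, -1, 0, 3), 10), 6, 10),
                         nonboundary = matrix(1, 6, 10)))),
                  class = "pattern_set")
  expect_equal(as.numeric(mean_between_movie_similarity(ps, c("recall", "recall"), "boundary")), 1)
  expect_error(mean_between_movie_similarity(ps, c("recall", "recall"), "nonboundary"),
               "constant pattern")
})

test_that("similarity statistics are invariant to global scaling of a subject's data", {
  exp <- tiny_experiment()
  df1 <- similarity_result(exp)$per_subject
  exp2 <- exp
  for (id in names(exp2$runs)) {
    if (exp2$runs[[id]]$subject == "s01") exp2$runs[[id]]$data <- exp2$runs[[id]]$data * 3.7
  }
  df2 <- similarity_result(exp2)$per_subject
  expect_equal(df1[, c("a", "b", "c", "d")], df2[, c("a", "b", "c", "d")],
               tolerance = 1e-12)
})

test_that("the 40 x 40 condition matrix is symmetric with unit diagonal", {
  exp <- tiny_experiment()
  sets <- lapply(experiment_subjects(exp), function(s) build_pattern_set(exp, s))
  M <- full_condition_matrix(sets)
  expect_equal(dim(M), c(40, 40))
  expect_equal(unname(diag(M)), rep(1, 40))
  expect_lt(max(abs(M - t(M))), 1e-12)
  # noiseless boundary-only data: the boundary-boundary off-diagonal block is 1
  cfg <- tiny_config(noise_sd = 0, amp_content = 0, amp_event = 0, amp_silence_aud = 0)
  exp0 <- generate_experiment(cfg)
  bv <- which(exp0$runs[[1]]$vertex_parcel %in% cfg$boundary_parcels)
  sets0 <- lapply(experiment_subjects(exp0),
                  function(s) build_pattern_set(exp0, s, vertices = bv))
  M0 <- full_condition_matrix(sets0)
  bcells <- c(1:10, 21:30)    # encoding- and recall-boundary rows
  blk <- M0[bcells, bcells]
  expect_equal(unname(blk[upper.tri(blk)]), rep(1, sum(upper.tri(blk))),
               tolerance = 1e-6)
})

test_that("boundary bars dominate non-boundary bars when only the boundary is planted", {
  cfg <- signal_config(amp_content = 0.25, amp_event = 0, amp_silence_aud = 0)
  exp <- cached_experiment("boundary_only", cfg)
  res <- similarity_result(exp, region = cfg$boundary_parcels)
  expect_gt(mean(res$per_subject$a), 0.3)
  expect_gt(mean(res$per_subject$c), 0.3)
  # non-boundary similarity stays small (a mild positive bias remains because
  # run-wise normalisation leaks a shared component into mid-movie windows)
  expect_lt(abs(mean(res$per_subject$b)), 0.2)
  expect_lt(abs(mean(res$per_subject$d)), 0.2)
  expect_lt(res$tests$a_vs_b$p_two_tailed, 0.01)
})

test_that("conjunction and visual-control maps localise the planted parcels", {
  exp <- signal_experiment()
  sims <- parcelwise_similarity(exp)
  cm <- conjunction_map(sims$a, sims$b)
  planted <- exp$config$boundary_parcels
  expect_true(all(which(as.logical(cm)) %in%
                    c(planted, exp$config$aud_parcels)))
  expect_true(any(as.logical(cm)[planted]))
  vc <- visual_control_contrast(sims)
  expect_true(all(vc$parcel[vc$significant] %in% c(planted, exp$config$aud_parcels)))
  expect_error(conjunction_map(sims$a[1, , drop = FALSE], sims$b[1, , drop = FALSE]),
               ">= 2 subjects")
})
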