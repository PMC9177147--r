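test_that("regeneration with the same seed is bit-identical", {
  cfg <- tiny_config()
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(lapply(e1$runs, `[[`, "data"), lapply(e2$runs, `[[`, "data"))
  expect_identical(e1$events, e2$events)
  expect_identical(e1$envelopes, e2$envelopes)
})

test_that("planted patterns are unit-norm with the exact target correlation", {
  exp <- tiny_experiment()
  tr <- exp$truth
  expect_equal(sum(tr$p_bound^2), 1, tolerance = 1e-12)
  expect_equal(sum(tr$p_evt^2), 1, tolerance = 1e-12)
  expect_equal(sum(tr$p_sil^2), 1, tolerance = 1e-12)
  bv <- which(exp$runs[[1]]$vertex_parcel %in% exp$config$boundary_parcels)
  expect_equal(cor(tr$p_bound[bv], tr$p_evt[bv]), -0.3, tolerance = 1e-10)
  expect_equal(tr$realized_corr_event_boundary, -0.3, tolerance = 1e-10)
})

test_that("generated timelines respect the experimental design", {
  exp <- tiny_experiment()
  ev <- exp$events
  enc_titles <- ev[ev$phase == "encoding" & ev$kind == "title", ]
  expect_true(all(abs(enc_titles$offset_s - enc_titles$onset_s - 6) < 1e-9))
  # every encoding movie is immediately preceded by its title
  enc_mv <- ev[ev$phase == "encoding" & ev$kind == "movie", ]
  key <- paste(enc_mv$subject, enc_mv$run, enc_mv$movie_id)
  tkey <- paste(enc_titles$subject, enc_titles$run, enc_titles$movie_id)
  expect_equal(enc_mv$onset_s, enc_titles$offset_s[match(key, tkey)])
  # first stimulus begins 3 s after the first volume
  expect_equal(min(enc_titles$onset_s), 3)
  # 17 within-movie boundaries per subject, 15 surviving the 45-s rule at
  # the default (full-length) movie durations
  cfg <- ground_truth_config(n_subjects = 1, seed = 5)
  full <- generate_experiment(cfg)
  wb <- full$events[full$events$kind == "within_event_boundary", ]
  expect_equal(nrow(wb), 17)
  expect_equal(nrow(select_within_boundaries(full$events)), 15)
  # each subject recalls all 10 movies exactly once, with 9 pauses
  rec <- ev[ev$phase == "recall" & ev$subject == "s01", ]
  expect_setequal(rec$movie_id[rec$kind == "movie"], 1:10)
  expect_equal(sum(rec$kind == "pause"), 9)
  expect_true(all(rec$offset_s[rec$kind == "pause"] - rec$onset_s[rec$kind == "pause"] <= 60))
})

test_that("noiseless boundary-only signal yields perfectly consistent boundary patterns", {
  cfg <- tiny_config(noise_sd = 0, amp_content = 0, amp_event = 0,
                     amp_silence_aud = 0, amp_boundary = 0.5)
  exp <- generate_experiment(cfg)   # raw: z-scoring skipped for noiseless data
  bv <- which(exp$runs[[1]]$vertex_parcel %in% cfg$boundary_parcels)
  ps <- build_pattern_set(exp, "s01", vertices = bv)
  r <- mean_between_movie_similarity(ps, c("recall", "recall"), "boundary")
  expect_equal(as.numeric(r), 1, tolerance = 1e-6)
  # the pattern is the planted boundary topography itself
  pat <- ps$patterns$recall$boundary[, 1]
  expect_gt(abs(cosine(pat, exp$truth$p_bound[bv])), 0.999)
})

test_that("movie content leaves only HRF-tail traces in boundary windows", {
  cfg <- tiny_config(noise_sd = 0, amp_content = 0.5, amp_event = 0,
                     amp_silence_aud = 0, amp_boundary = 0.5)
  exp <- generate_experiment(cfg)
  bv <- which(exp$runs[[1]]$vertex_parcel %in% cfg$boundary_parcels)
  ps <- build_pattern_set(exp, "s01", vertices = bv)
  # last movie of encoding run 1: no following movie, only its own content tail
  pat <- ps$patterns$encoding$boundary[, 5]
  expect_gt(abs(cosine(pat, exp$truth$p_bound[bv])), 0.9)
})

test_that("audio envelopes are nonnegative, silent during titles, and dips are recoverable", {
  exp <- generate_experiment(tiny_config())
  for (id in names(exp$envelopes)) {
    env <- exp$envelopes[[id]]
    run <- exp$runs[[id]]
    expect_true(all(env >= 0))
    ev <- exp$events[exp$events$subject == run$subject &
                       exp$events$phase == "encoding" & exp$events$run == run$run, ]
    titles <- ev[ev$kind == "title", ]
    for (i in seq_len(nrow(titles))) {
      trs <- seconds_to_tr_range(titles$onset_s[i], titles$offset_s[i], run)
      expect_true(all(env[trs] == 0))
    }
  }
  # with the raw envelope, the silent set is exactly the planted dips beyond 45 s
  id <- "s01_encoding1"
  run <- trim_initial_volumes(exp$runs[[id]])
  env <- exp$envelopes[[id]]
  env <- env[-seq_len(length(env) - ncol(run$data))]
  mask <- silence_timepoints(env, exp$events, run)
  expect_equal(mask$threshold, 0)
  ev <- exp$events[exp$events$subject == "s01" & exp$events$phase == "encoding" &
                     exp$events$run == 1, ]
  mv <- ev[ev$kind == "movie", ]
  cfg <- exp$config
  expected <- sort(unlist(lapply(seq_len(nrow(mv)), function(i) {
    d <- mv$offset_s[i] - mv$onset_s[i]
    dip0 <- mv$onset_s[i] + cfg$dip_frac * d
    intersect(seconds_to_tr_range(dip0, min(dip0 + cfg$dip_s, mv$offset_s[i]), run),
              seconds_to_tr_range(mv$onset_s[i] + 45, mv$offset_s[i], run))
  })))
  expect_identical(mask$tr_idx, expected)
  expect_gt(length(expected), 0)
})

test_that("generator validates its configuration", {
  expect_error(ground_truth_config(amp_boundary = -1), "amplitudes")
  expect_error(ground_truth_config(corr_event_boundary = 1.2), "corr_event_boundary")
  expect_error(ground_truth_config(boundary_parcels = 1:4, aud_parcels = 4:5), "disjoint")
  expect_error(ground_truth_config(movie_durations_s = c(100, 200)), "10 movie durations")
})
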