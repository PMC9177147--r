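test_that("the 45-s carry-over exclusion keeps boundaries at or beyond 45 s", {
  mk <- function(times) {
    event_table(rbind(
      data.frame(subject = "s01", phase = "encoding", run = 1, movie_id = 1,
                 kind = "movie", onset_s = 10, offset_s = 210),
      data.frame(subject = "s01", phase = "encoding", run = 1, movie_id = 1,
                 kind = "within_event_boundary", onset_s = 10 + times,
                 offset_s = NA_real_)))
  }
  expect_equal(select_within_boundaries(mk(c(40, 50, 100)))$rel_s, c(50, 100))
  expect_equal(select_within_boundaries(mk(45))$rel_s, 45)   # >= convention
  empty <- mk(100)
  expect_equal(nrow(select_within_boundaries(empty[empty$kind == "movie", , drop = FALSE])), 0)
})

test_that("interval overlap detection matches the exclusion examples", {
  overlap <- boundarypattern:::intervals_overlap
  expect_true(overlap(c(100, 115), c(110.5, 125.5)))   # 4.5-s overlap
  expect_true(overlap(c(100, 115), c(101.5, 115)))     # 13.5-s overlap
  expect_false(overlap(c(100, 115), c(115, 130)))      # touching, no overlap
})

test_that("noiseless planted patterns are recovered exactly by the templates", {
  cfg <- tiny_config(noise_sd = 0, amp_content = 0, amp_silence_aud = 0)
  exp <- generate_experiment(cfg)
  ts <- build_templates(exp, "s01", region = cfg$boundary_parcels)
  bv <- ts$vertices
  expect_gt(abs(cosine(ts$within, exp$truth$p_evt[bv])), 0.999)
  sim <- template_similarity(ts)
  # orange deviates from 1 only by HRF-undershoot leakage of event responses
  expect_gt(sim$orange, 0.999)
  # the green correlation recovers the planted event/boundary correlation
  expect_equal(sim$green, -0.3, tolerance = 0.02)
  # with no event responses at all, the cross-phase template match is exact
  cfg2 <- tiny_config(noise_sd = 0, amp_content = 0, amp_silence_aud = 0,
                      amp_event = 0)
  exp2 <- generate_experiment(cfg2)
  ps2 <- build_templates(exp2, "s01", region = cfg2$boundary_parcels)
  expect_equal(cor(ps2$between$encoding, ps2$between$recall), 1, tolerance = 1e-9)
})

test_that("a single retained boundary makes the template that window's mean", {
  cfg <- tiny_config(noise_sd = 0, amp_content = 0, amp_silence_aud = 0)
  exp <- generate_experiment(cfg)
  ev <- exp$events
  keep_first <- which(ev$kind == "within_event_boundary" & ev$subject == "s01")[14]
  drop <- ev$kind == "within_event_boundary" & ev$subject == "s01" &
    seq_len(nrow(ev)) != keep_first
  exp1 <- exp
  exp1$events <- ev[!drop, ]
  ts <- build_templates(exp1, "s01", region = cfg$boundary_parcels)
  expect_equal(nrow(ts$retained), 1)
  run <- get_run(exp1, "s01", "encoding", ts$retained$run)
  win <- boundary_window(ts$retained$onset_s, window_spec())
  manual <- extract_mean_pattern(run, seconds_to_tr_range(win[1], win[2], run))[ts$vertices]
  expect_equal(ts$within, manual, tolerance = 1e-12)
})

test_that("within-movie boundary patterns are internally consistent on planted data", {
  cfg <- tiny_config(noise_sd = 0, amp_content = 0, amp_silence_aud = 0)
  exp <- generate_experiment(cfg)
  res <- within_movie_consistency(exp, region = cfg$boundary_parcels,
                                  inference = FALSE)
  expect_equal(res$per_subject$within_r, rep(1, 2), tolerance = 1e-6)
})

test_that("orange exceeds green across noise levels when the planted correlation < 1", {
  for (noise in c(0.5, 1, 2)) {
    cfg <- tiny_config(noise_sd = noise, seed = 31 + noise * 10)
    exp <- generate_experiment(cfg)
    exp <- preprocess_experiment(exp)
    ts <- template_similarity_stats(exp, region = cfg$boundary_parcels)
    expect_gt(mean(ts$per_subject$orange), mean(ts$per_subject$green))
  }
})

test_that("the short-window variant shifts the boundary-period windows", {
  spec45 <- window_spec(4.5, 4.5)
  expect_equal(boundary_window(100, spec45), c(104.5, 109))
  exp <- tiny_experiment()
  ts15 <- build_templates(exp, "s01", region = exp$config$boundary_parcels)
  ts45 <- build_templates(exp, "s01", spec = spec45,
                          region = exp$config$boundary_parcels)
  expect_false(isTRUE(all.equal(ts15$between$recall, ts45$between$recall)))
})
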