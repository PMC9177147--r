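test_that("the group map applies BH then the component-area filter", {
  set.seed(17)
  nv <- 30
  contrasts <- matrix(rnorm(nv * 10, sd = 0.2), nv, 10)
  contrasts[1:5, ] <- contrasts[1:5, ] + 1      # strong cluster in parcel 1
  contrasts[7, ] <- contrasts[7, ] + 1          # isolated vertex in parcel 2
  parcel <- rep(1:6, each = 5)
  area <- rep(8, nv); area[7] <- 4
  full <- group_univariate_map(contrasts, min_area_mm2 = 0, vertex_parcel = parcel,
                               vertex_area_mm2 = area)
  expect_true(all(full$significant[1:5]))
  expect_true(full$significant[7])
  # the 4-mm2 isolated vertex dies at min_area 16; the 40-mm2 cluster survives
  filt <- group_univariate_map(contrasts, min_area_mm2 = 16, vertex_parcel = parcel,
                               vertex_area_mm2 = area)
  expect_true(all(filt$significant[1:5]))
  expect_false(filt$significant[7])
  # the filter is monotone in min_area: raising it can only shrink the set
  prev <- full$significant
  for (m in c(16, 41)) {
    f <- group_univariate_map(contrasts, min_area_mm2 = m, vertex_parcel = parcel,
                              vertex_area_mm2 = area)
    expect_true(all(!f$significant | prev))
    prev <- f$significant
  }
  expect_error(group_univariate_map(contrasts, min_area_mm2 = 16), "connectivity")
  expect_error(group_univariate_map(contrasts[, 1, drop = FALSE]), ">= 2 subjects")
})

test_that("explicit vertex adjacency drives the component grouping", {
  set.seed(18)
  contrasts <- matrix(rnorm(6 * 10, sd = 0.1), 6, 10)
  contrasts[1:3, ] <- contrasts[1:3, ] + 2
  adj <- rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6))   # chain 1-2-3 and 4-5-6
  out <- group_univariate_map(contrasts, min_area_mm2 = 3, adjacency = adj)
  expect_true(all(out$significant[1:3]))
  out2 <- group_univariate_map(contrasts, min_area_mm2 = 4, adjacency = adj)
  expect_false(any(out2$significant))
})

test_that("the map is invariant to subject ordering", {
  exp <- signal_experiment()
  contrasts <- boundary_contrasts(exp)
  m1 <- group_univariate_map(contrasts, vertex_parcel = exp$runs[[1]]$vertex_parcel,
                             vertex_area_mm2 = exp$runs[[1]]$vertex_area_mm2)
  m2 <- group_univariate_map(contrasts[, rev(seq_len(ncol(contrasts)))],
                             vertex_parcel = exp$runs[[1]]$vertex_parcel,
                             vertex_area_mm2 = exp$runs[[1]]$vertex_area_mm2)
  expect_equal(m1$t, m2$t, tolerance = 1e-12)
  expect_identical(m1$significant, m2$significant)
})

test_that("planted boundary signal surfaces only in the carrier parcels", {
  exp <- signal_experiment()
  contrasts <- boundary_contrasts(exp)
  map <- group_univariate_map(contrasts, vertex_parcel = exp$runs[[1]]$vertex_parcel,
                              vertex_area_mm2 = exp$runs[[1]]$vertex_area_mm2)
  sig_parcels <- unique(exp$runs[[1]]$vertex_parcel[map$significant])
  expect_gt(sum(map$significant), 0)
  expect_true(all(sig_parcels %in% exp$config$boundary_parcels))
  # single-movie averaging identity: the contrast of a one-movie phase equals
  # that movie's window difference
  s <- experiment_subjects(exp)[1]
  ev <- exp$events
  keep <- !(ev$phase == "recall" & ev$kind == "movie" & ev$movie_id != 1)
  exp1 <- exp
  exp1$events <- ev[keep | ev$phase != "recall", ]
  con1 <- subject_boundary_contrast(exp1, s)
  mv <- ev[ev$phase == "recall" & ev$subject == s & ev$kind == "movie" & ev$movie_id == 1, ]
  run <- get_run(exp, s, "recall", mv$run)
  spec <- window_spec()
  manual <- extract_mean_pattern(run, seconds_to_tr_range(mv$offset_s + 4.5, mv$offset_s + 19.5, run)) -
    extract_mean_pattern(run, do.call(seconds_to_tr_range,
                                      c(as.list(middle_window(mv$onset_s, mv$offset_s, spec)), list(run))))
  expect_equal(con1, manual, tolerance = 1e-12)
})
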