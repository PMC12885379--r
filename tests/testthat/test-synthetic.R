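test_that("lifeact generator plants events recoverable by hand arithmetic", {
  sp <- trace_spec(20, baseline_level = 1, events = list(c(5, 4, 4)),
                   noise_sd = 0, background_level = 2)
  g <- gen_lifeact_trace(sp)
  corr <- background_subtract(g$trace)
  expect_equal(corr, c(rep(1, 4), rep(5, 4), rep(1, 12)))
  expect_equal(mean_threshold(corr), (16 * 1 + 4 * 5) / 20) # = 1.8
  expect_equal(g$truth$events$start_frame, 5)
  expect_equal(g$truth$events$end_frame, 8)

  # empty events: constant trace, zero-event truth
  g0 <- gen_lifeact_trace(trace_spec(10, events = list(), noise_sd = 0))
  expect_equal(length(unique(background_subtract(g0$trace))), 1L)
  expect_equal(nrow(g0$truth$events), 0L)
})

test_that("lifeact generator rejects overlapping events and planted spans are recovered", {
  expect_error(trace_spec(20, events = list(c(5, 4, 4), c(7, 4, 4))),
               "overlap")
  sp <- trace_spec(40, baseline_level = 1,
                   events = list(c(5, 4, 6), c(20, 12, 6)), noise_sd = 0)
  g <- gen_lifeact_trace(sp)
  ev <- trace_events(g$trace)
  expect_equal(ev$start_frame, c(5, 20))
  expect_equal(ev$end_frame, c(8, 31))
  expect_equal(ev$duration_min, c(20, 60))
  # matches the brute-force oracle on the emitted trace
  corr <- background_subtract(g$trace)
  o <- oracle_runs(corr > mean_threshold(corr), 4)
  expect_equal(ev$start_frame, o$start)
  expect_equal(ev$end_frame, o$end)
})

test_that("orthogonal profile generator places peaks as declared", {
  g <- gen_orth_profiles(-2, noise_sd = 0)
  expect_equal(g$truth$axon_center_um, 2)
  expect_equal(g$truth$boundary_center_um, 4)
  expect_lt(g$truth$axon_center_um, g$truth$boundary_center_um)
  expect_error(gen_orth_profiles(-5), "off the line")
  # degenerate tie case
  g0 <- gen_orth_profiles(0, noise_sd = 0)
  expect_equal(g0$truth$axon_center_um, g0$truth$boundary_center_um)
})

test_that("track generator plants exact drifts", {
  g <- gen_tracks(141, drift_um_per_frame = c(0, 0.05), jitter_sd = 0)
  expect_equal(g$track$y_um[141] - g$track$y_um[1], 7.0)
  g0 <- gen_tracks(50, drift_um_per_frame = c(0, 0), jitter_sd = 0)
  expect_equal(g0$truth$endpoint_distance_um, 0)
  g345 <- gen_tracks(141, drift_um_per_frame = c(3 / 140, 4 / 140),
                     jitter_sd = 0)
  expect_equal(g345$truth$endpoint_distance_um, 5)
  expect_equal(total_migration(g345$track, 1, 141)$distance_um, 5)
})

test_that("calcium generator calibrates planted z-amplitudes exactly", {
  cls <- calcium_classes(20, 5, 5)
  g <- gen_calcium(calcium_spec(cls, peak_amplitude_sd_units = 3,
                                noise_sd = 0))
  z <- zscore_cells(g$recording)
  rapid_cells <- cls$cell_id[cls$class == "rapid"]
  expect_equal(unname(z[rapid_cells, 16]), rep(3, length(rapid_cells)),
               tolerance = 1e-9)
  # all 30 spinal labels recovered from planted truth
  calls <- score_cells(g$recording)
  got <- c(rapid_synchronous = "rapid", delayed = "delayed",
           none = "none")[calls$category]
  expect_equal(unname(got), cls$class)
  # delayed first crossing at planted onset
  del <- cls$cell_id[cls$class == "delayed"]
  expect_equal(calls$first_active_frame[match(del, calls$cell_id)],
               cls$onset_frame[match(del, cls$cell_id)])
})

test_that("all-none calcium recording fails the DRG inclusion rule", {
  cls <- calcium_classes(0, 0, 30, n_drg = 1)
  cls$class[1] <- "none" # DRG itself never activates
  g <- gen_calcium(calcium_spec(cls))
  s <- summarize_animal(g$recording)
  expect_false(s$included)
  expect_equal(s$drg_rapid_count, 0)
})

test_that("behavior generator bookkeeping matches planted bouts", {
  sh <- gen_behavior_tracks(behavior_spec(bouts = list(
    list(start = 101, length = 200, kind = "shiver", amplitude = 1))))
  expect_equal(sum(sh$truth$shiver_frames[1:400]), 200)
  still <- gen_behavior_tracks(behavior_spec(bouts = list()))
  expect_equal(sum(still$truth$shiver_frames), 0)
  swim <- gen_behavior_tracks(behavior_spec(bouts = list(
    list(start = 1, length = 300, kind = "swim", net_speed = 1))))
  expect_equal(sum(swim$truth$shiver_frames), 0)
})

test_that("hcr generator respects mask, separation and truth count", {
  mask <- square_mask(1, 1, 10)
  g <- gen_hcr_image(12, mask, seed = 7)
  expect_equal(nrow(g$truth$centers), 12)
  expect_true(all(point_in_polygon(g$truth$centers$x_um,
                                   g$truth$centers$y_um, mask)))
  d <- as.matrix(stats::dist(g$truth$centers))
  diag(d) <- Inf
  expect_gte(min(d), 3 * 0.15)
  # mask too small for the separation rule
  expect_error(gen_hcr_image(500, square_mask(1, 1, 2), max_tries = 200),
               "too small")
  # zero puncta: flat image
  g0 <- gen_hcr_image(0, mask)
  expect_equal(length(unique(as.vector(g0$image))), 1L)
})

test_that("generators are bit-identical under identical seed and spec", {
  a <- gen_lifeact_trace(trace_spec(50, events = list(c(10, 5, 4)),
                                    noise_sd = 2, seed = 11))
  b <- gen_lifeact_trace(trace_spec(50, events = list(c(10, 5, 4)),
                                    noise_sd = 2, seed = 11))
  expect_identical(a, b)
  a <- gen_tracks(30, jitter_sd = 1, seed = 5)
  b <- gen_tracks(30, jitter_sd = 1, seed = 5)
  expect_identical(a, b)
  a <- gen_hcr_image(5, square_mask(1, 1, 8), poisson_noise = TRUE, seed = 3)
  b <- gen_hcr_image(5, square_mask(1, 1, 8), poisson_noise = TRUE, seed = 3)
  expect_identical(a, b)
  cls <- calcium_classes(10, 2, 3)
  a <- gen_calcium(calcium_spec(cls, noise_sd = 1, seed = 9))
  b <- gen_calcium(calcium_spec(cls, noise_sd = 1, seed = 9))
  expect_identical(a, b)
})
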