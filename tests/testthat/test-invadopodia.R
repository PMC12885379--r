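test_that("background subtraction preserves sign and errors on mismatch", {
  tr <- intensity_trace(values = c(10, 12), background = c(2, 2))
  expect_equal(background_subtract(tr), c(8, 10))
  tr <- intensity_trace(values = c(5, 5), background = c(5, 5))
  expect_equal(background_subtract(tr), c(0, 0))
  expect_error(intensity_trace(values = 1:3, background = 1:2))
})

test_that("mean threshold is the window mean and window_start shifts it", {
  corr <- c(rep(1, 4), rep(5, 4), rep(1, 12))
  expect_equal(mean_threshold(corr), 1.8)
  expect_equal(mean_threshold(corr, window_start = 5),
               mean(corr[5:20]))
  expect_equal(mean_threshold(rep(2, 6)), 2)
  expect_error(mean_threshold(corr, window_start = 21), "empty")
})

test_that("detect_events applies the >= 4 consecutive timepoints rule", {
  corr <- c(rep(1, 4), rep(5, 4), rep(1, 12))
  ev <- detect_events(corr, mean_threshold(corr), 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 5)
  expect_equal(ev$end_frame, 8)
  expect_equal(ev$duration_min, 20)
  # a 3-frame run is not an event
  corr3 <- c(rep(0, 5), rep(2, 3), rep(0, 12))
  expect_equal(nrow(detect_events(corr3, 1, 5)), 0L)
  # a 12-frame run is one 60-min event
  corr12 <- c(rep(0, 3), rep(2, 12), rep(0, 5))
  ev <- detect_events(corr12, 1, 5)
  expect_equal(ev$duration_min, 60)
  # strictness: frames exactly at threshold do not extend runs
  expect_equal(nrow(detect_events(rep(2, 10), 2, 5)), 0L)
  # boundary-touching runs are kept
  ev <- detect_events(c(rep(2, 6), rep(0, 4)), 1, 5)
  expect_equal(ev$start_frame, 1)
})

test_that("event calls are invariant under positive affine transforms", {
  set.seed(7)
  for (i in 1:25) {
    corr <- rnorm(60)
    thr <- mean_threshold(corr)
    base <- detect_events(corr, thr, 5)
    scaled <- corr * 3.7 + 12 # mean threshold co-transforms
    ev2 <- detect_events(scaled, mean_threshold(scaled), 5)
    expect_equal(base$start_frame, ev2$start_frame)
    expect_equal(base$end_frame, ev2$end_frame)
  }
  # adding a constant to both signal and background leaves events unchanged
  g <- gen_lifeact_trace(trace_spec(60, events = list(c(10, 6, 5)),
                                    noise_sd = 1, seed = 3))
  tr2 <- g$trace
  tr2$values <- tr2$values + 40
  tr2$background <- tr2$background + 40
  expect_equal(trace_events(g$trace), trace_events(tr2))
})

test_that("classify_event reproduces the printed stability bands", {
  expect_equal(classify_event(20), "transient")
  expect_equal(classify_event(35), "transient")
  expect_equal(classify_event(40), "intermediate")
  expect_equal(classify_event(45), "intermediate")
  expect_equal(classify_event(55), "intermediate")
  expect_equal(classify_event(60), "stable")
  expect_equal(classify_event(65), "stable")
  expect_error(classify_event(15), "not invadopodia")
  # partition of the 5-min-sampling duration lattice: no gaps, no overlap
  durs <- seq(20, 200, by = 5)
  cls <- classify_event(durs)
  expect_true(all(cls %in% c("transient", "intermediate", "stable")))
  expect_equal(max(durs[cls == "transient"]), 35)
  expect_equal(min(durs[cls == "stable"]), 60)
})

test_that("compile_events assigns at-DREZ by strict frame majority", {
  # event fully inside the at-DREZ block
  g <- gen_lifeact_trace(trace_spec(60, events = list(c(40, 6, 5)),
                                    noise_sd = 0, drez_arrival_frame = 30))
  ev <- trace_events(g$trace)
  expect_true(ev$at_drez)
  # event fully during navigation
  g2 <- gen_lifeact_trace(trace_spec(60, events = list(c(5, 6, 5)),
                                     noise_sd = 0, drez_arrival_frame = 30))
  expect_false(trace_events(g2$trace)$at_drez)
  # straddling: 3 of 6 frames at DREZ is not a strict majority
  g3 <- gen_lifeact_trace(trace_spec(60, events = list(c(27, 6, 5)),
                                     noise_sd = 0, drez_arrival_frame = 30))
  ev3 <- trace_events(g3$trace)
  expect_equal(ev3$frac_frames_at_drez, 0.5)
  expect_false(ev3$at_drez)
  # 4 of 6 is
  g4 <- gen_lifeact_trace(trace_spec(60, events = list(c(28, 6, 5)),
                                     noise_sd = 0, drez_arrival_frame = 30))
  expect_true(trace_events(g4$trace)$at_drez)

  comp <- compile_events(list(g$trace, g2$trace), "grp")
  expect_equal(comp$durations_all, c(30, 30))
  expect_equal(comp$durations_at_drez, 30)
  expect_true(all(comp$durations_at_drez %in% comp$durations_all))
})

test_that("compiled group means recover planted duration contrast", {
  # planted at-DREZ durations around the dcc+/- (69.4 min) vs DMSO
  # (41.0 min) contrast: ~14 vs ~8 frames at 5 min
  set.seed(21)
  mk_group <- function(mean_frames, n) {
    lapply(seq_len(n), function(i) {
      len <- max(4, round(rnorm(1, mean_frames, 1.5)))
      gen_lifeact_trace(trace_spec(
        200, events = list(c(60, len, 6)), noise_sd = 0,
        drez_arrival_frame = 40, seed = i))$trace
    })
  }
  dcc <- compile_events(mk_group(69.44 / 5, 7), "dcc")
  dmso <- compile_events(mk_group(41.04 / 5, 10), "dmso")
  expect_gt(mean(dcc$durations_at_drez), mean(dmso$durations_at_drez))
  expect_equal(mean(dcc$durations_at_drez), 69.44, tolerance = 0.15)
  expect_equal(mean(dmso$durations_at_drez), 41.04, tolerance = 0.15)
})

test_that("basal_width implements interpolated FWHM", {
  pos <- seq(0, 10, by = 0.25)
  # rectangular profile spanning 8 samples = 2 um
  v <- as.numeric(pos >= 3 & pos < 5)
  expect_equal(basal_width(v, pos)$width_um, 2)
  # Gaussian sigma = 1 um: closed form 2 sqrt(2 ln 2)
  posf <- seq(0, 20, by = 0.02)
  vg <- exp(-(posf - 10)^2 / 2)
  expect_equal(basal_width(vg, posf)$width_um, 2 * sqrt(2 * log(2)),
               tolerance = 1e-3)
  # flat profile flagged
  expect_true(is.na(basal_width(rep(1, 10), seq(0, 9))$width_um))
  # planted widths preserve ordering (invadopodia wide, filopodia narrow)
  widths <- c(0.5, 1, 2, 3)
  got <- vapply(widths, function(s) {
    basal_width(exp(-(posf - 10)^2 / (2 * s^2)), posf)$width_um
  }, 0)
  expect_true(all(diff(got) > 0))
})

test_that("detector equals the brute-force oracle on random traces", {
  set.seed(123)
  for (i in 1:500) {
    n <- sample(10:80, 1)
    corr <- rnorm(n)
    thr <- mean_threshold(corr)
    ev <- detect_events(corr, thr, 5)
    o <- oracle_runs(corr > thr, 4)
    expect_identical(ev$start_frame, o$start)
    expect_identical(ev$end_frame, o$end)
    # durations always multiples of the interval, >= 4 x interval
    expect_true(all(ev$duration_min %% 5 == 0))
    expect_true(all(ev$duration_min >= 20))
  }
})
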