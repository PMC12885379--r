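test_that("zscore_cells standardizes per cell with sample sd", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(10, 10, 10, 30))
  rec <- calcium_recording(m, c("drg", "spinal"), rt_frame = 2,
                           cold_frame = 3)
  z <- zscore_cells(rec)
  expect_equal(z["a", ], (m["a", ] - mean(m["a", ])) / sd(m["a", ]))
  # single-spike trace engineered to sit exactly 2 sample-SDs above its
  # mean: a 24-frame shape calibrated by the generator
  shape <- regenquant:::calibrate_calcium_shape(24, 16, 1, 0.8, 2)
  zr <- (shape - mean(shape)) / sd(shape)
  expect_equal(zr[16], 2, tolerance = 1e-9)
  # affine invariance
  z2 <- zscore_cells(calcium_recording(3 * m + 7, c("drg", "spinal"),
                                       rt_frame = 2, cold_frame = 3))
  expect_equal(unname(z), unname(z2))
  # constant trace flagged unanalyzable
  m2 <- rbind(a = c(1, 2, 3, 4), flat = rep(5, 4))
  expect_warning(z3 <- zscore_cells(calcium_recording(m2, c("drg", "spinal"),
                                                      rt_frame = 2,
                                                      cold_frame = 3)),
                 "unanalyzable")
  expect_true(all(is.na(z3["flat", ])))
  expect_equal(unname(attr(z3, "unanalyzable")), c(FALSE, TRUE))
})

test_that("classify_cell applies the inclusive z >= 2 schedule rules", {
  z <- rep(0, 24)
  # exactly 2.0 at the cold frame is rapid ("2.0 or more" is inclusive)
  z16 <- z; z16[16] <- 2.0
  expect_equal(classify_cell(z16, 16)$category, "rapid_synchronous")
  # first crossing at frame 18 is delayed
  z18 <- z; z18[18] <- 3
  call <- classify_cell(z18, 16)
  expect_equal(call$category, "delayed")
  expect_equal(call$first_active_frame, 18L)
  # never crossing is none
  expect_equal(classify_cell(rep(1.9, 24), 16)$category, "none")
  # pre-cold-only crossing: none for synchrony, flagged rt_responder
  zrt <- z; zrt[9] <- 4
  call <- classify_cell(zrt, 16)
  expect_equal(call$category, "none")
  expect_true(call$rt_responder)
  expect_equal(call$pre_cold_crossing, 9L)
})

test_that("summarize_animal computes percentages over analyzable spinal cells", {
  g <- gen_calcium(calcium_spec(calcium_classes(27, 2, 1)))
  s <- summarize_animal(g$recording)
  expect_equal(s$pct_spinal_rapid, 90)
  expect_equal(s$pct_spinal_delayed, 100 * 2 / 30)
  expect_equal(s$pct_spinal_none, 100 * 1 / 30)
  expect_equal(s$pct_spinal_rapid + s$pct_spinal_delayed + s$pct_spinal_none,
               100)
  expect_true(s$included)
  # 30/30 rapid
  g2 <- gen_calcium(calcium_spec(calcium_classes(30, 0, 0)))
  expect_equal(summarize_animal(g2$recording)$pct_spinal_rapid, 100)
})

test_that("category assignment is invariant under per-cell affine transforms", {
  cls <- calcium_classes(12, 9, 9)
  g <- gen_calcium(calcium_spec(cls, noise_sd = 0.5, seed = 4))
  base <- score_cells(g$recording)$category
  m <- g$recording$matrix
  set.seed(11)
  m2 <- m * runif(nrow(m), 0.1, 10) + rnorm(nrow(m), 0, 50)
  rec2 <- calcium_recording(m2, g$recording$roles)
  expect_equal(score_cells(rec2)$category, base)
})

test_that("planted categories recovered exhaustively over class mixes", {
  for (mix in list(c(30, 0, 0), c(0, 30, 0), c(0, 0, 30),
                   c(10, 10, 10), c(25, 3, 2), c(1, 1, 28))) {
    cls <- calcium_classes(mix[1], mix[2], mix[3])
    g <- gen_calcium(calcium_spec(cls, noise_sd = 0))
    calls <- score_cells(g$recording)
    got <- c(rapid_synchronous = "rapid", delayed = "delayed",
             none = "none")[calls$category]
    expect_equal(unname(got), cls$class)
  }
})

test_that("compare_groups runs pairwise Fisher tests on pooled counts", {
  mk_group <- function(n_rapid, n_delayed, n_none, seeds) {
    lapply(seeds, function(s) {
      g <- gen_calcium(calcium_spec(
        calcium_classes(n_rapid, n_delayed, n_none), seed = s))
      summarize_animal(g$recording, animal_id = paste0("a", s))
    })
  }
  same <- compare_groups(list(a = mk_group(20, 5, 5, 1),
                              b = mk_group(20, 5, 5, 2)))
  expect_equal(same$p_value, 1)
  expect_equal(c(same$rapid1, same$delayed1), c(20, 5))
  # extreme separation
  far <- compare_groups(list(a = mk_group(10, 0, 20, 1),
                             b = mk_group(0, 10, 20, 2)))
  expect_lt(far$p_value, 1e-4)
  expect_equal(far$p_value, oracle_fisher_p(10, 0, 0, 10))
  expect_error(compare_groups(list(a = list(), b = list())), "empty group")
})
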