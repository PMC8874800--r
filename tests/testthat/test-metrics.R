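test_that("range of motion recovers programmed excursions", {
  static <- matrix(1:3, 10, 3, byrow = TRUE)
  expect_equal(range_of_motion(static), 0)
  # straight excursion to 0.61 m on x and back
  x <- 0.61 * sin(seq(0, pi, length.out = 101))
  p <- cbind(x, 0, 0)
  expect_equal(range_of_motion(p, "x"), 0.61, tolerance = 1e-12)
  expect_equal(range_of_motion(p, "all"), 0.61, tolerance = 1e-12)
  expect_equal(range_of_motion(p, "y"), 0)
  # raw-coordinate reference measures distance from the frame origin
  p2 <- cbind(0.2 + x, 0, 0)
  expect_equal(range_of_motion(p2, "x", reference = "origin"), 0.81,
               tolerance = 1e-12)
  # brute-force max oracle on a random walk
  set.seed(3)
  rw <- matrix(cumsum(stats::rnorm(300, sd = 0.01)), 100, 3)
  expect_equal(range_of_motion(rw, "z"),
               max(abs(rw[, 3] - rw[1, 3])), tolerance = 1e-12)
  expect_error(range_of_motion(rw[0, ]), "empty")
})

test_that("mean speed matches constant and analytic profiles", {
  dt <- 1 / 89
  t <- seq(0, 1, by = dt)
  expect_equal(mean_speed(cbind(0.86 * t, 0, 0), dt), 0.86, tolerance = 1e-12)
  expect_equal(mean_speed(matrix(0.5, 50, 3), dt), 0)
  # half-sine speed profile with peak v: mean = 2v/pi
  v <- 1.3
  x <- cumsum(c(0, v * sin(pi * t[-1]) * dt))
  expect_equal(mean_speed(cbind(x, 0, 0), dt), 2 * v / pi, tolerance = 0.01)
})

test_that("smoothness is mean over max speed with analytic oracles", {
  dt <- 1 / 89
  t <- seq(0, 1, by = dt)
  expect_equal(smoothness(cbind(t, 0, 0), dt), 1, tolerance = 1e-12)
  # half-sine: mean/max = 2/pi
  x <- cumsum(c(0, sin(pi * t[-1]) * dt))
  expect_equal(smoothness(cbind(x, 0, 0), dt), 2 / pi, tolerance = 0.01)
  expect_equal(smoothness(cbind(x, 0, 0), dt, reciprocal = TRUE), pi / 2,
               tolerance = 0.01)
  # a single step among N zero-steps gives 1/N
  p <- cbind(c(rep(0, 10), rep(1, 10)), 0, 0)
  expect_equal(smoothness(p, dt), 1 / 19, tolerance = 1e-12)
  expect_warning(sm <- smoothness(matrix(1, 5, 3), dt), "undefined")
  expect_true(is.na(sm))
})

test_that("smoothness is invariant to time rescaling, speed and path scale", {
  set.seed(8)
  p <- matrix(cumsum(stats::rnorm(150, sd = 0.01)), 50, 3)
  expect_equal(smoothness(p, 0.01), smoothness(p, 0.05), tolerance = 1e-12)
  expect_equal(mean_speed(3 * p, 0.01), 3 * mean_speed(p, 0.01),
               tolerance = 1e-12)
  expect_equal(path_length(3 * p), 3 * path_length(p), tolerance = 1e-12)
})

test_that("path length sums consecutive distances and beats ROM out-and-back", {
  expect_equal(path_length(matrix(0.3, 8, 3)), 0)
  # straight 0.5 m segment regardless of sampling density
  for (n in c(5, 50, 500)) {
    p <- cbind(seq(0, 0.5, length.out = n), 0, 0)
    expect_equal(path_length(p), 0.5, tolerance = 1e-12)
  }
  # out-and-back along 0.4 m: path 0.8 exceeds the 0.4 range of motion
  x <- c(seq(0, 0.4, length.out = 21), seq(0.4, 0, length.out = 21)[-1])
  p <- cbind(x, 0, 0)
  expect_equal(path_length(p), 0.8, tolerance = 1e-12)
  expect_equal(range_of_motion(p, "x"), 0.4, tolerance = 1e-12)

  # superadditive under concatenation up to the join step
  set.seed(9)
  a <- matrix(cumsum(stats::rnorm(60, sd = 0.01)), 20, 3)
  b <- matrix(cumsum(stats::rnorm(60, sd = 0.01)), 20, 3)
  join <- sqrt(sum((b[1, ] - a[20, ])^2))
  expect_gte(path_length(rbind(a, b)) + 1e-12,
             path_length(a) + path_length(b))
  expect_lte(path_length(rbind(a, b)),
             path_length(a) + path_length(b) + join + 1e-12)
})

truth_segments <- function(sim) {
  tr <- sim$truth$repetitions
  data.frame(start = tr$out_start - 1L, end = tr$ret_end,
             out_start = tr$out_start - 1L, out_end = tr$out_end,
             ret_start = tr$ret_start - 1L, ret_end = tr$ret_end,
             class = tr$class, repetition = tr$repetition)
}

test_that("per-movement summary matches a group-by oracle", {
  sim <- generate_calibration_session(clean_params(), reps = 2, seed = 4)
  tab <- assemble_variable_table(sim$session)
  seg <- truth_segments(sim)
  res <- summarize_metrics(tab, seg)
  expect_identical(nrow(res$summary), 10L)   # 5 classes x 2 hands
  expect_identical(nrow(res$per_segment), 20L)

  # identical noise-free repetitions: SD 0, mean equals the metric
  expect_true(all(res$summary$range_of_motion_sd < 1e-9))
  one <- res$per_segment[res$per_segment$class == "flexion_up" &
                           res$per_segment$hand == "right", ]
  srow <- res$summary[res$summary$class == "flexion_up" &
                        res$summary$hand == "right", ]
  expect_equal(srow$mean_speed_mean, mean(one$mean_speed), tolerance = 1e-12)

  # programmed amplitude recovery: flexion_up reaches 0.6 m up with a
  # 0.15 m forward arc -> 3-D amplitude sqrt(0.6^2 + 0.15^2)
  expect_equal(srow$range_of_motion_mean, sqrt(0.6^2 + 0.15^2),
               tolerance = 0.02)
  # one-way minimum-jerk mean speed ~ amplitude / duration
  expect_equal(srow$mean_speed_mean, sqrt(0.6^2 + 0.15^2) / 0.7,
               tolerance = 0.05)
  # minimum-jerk smoothness: mean/max = 1/1.875
  expect_equal(srow$smoothness_mean, 1 / 1.875, tolerance = 0.02)
  # single segment per class: SD reported as 0
  sim1 <- generate_calibration_session(clean_params(), reps = 1, seed = 4)
  res1 <- summarize_metrics(assemble_variable_table(sim1$session),
                            truth_segments(sim1))
  expect_true(all(res1$summary$smoothness_sd == 0))
})

test_that("impairment degrades the affected arm's metrics as programmed", {
  healthy <- generate_impaired_session(clean_params(), reps = 1, seed = 6,
                                       side = "left", amplitude_factor = 1,
                                       submovements = 1)
  impaired <- generate_impaired_session(clean_params(), reps = 1, seed = 6,
                                        side = "left", amplitude_factor = 0.5,
                                        submovements = 3)
  # amplitude factor 1 / single submovement reproduces the healthy generator
  base <- generate_calibration_session(clean_params(), reps = 1, seed = 6)
  expect_equal(healthy$session$left$x, base$session$left$x, tolerance = 1e-12)

  mh <- summarize_metrics(assemble_variable_table(healthy$session),
                          truth_segments(healthy))$summary
  mi <- summarize_metrics(assemble_variable_table(impaired$session),
                          truth_segments(impaired))$summary
  left_h <- mh[mh$hand == "left", ]; left_i <- mi[mi$hand == "left", ]
  right_i <- mi[mi$hand == "right", ]
  # affected arm: halved range of motion, intact arm untouched
  expect_equal(left_i$range_of_motion_mean, left_h$range_of_motion_mean / 2,
               tolerance = 0.02)
  expect_equal(right_i$range_of_motion_mean,
               mh[mh$hand == "right", ]$range_of_motion_mean,
               tolerance = 0.02)
  # segmented 3-subpeak profile is strictly less smooth than minimum jerk
  expect_true(all(left_i$smoothness_mean < left_h$smoothness_mean))
})
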