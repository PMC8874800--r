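test_that("default feature spec yields exactly 21 named features", {
  spec <- feature_spec()
  expect_identical(spec$window_length, 13L)
  expect_identical(length(feature_names(spec)), 21L)
  expect_identical(anyDuplicated(feature_names(spec)), 0L)
  expect_identical(sum(startsWith(feature_names(spec), "mean_")), 12L)
  expect_identical(sum(startsWith(feature_names(spec), "sd_")), 6L)
  expect_identical(sum(startsWith(feature_names(spec), "cor_")), 3L)
})

test_that("window labels follow the mode with earliest-occurrence ties", {
  expect_identical(window_label(rep("flexion_up", 13)), "flexion_up")
  # 7 no-movement vs 6 gesture steps: majority wins
  expect_identical(window_label(c(rep("no_movement", 7), rep("flexion_up", 6))),
                   "no_movement")
  expect_identical(window_label(c(rep("flexion_up", 7), rep("no_movement", 6))),
                   "flexion_up")
  # 5/5/3 three-class window: earliest-occurring of the tied pair
  w <- c(rep("b", 5), rep("a", 5), rep("c", 3))
  expect_identical(window_label(w), "b")
  expect_error(window_label(character(0)), "empty")

  # exhaustive small-window enumeration against a counting oracle
  set.seed(17)
  for (i in 1:300) {
    w <- sample(c("a", "b", "c"), 13, replace = TRUE)
    counts <- table(w)
    top <- names(counts)[counts == max(counts)]
    oracle <- top[which.min(vapply(top, function(cl) match(cl, w), 1L))]
    expect_identical(window_label(w), oracle)
  }
})

test_that("window features match independent recomputation", {
  sim <- generate_gesture("abduction_right", reps = 1, seed = 19)
  tab <- assemble_variable_table(sim$session)
  spec <- feature_spec()
  slice <- tab[101:113, ]
  f <- window_features(slice, spec)
  expect_identical(length(f), 21L)
  # independent oracle: plain colwise stats
  for (v in spec$mean_vars)
    expect_equal(unname(f[paste0("mean_", v)]), mean(slice[[v]]),
                 tolerance = 1e-12)
  for (v in spec$sd_vars)
    expect_equal(unname(f[paste0("sd_", v)]), stats::sd(slice[[v]]),
                 tolerance = 1e-12)
  expect_equal(unname(f["cor_gamma_H_R__gamma_H_L"]),
               stats::cor(slice$gamma_H_R, slice$gamma_H_L),
               tolerance = 1e-12)
  expect_true(all(abs(f[startsWith(names(f), "cor_")]) <= 1))

  # constant window: SDs zero, correlations flagged zero
  const <- tab[rep(1, 13), ]
  fc <- window_features(const, spec)
  expect_true(all(fc[startsWith(names(fc), "sd_")] == 0))
  expect_true(all(fc[startsWith(names(fc), "cor_")] == 0))
  expect_identical(length(attr(fc, "degenerate_cor")), 3L)

  # identical angle series across hands: correlation exactly 1
  twin <- slice
  twin$gamma_H_L <- twin$gamma_H_R
  expect_equal(unname(window_features(twin, spec)["cor_gamma_H_R__gamma_H_L"]),
               1, tolerance = 1e-12)
  expect_error(window_features(tab[1:7, ], spec), "exactly 13")
})

test_that("mean features are translation-equivariant, SD/cor invariant", {
  sim <- generate_gesture("push_forward", reps = 1, seed = 20)
  tab <- assemble_variable_table(sim$session)
  slice <- tab[51:63, ]
  shifted <- slice
  for (v in feature_spec()$mean_vars) shifted[[v]] <- shifted[[v]] + 0.77
  f0 <- window_features(slice); f1 <- window_features(shifted)
  expect_equal(unname(f1[1:12]), unname(f0[1:12] + 0.77), tolerance = 1e-9)
  expect_equal(f1[13:21], f0[13:21], tolerance = 1e-9)
})

test_that("sliding dataset has N - 12 aligned rows matching the per-window oracle", {
  sim <- generate_gesture("extension_down", reps = 2, seed = 21)
  tab <- assemble_variable_table(sim$session)
  ds <- build_window_dataset(tab)
  expect_identical(nrow(ds), nrow(tab) - 12L)
  expect_identical(ds$window_start, seq_len(nrow(ds)))

  # N = 13 -> exactly one window
  one <- build_window_dataset(tab[1:13, ], labels = attr(tab, "labels")[1:13])
  expect_identical(nrow(one), 1L)
  # N = 100 -> 88 windows
  expect_identical(nrow(build_window_dataset(tab[1:100, ],
                                             labels = attr(tab, "labels")[1:100])),
                   88L)

  # vectorised features and labels agree with the single-window path
  labels <- attr(tab, "labels")
  set.seed(22)
  for (i in sample(nrow(ds), 40)) {
    slice <- tab[i:(i + 12), ]
    f <- window_features(slice)
    expect_equal(unlist(ds[i, names(f)]), f, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_identical(as.character(ds$class[i]),
                     window_label(labels[i:(i + 12)]))
  }

  # shifting the session shifts all windows
  ds_shift <- build_window_dataset(tab[6:nrow(tab), ],
                                   labels = labels[6:length(labels)])
  expect_equal(as.matrix(ds_shift[1:50, feature_names()]),
               as.matrix(ds[6:55, feature_names()]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_window_dataset(tab, labels = NULL), "labels")
})
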