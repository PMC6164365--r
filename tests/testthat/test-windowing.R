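test_that("adaptive window plans stretch the shift to tile the segment", {
  p <- plan_windows(50, 8, 4)
  expect_identical(p$count, 13L)
  expect_equal(p$T_S_exact, 3.5)
  expect_equal(tail(p$starts, 1), 42)

  expect_identical(plan_windows(3, 8, 4)$count, 0L)

  p8 <- plan_windows(8, 8, 4)
  expect_identical(p8$count, 1L)
  expect_equal(p8$starts, 0)

  p16 <- plan_windows(16, 8, 4)
  expect_identical(p16$count, 4L)
  expect_equal(p16$starts, c(0, 8 / 3, 16 / 3, 8))

  expect_error(plan_windows(-5, 8, 4), class = "fitfuse_validation_error")
  expect_error(plan_windows(20, 4, 8), class = "fitfuse_validation_error")
})

test_that("window plans tile any segment exactly with equal shifts", {
  set.seed(19)
  for (T_E in c(runif(40, 8.01, 200), 8.5, 12, 100)) {
    p <- plan_windows(T_E, 8, 4)
    expect_identical(p$count, as.integer(ceiling(T_E / 4)))
    expect_equal(p$starts[1], 0)
    expect_equal(tail(p$starts, 1), T_E - 8, tolerance = 1e-9)
    if (p$count > 2) {
      expect_lt(max(abs(diff(p$starts) - p$T_S_exact)), 1e-9)
      expect_lte(p$T_S_exact, 4 + 1e-9)
    }
  }
})

test_that("movement extrema sit at the endpoints of a periodic swing", {
  rate <- 125
  t <- (0:(8 * rate - 1)) / rate
  theta <- (pi / 4) * (1 - cos(2 * pi * 0.5 * t))   # 0.5 Hz, swing pi/2
  acc <- fitfuse:::rotate_about(c(0, -1, 0), c(1, 0, 0), theta)
  ex <- movement_extrema(acc, rate)
  expect_gte(length(ex$idx), 6)
  expect_lte(length(ex$idx), 9)
  far <- fitfuse:::rotate_about(c(0, -1, 0), c(1, 0, 0), pi / 2)[1, ]
  d_rest <- sqrt(rowSums(sweep(ex$accel, 2, c(0, -1, 0))^2))
  d_far <- sqrt(rowSums(sweep(ex$accel, 2, far)^2))
  expect_true(all(pmin(d_rest, d_far) < 0.1))

  expect_length(movement_extrema(matrix(0.5, 1000, 3), rate)$idx, 0)

  # a single swing out and back still yields a peak at the far endpoint
  theta_half <- (pi / 4) * (1 - cos(2 * pi * t / 8))
  acc_half <- fitfuse:::rotate_about(c(0, -1, 0), c(1, 0, 0), theta_half)
  ex_half <- movement_extrema(acc_half, rate)
  expect_gte(length(ex_half$idx), 1)
  expect_lt(min(sqrt(rowSums(sweep(ex_half$accel, 2, far)^2))), 0.1)
})

test_that("endpoint clustering recovers the two generating centers", {
  set.seed(23)
  c_rest <- c(0, -1, 0); c_up <- c(0, 0, 1)
  peaks <- rbind(matrix(rnorm(15, 0, 0.02), 5, 3) + rep(c_rest, each = 5),
                 matrix(rnorm(15, 0, 0.02), 5, 3) + rep(c_up, each = 5))
  cl <- cluster_endpoints(peaks)
  expect_false(is.null(cl))
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(min(d(cl$a, c_rest), d(cl$a, c_up)), 0.05)
  expect_lt(min(d(cl$b, c_rest), d(cl$b, c_up)), 0.05)
  expect_gt(d(cl$a, cl$b), 0.5)

  expect_null(cluster_endpoints(peaks[1, , drop = FALSE]))
  expect_null(cluster_endpoints(matrix(0.3, 10, 3)))
  # two clouds closer than the separation floor are degenerate too
  tight <- rbind(matrix(rnorm(30, 0, 0.001), 10, 3))
  expect_null(cluster_endpoints(tight))
})

test_that("cluster ordering puts the rest-side endpoint first", {
  oc <- order_clusters(c(0, -1, 0), c(0, 0, 1), g_hat = c(0, -1, 0))
  expect_equal(oc$c1, c(0, -1, 0))
  oc_sw <- order_clusters(c(0, 0, 1), c(0, -1, 0), g_hat = c(0, -1, 0))
  expect_equal(oc_sw$c1, oc$c1)
  expect_equal(oc_sw$c2, oc$c2)
  expect_error(order_clusters(c(0, -1, 0), c(0, 0, 1), c(0, 0, 0)),
               class = "fitfuse_validation_error")
})

test_that("rotation vector encodes the axis and angle between endpoints", {
  r <- rotation_vector(c(0, -1, 0), c(0, 0, 1))
  expect_equal(r, (pi / 2) * c(-1, 0, 0), tolerance = 1e-12)

  expect_equal(rotation_vector(c(0, -2, 0), c(0, -2, 0)), c(0, 0, 0))

  # antisymmetry: swapping the endpoints flips the axis, keeps the angle
  set.seed(31)
  for (i in 1:20) {
    c1 <- rnorm(3); c1 <- c1 / sqrt(sum(c1^2))
    ax <- rnorm(3); ax <- ax - sum(ax * c1) * c1; ax <- ax / sqrt(sum(ax^2))
    theta <- runif(1, 0.05, 3.0)
    c2 <- fitfuse:::rotate_about(c1, ax, theta)[1, ]
    r12 <- rotation_vector(c1, c2)
    expect_equal(sqrt(sum(r12^2)), theta, tolerance = 1e-9)
    expect_equal(r12 / theta, ax, tolerance = 1e-9)
    expect_equal(rotation_vector(c2, c1), -r12, tolerance = 1e-9)
  }

  # antiparallel endpoints resolve deterministically to angle pi
  r_anti <- rotation_vector(c(0, -1, 0), c(0, 1, 0))
  expect_equal(sqrt(sum(r_anti^2)), pi)
  expect_equal(r_anti, rotation_vector(c(0, -1, 0), c(0, 1, 0)))

  expect_error(rotation_vector(c(0, 0, 0), c(1, 0, 0)),
               class = "fitfuse_validation_error")
})

test_that("envelope window features follow the closed forms", {
  rate <- 125
  e_const <- rep(1, 8 * rate)
  f <- emg_window_features(e_const, rate)
  expect_equal(f$m, 1)
  expect_equal(f$z, 1)

  t <- (0:(8 * rate - 1)) / rate
  e_sin <- 1 + sin(2 * pi * 0.5 * t)
  f <- emg_window_features(e_sin, rate)
  expect_equal(f$m, 1, tolerance = 0.02)
  expect_equal(f$p, 2, tolerance = 0.02)
  expect_equal(f$z, 2, tolerance = 0.04)
  expect_equal(f$z, f$p / f$m)

  # z is invariant to channel gain
  f_scaled <- emg_window_features(37.5 * e_sin, rate)
  expect_equal(f_scaled$z, f$z, tolerance = 1e-12)

  expect_error(emg_window_features(numeric(1000), rate),
               class = "fitfuse_validation_error")
})

test_that("feature extraction honours the window plan and the active set", {
  profs <- subject_profiles(1, seed = 13)
  rec <- generate_recording(profs[[1]], sets_per_class = 1,
                            set_duration_s = 21, gap_s = 3, seed = 13)
  rec_p <- preprocess_recording(rec, small_filters())
  feats <- extract_features(rec_p)

  # FR segments contribute nothing under the default active set
  expect_false("FR" %in% feats$label)
  per_seg <- table(feats$segment_idx)
  for (si in as.integer(names(per_seg))) {
    T_E <- rec$segments$end_s[si] - rec$segments$start_s[si]
    expect_identical(as.integer(per_seg[[as.character(si)]]),
                     plan_windows(T_E)$count)
  }

  # keeping all classes brings FR back
  feats_all <- extract_features(rec_p, classes = NULL)
  expect_true("FR" %in% feats_all$label)
  expect_identical(ncol(feats), 19L)
  expect_identical(names(feats)[5:13], acc_feature_names())
  expect_identical(names(feats)[14:19], emg_feature_names())

  empty <- make_tiny_recording(segment_table())
  empty_p <- preprocess_recording(empty, small_filters())
  expect_identical(nrow(extract_features(empty_p)), 0L)

  expect_error(extract_features(rec), "preprocess",
               class = "fitfuse_validation_error")
})
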