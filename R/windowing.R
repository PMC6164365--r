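# Segment-adaptive windowing and per-window feature extraction.
#
# Each labeled segment of duration T_E is sliced into overlapping windows of
# fixed length T_W (default 8 s) shifted by approximately T_S (default 4 s);
# the exact shift is stretched so that a whole number of windows exactly tiles
# the segment. Per window the features are: the rotation vector r (axis-angle
# summary of the periodic arm swing, from the filtered acceleration) for each
# node, and the normalized-envelope mean m and peak-to-mean ratio z = p/m for
# each node's sEMG.

#' Plan the adaptive windows of one segment
#'
#' For a segment of duration `T_E`, the number of windows is
#' `ceiling(T_E / T_S)` and the exact shift is `(T_E - T_W) / (count - 1)`,
#' so that the first window starts at 0 and the last ends exactly at `T_E`.
#' Segments shorter than `T_W` produce no windows; a segment of exactly `T_W`
#' produces one.
#'
#' @param T_E Segment duration in seconds.
#' @param T_W Window length in seconds (default 8).
#' @param T_S Nominal window shift in seconds (default 4); must not exceed
#'   `T_W`.
#' @return An object of class `window_plan` with fields `count`, `starts`,
#'   `T_W`, `T_S_nominal`, `T_S_exact` (`NA` when fewer than 2 windows).
#' @export
plan_windows <- function(T_E, T_W = 8, T_S = 4) {
  assert_that(is_scalar_number(T_E) && T_E > 0, "T_E must be > 0")
  assert_that(is_scalar_number(T_W) && T_W > 0, "T_W must be > 0")
  assert_that(is_scalar_number(T_S) && T_S > 0, "T_S must be > 0")
  assert_that(T_W >= T_S, "window length T_W must be >= shift T_S")
  if (T_E < T_W - 1e-9) {
    count <- 0L
    starts <- numeric(0)
    shift <- NA_real_
  } else {
    count <- as.integer(ceiling(T_E / T_S - 1e-12))
    if (count >= 2) {
      shift <- (T_E - T_W) / (count - 1)
      if (shift <= 1e-12) {          # T_E == T_W: a single window fits exactly
        count <- 1L
        shift <- NA_real_
        starts <- 0
      } else {
        starts <- (seq_len(count) - 1) * shift
      }
    } else {
      count <- 1L
      shift <- NA_real_
      starts <- 0
    }
  }
  structure(list(count = count, starts = starts, T_W = T_W,
                 T_S_nominal = T_S, T_S_exact = shift),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> %d window(s) of %g s, exact shift %s s\n",
              x$count, x$T_W,
              if (is.na(x$T_S_exact)) "-" else format(x$T_S_exact)))
  invisible(x)
}

# Local maxima of a signal with a prominence floor and a minimum distance,
# enforced greedily from the highest peak down.
find_peaks <- function(x, min_dist, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    l <- i; lo_l <- x[i]
    while (l > 1 && x[l] <= x[i]) { l <- l - 1L; lo_l <- min(lo_l, x[l]) }
    r <- i; lo_r <- x[i]
    while (r < n && x[r] <= x[i]) { r <- r + 1L; lo_r <- min(lo_r, x[r]) }
    base_l <- if (x[l] > x[i]) lo_l else min(x[seq.int(1, i)])
    base_r <- if (x[r] > x[i]) lo_r else min(x[seq.int(i, n)])
    x[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  if (!length(keep)) return(integer(0))
  keep <- keep[order(x[keep], decreasing = TRUE)]
  taken <- integer(0)
  for (i in keep) {
    if (!length(taken) || all(abs(taken - i) >= min_dist)) taken <- c(taken, i)
  }
  sort(taken)
}

#' Locate the extrema of the arm movement within a window
#'
#' Detrends the filtered acceleration window (subtracts its time average) and
#' finds the local maxima of the Euclidean norm of the detrended signal: for a
#' periodic swing these occur at the movement endpoints. Peaks must be at
#' least `min_dist_s` apart and have prominence at least `prominence_frac`
#' times the window's maximum norm.
#'
#' @param acc_win Numeric matrix (samples x 3) of filtered acceleration, g.
#' @param rate_hz Sampling rate of the window.
#' @param min_dist_s Minimum inter-peak distance, seconds (default 0.5).
#' @param prominence_frac Prominence floor as a fraction of the window maximum
#'   (default 0.1).
#' @return List with `idx` (peak sample indices), `t_s` (times within the
#'   window) and `accel` (the filtered acceleration vectors at the peaks, one
#'   row per peak). May be empty.
#' @export
movement_extrema <- function(acc_win, rate_hz, min_dist_s = 0.5,
                             prominence_frac = 0.1) {
  acc_win <- as.matrix(acc_win)
  d <- sweep(acc_win, 2, colMeans(acc_win))
  nd <- sqrt(rowSums(d^2))
  top <- max(nd)
  if (top <= 0) {
    return(list(idx = integer(0), t_s = numeric(0),
                accel = matrix(0, 0, 3)))
  }
  idx <- find_peaks(nd, min_dist = min_dist_s * rate_hz,
                    min_prom = prominence_frac * top)
  list(idx = idx, t_s = (idx - 1) / rate_hz,
       accel = acc_win[idx, , drop = FALSE])
}

# Deterministic 2-means (Lloyd) with farthest-pair initialization.
two_means <- function(x, max_iter = 50) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  far <- arrayInd(which.max(d2), dim(d2))
  if (d2[far] <= 1e-24) return(NULL)
  centers <- x[c(far[1], far[2]), , drop = FALSE]
  for (it in seq_len(max_iter)) {
    da <- rowSums(sweep(x, 2, centers[1, ])^2)
    db <- rowSums(sweep(x, 2, centers[2, ])^2)
    grp <- ifelse(da <= db, 1L, 2L)
    if (!any(grp == 1L) || !any(grp == 2L)) return(NULL)
    new_centers <- rbind(colMeans(x[grp == 1L, , drop = FALSE]),
                         colMeans(x[grp == 2L, , drop = FALSE]))
    if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
    centers <- new_centers
  }
  centers
}

#' Cluster movement-endpoint acceleration vectors into two groups
#'
#' 2-means clustering with deterministic farthest-pair initialization (at
#' most 50 Lloyd iterations). The outcome is *degenerate* — and `NULL` is
#' returned — when there are fewer than 2 peaks or the two group means end up
#' closer than `min_separation_g` (no real two-endpoint structure, e.g. a
#' still arm).
#'
#' @param peaks Numeric matrix (peaks x 3) of acceleration vectors at the
#'   movement extrema.
#' @param min_separation_g Minimum distance between group means in g
#'   (default 0.05).
#' @return List with mean vectors `a` and `b`, or `NULL` when degenerate.
#' @export
cluster_endpoints <- function(peaks, min_separation_g = 0.05) {
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 2) return(NULL)
  centers <- two_means(peaks)
  if (is.null(centers)) return(NULL)
  if (vnorm(centers[1, ] - centers[2, ]) < min_separation_g) return(NULL)
  list(a = centers[1, ], b = centers[2, ])
}

#' Order endpoint clusters so the first is the rest-side endpoint
#'
#' The rest-side endpoint `c1` is the group mean with the smaller angle to
#' the estimated gravity direction `g_hat`; ties go to the group whose Y
#' component is closer to -1 (the at-rest reading of the axis convention).
#'
#' @param group_a,group_b Endpoint mean 3-vectors.
#' @param g_hat Estimated gravity direction (need not be unit length).
#' @return List with elements `c1` (rest side) and `c2`.
#' @export
order_clusters <- function(group_a, group_b, g_hat) {
  assert_that(vnorm(g_hat) > 0, "g_hat must be nonzero")
  ang <- function(v) {
    assert_that(vnorm(v) > 0, "endpoint vectors must be nonzero")
    acos(pmin(1, pmax(-1, sum(v * g_hat) / (vnorm(v) * vnorm(g_hat)))))
  }
  aa <- ang(group_a); ab <- ang(group_b)
  if (abs(aa - ab) < 1e-12) {
    first_a <- abs(group_a[2] + 1) <= abs(group_b[2] + 1)
  } else {
    first_a <- aa < ab
  }
  if (first_a) list(c1 = group_a, c2 = group_b) else list(c1 = group_b, c2 = group_a)
}

#' Rotation vector between the two movement endpoints
#'
#' Axis-angle representation of the arm swing: the angle is
#' `alpha = atan2(||c1 x c2||, c1 . c2)` (in `[0, pi]`) and the axis is the
#' direction of `c1 x c2`, so `r = alpha * (c1 x c2) / ||c1 x c2||`.
#' Parallel endpoints give the zero vector; antiparallel endpoints give
#' `alpha = pi` about a deterministic axis orthogonal to `c1` (Gram-Schmidt of
#' `[1,0,0]`, falling back to `[0,1,0]`).
#'
#' @param c1,c2 Nonzero 3-vectors (rest-side endpoint first).
#' @return Rotation vector (3-vector, radians).
#' @export
rotation_vector <- function(c1, c2) {
  assert_that(vnorm(c1) > 0 && vnorm(c2) > 0, "endpoint vectors must be nonzero")
  cr <- cross3(c1, c2)
  ncr <- vnorm(cr)
  dt <- sum(c1 * c2)
  if (ncr < 1e-12) {
    if (dt > 0) return(c(0, 0, 0))
    axis <- c(1, 0, 0) - sum(c(1, 0, 0) * c1) / sum(c1 * c1) * c1
    if (vnorm(axis) < 1e-9) {
      axis <- c(0, 1, 0) - sum(c(0, 1, 0) * c1) / sum(c1 * c1) * c1
    }
    return(pi * axis / vnorm(axis))
  }
  alpha <- atan2(ncr, dt)
  alpha * cr / ncr
}

#' Estimate the gravity direction of a node
#'
#' Normalized whole-recording mean of the filtered acceleration; if the mean
#' has norm below `0.5` g (heavily moving recording) the nominal at-rest
#' direction `[0, -1, 0]` is used instead.
#'
#' @param accel Filtered acceleration matrix (samples x 3).
#' @return Unit 3-vector.
#' @export
estimate_gravity <- function(accel) {
  m <- colMeans(as.matrix(accel))
  if (vnorm(m) < 0.5) c(0, -1, 0) else m / vnorm(m)
}

#' Acceleration features of one window
#'
#' Runs the endpoint pipeline — [movement_extrema()], [cluster_endpoints()],
#' [order_clusters()], [rotation_vector()] — on one filtered-acceleration
#' window. Degenerate windows (still arm, < 2 peaks or merged clusters)
#' yield the zero rotation vector rather than being dropped, so that still
#' exercises remain represented and are discriminated by the sEMG features.
#'
#' @inheritParams movement_extrema
#' @param g_hat Estimated gravity direction for the node (see
#'   [estimate_gravity()]).
#' @return List with `r` (rotation 3-vector), `alpha` (its norm), `n_peaks`,
#'   and endpoints `c1`, `c2` (NULL when degenerate).
#' @export
acc_window_features <- function(acc_win, rate_hz, g_hat = c(0, -1, 0),
                                min_dist_s = 0.5, prominence_frac = 0.1) {
  ex <- movement_extrema(acc_win, rate_hz, min_dist_s, prominence_frac)
  cl <- cluster_endpoints(ex$accel)
  if (is.null(cl)) {
    return(list(r = c(0, 0, 0), alpha = 0, n_peaks = length(ex$idx),
                c1 = NULL, c2 = NULL))
  }
  oc <- order_clusters(cl$a, cl$b, g_hat)
  r <- rotation_vector(oc$c1, oc$c2)
  list(r = r, alpha = vnorm(r), n_peaks = length(ex$idx),
       c1 = oc$c1, c2 = oc$c2)
}

#' sEMG features of one window
#'
#' From a window of the normalized MAV envelope: `m` is the time average, `p`
#' the mean of the peak values (local maxima at least `min_dist_s` apart with
#' prominence at least `prominence_frac` of the window's range; the window
#' maximum when no peaks qualify, e.g. a constant isometric envelope), and
#' `z = p / m` the peak-to-mean ratio. `z` is close to 1 for constant
#' (isometric) activation and close to 2 for burst-like dynamic repetitions.
#'
#' @param e Nonnegative numeric vector: one window of the normalized envelope.
#' @param rate_hz Sampling rate of the envelope.
#' @param min_dist_s Minimum inter-peak distance, seconds (default 0.5).
#' @param prominence_frac Prominence floor as a fraction of the window range
#'   (default 0.05).
#' @return List with `m`, `z`, `p`.
#' @export
emg_window_features <- function(e, rate_hz, min_dist_s = 0.5,
                                prominence_frac = 0.05) {
  m <- mean(e)
  assert_that(is.finite(m) && m > 1e-12, "silent window: envelope mean is zero")
  rng <- diff(range(e))
  idx <- find_peaks(e, min_dist = min_dist_s * rate_hz,
                    min_prom = prominence_frac * rng)
  p <- if (length(idx)) mean(e[idx]) else max(e)
  list(m = m, z = p / m, p = p)
}

window_slice <- function(n_samples, rate_hz, start_s, dur_s) {
  i0 <- round(start_s * rate_hz) + 1
  i1 <- i0 + round(dur_s * rate_hz) - 1
  seq.int(max(1, i0), min(n_samples, i1))
}

#' Extract the per-window feature table of a recording
#'
#' For every labeled segment whose class is in `classes` and whose duration
#' is at least `T_W`, plans the adaptive windows ([plan_windows()]) and
#' extracts, per window, the rotation vector of each node and the (m, z)
#' envelope features of each node. Acceleration and sEMG windows share
#' identical start times and durations.
#'
#' @param rec A preprocessed [recording()] (see [preprocess_recording()]).
#' @param T_W,T_S Window length and nominal shift in seconds.
#' @param classes Labels to extract (default [active_classes()], which
#'   excludes FR); `NULL` keeps every segment.
#' @param min_dist_s,acc_prominence_frac,emg_prominence_frac Peak-detection
#'   parameters passed to the per-window feature functions.
#' @return A `data.frame` with one row per window: `subject`, `label`,
#'   `segment_idx`, `window_start_s`, the 9 rotation-vector columns
#'   `r1x ... r3z` (node-major: 1 = biceps, 2 = deltoid, 3 = triceps) and the
#'   6 envelope columns `m1, z1, m2, z2, m3, z3`.
#' @export
extract_features <- function(rec, T_W = 8, T_S = 4, classes = active_classes(),
                             min_dist_s = 0.5, acc_prominence_frac = 0.1,
                             emg_prominence_frac = 0.05) {
  assert_that(isTRUE(attr(rec, "preprocessed")),
              "recording must be preprocessed (see preprocess_recording)")
  g_hats <- lapply(rec$nodes, function(n) estimate_gravity(n$accel))
  rows <- list()
  seg <- rec$segments
  for (si in seq_len(nrow(seg))) {
    if (!is.null(classes) && !(seg$label[si] %in% classes)) next
    T_E <- seg$end_s[si] - seg$start_s[si]
    if (T_E < T_W - 1e-9) next
    plan <- plan_windows(T_E, T_W, T_S)
    for (ws in plan$starts) {
      t0 <- seg$start_s[si] + ws
      acc_vals <- numeric(0)
      emg_vals <- numeric(0)
      for (ni in seq_along(rec$nodes)) {
        nd <- rec$nodes[[ni]]
        ai <- window_slice(nrow(nd$accel), nd$accel_rate_hz, t0, T_W)
        af <- acc_window_features(nd$accel[ai, , drop = FALSE],
                                  nd$accel_rate_hz, g_hats[[ni]],
                                  min_dist_s, acc_prominence_frac)
        ei <- window_slice(length(nd$emg), nd$emg_rate_hz, t0, T_W)
        ef <- emg_window_features(nd$emg[ei], nd$emg_rate_hz,
                                  min_dist_s, emg_prominence_frac)
        acc_vals <- c(acc_vals, af$r)
        emg_vals <- c(emg_vals, ef$m, ef$z)
      }
      rows[[length(rows) + 1]] <- c(list(subject = rec$subject_id,
                                         label = seg$label[si],
                                         segment_idx = si,
                                         window_start_s = t0),
                                    as.list(c(acc_vals, emg_vals)))
    }
  }
  cols <- c("subject", "label", "segment_idx", "window_start_s",
            acc_feature_names(), emg_feature_names())
  if (!length(rows)) {
    out <- as.data.frame(setNames(
      c(list(character(0), character(0), integer(0), numeric(0)),
        rep(list(numeric(0)), 15)), cols), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(setNames(r, cols), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  assert_that(all(vapply(out[cols[-(1:2)]], function(x) all(is.finite(x)), logical(1))),
              "non-finite feature values extracted")
  out
}

#' Column names of the two feature blocks
#'
#' Node-major fixed layout: node 1 = biceps, 2 = deltoid, 3 = triceps.
#' @return Character vector of column names.
#' @export
acc_feature_names <- function() {
  as.vector(t(outer(paste0("r", 1:3), c("x", "y", "z"), paste0)))
}

#' @rdname acc_feature_names
#' @export
emg_feature_names <- function() {
  as.vector(t(outer(1:3, c("m", "z"), function(i, p) paste0(p, i))))
}
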