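# Shared fixtures, built in code.

# Reduced-size filter pair for unit tests: same 0.625 Hz cutoff as the
# defaults, fewer taps (the transition band is wider but everything the unit
# tests assert is preserved).
small_filters <- function() {
  list(accel = fir_spec(801, 0.625, 125),
       emg = fir_spec(4001, 0.625, 2000))
}

# Hand-built 6 s recording with deterministic streams (no generator, no
# filtering) for I/O round-trip tests.
make_tiny_recording <- function(segments = segment_table("BC", 0.5, 4.5)) {
  t_a <- (0:(6 * 125 - 1)) / 125
  t_e <- (0:(6 * 2000 - 1)) / 2000
  nodes <- lapply(seq_along(node_names()), function(i) {
    node_stream(node_names()[i],
                cbind(sin(2 * pi * 0.3 * t_a + i), -1 + 0.01 * cos(t_a),
                      0.02 * sin(5 * t_a + i)),
                sin(2 * pi * 40 * t_e + i) * (1 + 0.5 * sin(2 * pi * 0.3 * t_e)))
  })
  recording("tiny", nodes, segments, meta = list(weight_kg = 3))
}

# Small synthetic cohort shared by the fusion and evaluation unit tests;
# built once per test run.
small_dataset_cache <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(small_dataset_cache$features)) {
    small_dataset_cache$features <- simulate_features(
      n_subjects = 4, sets_per_class = 1, set_duration_s = 24, gap_s = 4,
      seed = 7, filters = small_filters())
  }
  small_dataset_cache$features
}

# Well-separated 4-class Gaussian blobs for classifier contract tests.
make_blobs <- function(n_per_class = 20, sd = 0.25, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  x <- do.call(rbind, lapply(1:4, function(i) {
    cbind(rnorm(n_per_class, centers[i, 1], sd),
          rnorm(n_per_class, centers[i, 2], sd))
  }))
  list(x = x, y = rep(c("BC", "LR", "VR", "IM"), each = n_per_class))
}

# Trivially separable feature table in the extract_features layout: each
# class sits at its own corner of feature space for every subject.
make_separable_features <- function(n_subjects = 6, n_windows = 6, seed = 5) {
  set.seed(seed)
  classes <- active_classes()
  rows <- expand.grid(subject = sprintf("s%d", seq_len(n_subjects)),
                      label = classes, w = seq_len(n_windows),
                      stringsAsFactors = FALSE)
  k <- match(rows$label, classes)
  out <- data.frame(subject = rows$subject, label = rows$label,
                    segment_idx = 1L, window_start_s = rows$w * 4,
                    stringsAsFactors = FALSE)
  for (cn in acc_feature_names()) out[[cn]] <- k + rnorm(nrow(rows), 0, 0.01)
  for (cn in emg_feature_names()) out[[cn]] <- 5 - k + rnorm(nrow(rows), 0, 0.01)
  out
}
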