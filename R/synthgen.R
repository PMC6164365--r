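# Seeded synthetic recording generator.
#
# Emulates the phenomenology the feature pipeline relies on, per exercise
# class:
#   * arm orientation: theta(t) = (swing/2) * (1 - cos(2*pi*rep_hz*t)), a
#     raised-cosine swing between the rest orientation and the far endpoint;
#     the accelerometer reads the rotated gravity vector (orientation-only
#     model — the sub-0.625 Hz low-pass keeps only the gravity component
#     anyway) plus slow orientation wander and white sensor noise;
#   * sEMG: amplitude-modulated band-limited (20-450 Hz) Gaussian noise — the
#     standard phenomenological surface-EMG model — with a burst envelope
#     phase-locked to the swing for dynamic exercises (peak-to-mean of the
#     MAV near 2) or a constant envelope for isometric contraction (near 1),
#     on top of a small broadband baseline.
# BC and IM keep the upper arm still (swing 0), so acceleration alone cannot
# separate them; LR and VR differ mainly in swing angle while their
# activation gains overlap across subjects, so sEMG alone separates them
# poorly. The fused system can separate all four — the testbed for the
# fusion-benefit claim.

REST_G <- c(0, -1, 0)

#' Exercise preset: kinematics and muscle activation of one class
#'
#' @param label Class label (see [exercise_classes()]).
#' @param rotation_axis Unit 3-vector the upper arm rotates about.
#' @param swing_rad Peak swing angle in radians (0 for still exercises).
#' @param rep_hz Repetition frequency in Hz.
#' @param activation Named list (`biceps`, `deltoid`, `triceps`), each a
#'   list with `gain` (>= 0) and `mode` in `{"bursty", "constant", "off"}`.
#' @return An object of class `exercise_preset`.
#' @export
exercise_preset <- function(label, rotation_axis, swing_rad, rep_hz,
                            activation) {
  assert_that(label %in% exercise_classes(), "unknown exercise label")
  assert_that(is_scalar_number(swing_rad) && swing_rad >= 0,
              "swing_rad must be >= 0")
  assert_that(all(node_names() %in% names(activation)),
              "activation must cover all three muscles")
  for (a in activation) {
    assert_that(is_scalar_number(a$gain) && a$gain >= 0 &&
                  a$mode %in% c("bursty", "constant", "off"),
                "activation entries need gain >= 0 and a valid mode")
  }
  structure(list(label = label,
                 rotation_axis = rotation_axis / vnorm(rotation_axis),
                 swing_rad = swing_rad, rep_hz = rep_hz,
                 activation = activation),
            class = "exercise_preset")
}

act <- function(gain, mode) list(gain = gain, mode = mode)

#' Default presets of the five exercise classes
#'
#' BC (biceps curl) and IM (isometric contraction) keep the upper arm still
#' (swing 0) and load the biceps — bursty for BC, constant for IM. LR
#' (lateral raise) swings ~pi/2 about X with the deltoid bursting; VR
#' (vertical raise) swings ~2.4 rad with deltoid plus some triceps; FR
#' (frontal raise) is available so exclusion logic can be exercised, but is
#' outside the default active set.
#'
#' @return Named list of [exercise_preset()]s.
#' @export
default_presets <- function() {
  list(
    BC = exercise_preset("BC", c(1, 0, 0), 0, 0.3,
                         list(biceps = act(1.0, "bursty"),
                              deltoid = act(0.1, "constant"),
                              triceps = act(0.15, "bursty"))),
    LR = exercise_preset("LR", c(1, 0, 0), pi / 2, 0.3,
                         list(biceps = act(0.1, "constant"),
                              deltoid = act(1.0, "bursty"),
                              triceps = act(0.3, "bursty"))),
    VR = exercise_preset("VR", c(1, 0, 0), 2.4, 0.3,
                         list(biceps = act(0.1, "constant"),
                              deltoid = act(1.1, "bursty"),
                              triceps = act(0.45, "bursty"))),
    FR = exercise_preset("FR", c(0.5, 0, sqrt(1 - 0.25)), pi / 2, 0.3,
                         list(biceps = act(0.15, "constant"),
                              deltoid = act(0.9, "bursty"),
                              triceps = act(0.3, "bursty"))),
    IM = exercise_preset("IM", c(1, 0, 0), 0, 0.3,
                         list(biceps = act(1.0, "constant"),
                              deltoid = act(0.1, "constant"),
                              triceps = act(0.2, "constant")))
  )
}

#' Subject profile: inter-subject variation of the generator
#'
#' @param subject_id Identifier.
#' @param gain_jitter Named multiplicative factors per muscle.
#' @param rep_hz_factor Multiplicative repetition-rate factor.
#' @param accel_sigma_g White accelerometer noise sd, g.
#' @param wander_sigma_g Slow (< 1 Hz) orientation-wander sd, g.
#' @param emg_baseline Baseline sEMG noise amplitude, arbitrary units.
#' @param exec_sdlog Sdlog of the per-segment execution gain jitter: each set
#'   draws one lognormal factor per muscle, modelling how much a subject's
#'   muscle involvement varies between executions of the same exercise. This
#'   variation survives envelope normalization (unlike a constant per-subject
#'   gain, which cancels), so it is what makes the envelope-mean features
#'   overlap across sets.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, gain_jitter = c(biceps = 1, deltoid = 1,
                                                        triceps = 1),
                            rep_hz_factor = 1, accel_sigma_g = 0.015,
                            wander_sigma_g = 0.01, emg_baseline = 0.05,
                            exec_sdlog = 0.3) {
  assert_that(all(gain_jitter > 0) && rep_hz_factor > 0 && accel_sigma_g > 0 &&
                wander_sigma_g >= 0 && emg_baseline > 0 && exec_sdlog >= 0,
              "profile parameters must be positive")
  structure(list(subject_id = as.character(subject_id),
                 gain_jitter = gain_jitter, rep_hz_factor = rep_hz_factor,
                 accel_sigma_g = accel_sigma_g, wander_sigma_g = wander_sigma_g,
                 emg_baseline = emg_baseline, exec_sdlog = exec_sdlog),
            class = "subject_profile")
}

#' Draw a cohort of subject profiles
#'
#' Gain jitter is lognormal (sdlog 0.35) per muscle, repetition rate jitters
#' within +/-10%. One cohort member (the 9th when present) gets uniformly
#' lower gains, mirroring the lighter-dumbbell subject of a typical mixed
#' cohort.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @return List of [subject_profile()]s named `s01`, `s02`, ...
#' @export
subject_profiles <- function(n_subjects, seed = 1) {
  with_seed(derive_seed(seed, "profiles"), {
    profs <- lapply(seq_len(n_subjects), function(i) {
      gj <- rlnorm(3, 0, 0.35)
      if (i == 9) gj <- gj * 0.6
      subject_profile(sprintf("s%02d", i),
                      gain_jitter = setNames(gj, node_names()),
                      rep_hz_factor = runif(1, 0.9, 1.1))
    })
    names(profs) <- vapply(profs, `[[`, character(1), "subject_id")
    profs
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Unit-variance band-limited (20-450 Hz at 2 kHz) Gaussian carrier.
emg_carrier <- function(n, rate_hz) {
  bp <- signal::butter(4, c(20, 450) / (rate_hz / 2), type = "pass")
  x <- as.numeric(signal::filter(bp, rnorm(n)))
  s <- sd(x)
  if (s > 0) x / s else x
}

# Slow orientation wander: 1 Hz-low-passed white noise rescaled to sigma.
slow_wander <- function(n, rate_hz, sigma) {
  if (sigma <= 0 || n < 8) return(numeric(n))
  lp <- signal::butter(2, min(1 / (rate_hz / 2), 0.99), type = "low")
  x <- as.numeric(signal::filter(lp, rnorm(n)))
  s <- sd(x)
  if (s > 0) x / s * sigma else numeric(n)
}

#' Generate the raw streams of one exercise segment
#'
#' Produces, for all three nodes, the accelerometer stream (gravity rotated
#' by the raised-cosine swing, plus wander and white noise) and the sEMG
#' stream (amplitude-modulated band-limited noise per the preset's activation
#' map). Deterministic given `seed`.
#'
#' @param preset An [exercise_preset()].
#' @param profile A [subject_profile()].
#' @param duration_s Segment duration, seconds (> 0).
#' @param seed Integer seed.
#' @param accel_rate_hz,emg_rate_hz Sampling rates.
#' @return List with `accel` (named list of samples x 3 matrices) and `emg`
#'   (named list of numeric vectors), one entry per node.
#' @export
generate_segment <- function(preset, profile, duration_s, seed = 1,
                             accel_rate_hz = 125, emg_rate_hz = 2000) {
  assert_that(is_scalar_number(duration_s) && duration_s > 0,
              "duration_s must be > 0")
  with_seed(derive_seed(seed, "segment", preset$label), {
    na <- round(duration_s * accel_rate_hz)
    ne <- round(duration_s * emg_rate_hz)
    f <- preset$rep_hz * profile$rep_hz_factor
    ta <- (seq_len(na) - 1) / accel_rate_hz
    te <- (seq_len(ne) - 1) / emg_rate_hz
    theta <- (preset$swing_rad / 2) * (1 - cos(2 * pi * f * ta))
    base_acc <- rotate_about(REST_G, preset$rotation_axis, theta)
    accel <- list()
    emg <- list()
    burst_e <- (1 - cos(2 * pi * f * te)) / 2
    exec_gain <- setNames(rlnorm(3, 0, profile$exec_sdlog), node_names())
    for (nn in node_names()) {
      wander <- cbind(slow_wander(na, accel_rate_hz, profile$wander_sigma_g),
                      slow_wander(na, accel_rate_hz, profile$wander_sigma_g),
                      slow_wander(na, accel_rate_hz, profile$wander_sigma_g))
      accel[[nn]] <- base_acc + wander +
        matrix(rnorm(3 * na, 0, profile$accel_sigma_g), na, 3)
      a <- preset$activation[[nn]]
      gain <- a$gain * profile$gain_jitter[[nn]] * exec_gain[[nn]]
      env <- switch(a$mode,
                    bursty = gain * burst_e,
                    constant = rep(gain, ne),
                    off = numeric(ne))
      emg[[nn]] <- profile$emg_baseline * emg_carrier(ne, emg_rate_hz) +
        env * emg_carrier(ne, emg_rate_hz)
    }
    list(accel = accel, emg = emg)
  })
}

rest_segment <- function(profile, duration_s, seed, accel_rate_hz, emg_rate_hz) {
  rest <- exercise_preset("IM", c(1, 0, 0), 0, 0.3,
                          list(biceps = act(0, "off"), deltoid = act(0, "off"),
                               triceps = act(0, "off")))
  generate_segment(rest, profile, duration_s, seed, accel_rate_hz, emg_rate_hz)
}

#' Generate one subject's labeled recording
#'
#' Lays out `sets_per_class` rounds of the five classes (order BC, LR, IM,
#' FR, VR within a round, the isometric hold sitting between the raises),
#' separated by rest gaps. The segment layout depends only on the durations,
#' never on the seed; the seed drives the noise realizations.
#'
#' @param profile A [subject_profile()].
#' @param presets Named list of presets (default [default_presets()]).
#' @param sets_per_class Sets per exercise class (default 2).
#' @param set_duration_s Duration of each set, seconds (default 60).
#' @param gap_s Rest gap between sets, seconds (default 6).
#' @param seed Integer seed.
#' @param accel_rate_hz,emg_rate_hz Sampling rates.
#' @return A validated [recording()].
#' @export
generate_recording <- function(profile, presets = default_presets(),
                               sets_per_class = 2, set_duration_s = 60,
                               gap_s = 6, seed = 1, accel_rate_hz = 125,
                               emg_rate_hz = 2000) {
  order_in_round <- c("BC", "LR", "IM", "FR", "VR")
  order_in_round <- order_in_round[order_in_round %in% names(presets)]
  acc_parts <- list(); emg_parts <- list()
  labels <- character(); starts <- numeric(); ends <- numeric()
  t_now <- 0
  k <- 0
  push <- function(parts, chunk) {
    for (nn in node_names()) {
      parts$accel[[nn]] <- c(parts$accel[[nn]], list(chunk$accel[[nn]]))
      parts$emg[[nn]] <- c(parts$emg[[nn]], list(chunk$emg[[nn]]))
    }
    parts
  }
  parts <- list(accel = setNames(vector("list", 3), node_names()),
                emg = setNames(vector("list", 3), node_names()))
  for (round in seq_len(sets_per_class)) {
    for (lab in order_in_round) {
      k <- k + 1
      parts <- push(parts, rest_segment(profile, gap_s,
                                        derive_seed(seed, profile$subject_id, "gap", k),
                                        accel_rate_hz, emg_rate_hz))
      t_now <- t_now + gap_s
      chunk <- generate_segment(presets[[lab]], profile, set_duration_s,
                                derive_seed(seed, profile$subject_id, "seg", k),
                                accel_rate_hz, emg_rate_hz)
      parts <- push(parts, chunk)
      labels <- c(labels, lab)
      starts <- c(starts, t_now)
      ends <- c(ends, t_now + set_duration_s)
      t_now <- t_now + set_duration_s
    }
  }
  parts <- push(parts, rest_segment(profile, gap_s,
                                    derive_seed(seed, profile$subject_id, "gap", k + 1),
                                    accel_rate_hz, emg_rate_hz))
  nodes <- lapply(node_names(), function(nn) {
    node_stream(nn, do.call(rbind, parts$accel[[nn]]),
                unlist(parts$emg[[nn]], use.names = FALSE),
                accel_rate_hz, emg_rate_hz)
  })
  recording(profile$subject_id, nodes,
            segment_table(labels, starts, ends),
            meta = list(generator = "fitfuse synthetic", seed = seed))
}

#' Generate a multi-subject synthetic dataset
#'
#' @param n_subjects Number of subjects (>= 3; default 10).
#' @param sets_per_class,set_duration_s,gap_s Layout parameters passed to
#'   [generate_recording()].
#' @param seed Integer seed.
#' @param presets Named list of presets.
#' @return List of [recording()]s, one per subject.
#' @export
generate_dataset <- function(n_subjects = 10, sets_per_class = 2,
                             set_duration_s = 60, gap_s = 6, seed = 1,
                             presets = default_presets()) {
  assert_that(n_subjects >= 3, "need at least 3 subjects")
  profs <- subject_profiles(n_subjects, seed)
  lapply(profs, function(p) {
    generate_recording(p, presets, sets_per_class, set_duration_s, gap_s,
                       seed = derive_seed(seed, p$subject_id))
  })
}

#' Generate, preprocess and extract features subject by subject
#'
#' Memory-friendly end-to-end convenience: for each subject, generates the
#' recording, runs [preprocess_recording()] and [extract_features()], and
#' discards the raw streams, returning only the stacked feature table.
#'
#' @inheritParams generate_dataset
#' @param filters Filter specs (default [default_filters()]).
#' @param T_W,T_S Window parameters.
#' @param classes Labels to extract (default [active_classes()]).
#' @return Feature `data.frame` as from [extract_features()], all subjects
#'   stacked.
#' @export
simulate_features <- function(n_subjects = 10, sets_per_class = 2,
                              set_duration_s = 60, gap_s = 6, seed = 1,
                              presets = default_presets(),
                              filters = default_filters(), T_W = 8, T_S = 4,
                              classes = active_classes()) {
  assert_that(n_subjects >= 3, "need at least 3 subjects")
  profs <- subject_profiles(n_subjects, seed)
  feats <- lapply(profs, function(p) {
    rec <- generate_recording(p, presets, sets_per_class, set_duration_s,
                              gap_s, seed = derive_seed(seed, p$subject_id))
    rec <- preprocess_recording(rec, filters)
    extract_features(rec, T_W = T_W, T_S = T_S, classes = classes)
  })
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}
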