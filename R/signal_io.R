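# Data model and on-disk formats for multi-node labeled recordings.
#
# A recording bundles, for one subject, three sensing nodes (biceps, deltoid,
# triceps) each carrying a tri-axial accelerometer stream (units of g) and one
# sEMG stream (arbitrary units), plus a table of manually labeled exercise
# segments. Time is seconds from recording start; segment spans are half-open
# [start_s, end_s). Axis convention: Y along the muscle pointing down at rest,
# Z outward normal, X tangential, so gravity at rest reads approximately
# [0, -1, 0] g.

#' Construct a sensing-node stream
#'
#' @param node_name One of `node_names()`.
#' @param accel Numeric matrix with 3 columns (x, y, z acceleration in g).
#' @param emg Numeric vector of sEMG samples (arbitrary units).
#' @param accel_rate_hz,emg_rate_hz Sampling rates in Hz.
#' @return An object of class `node_stream`.
#' @export
node_stream <- function(node_name, accel, emg, accel_rate_hz = 125,
                        emg_rate_hz = 2000) {
  assert_that(node_name %in% node_names(),
              paste0("unknown node name '", node_name, "'"))
  accel <- as.matrix(accel)
  assert_that(ncol(accel) == 3, "accel must have 3 columns (x, y, z)")
  assert_that(all(is.finite(accel)), "accel samples must be finite")
  assert_that(all(is.finite(emg)), "emg samples must be finite")
  assert_that(is_scalar_number(accel_rate_hz) && accel_rate_hz > 0,
              "accel_rate_hz must be a positive number")
  assert_that(is_scalar_number(emg_rate_hz) && emg_rate_hz > 0,
              "emg_rate_hz must be a positive number")
  span_a <- nrow(accel) / accel_rate_hz
  span_e <- length(emg) / emg_rate_hz
  assert_that(abs(span_a - span_e) <= 1 / accel_rate_hz + 1e-9,
              sprintf("accel (%.3f s) and emg (%.3f s) streams of node '%s' must cover a common time span",
                      span_a, span_e, node_name))
  structure(list(node_name = node_name, accel = unname(accel),
                 emg = as.numeric(emg), accel_rate_hz = accel_rate_hz,
                 emg_rate_hz = emg_rate_hz),
            class = "node_stream")
}

#' Construct a segment table
#'
#' @param label Character vector of class labels (see [exercise_classes()]).
#' @param start_s,end_s Numeric vectors of segment boundaries in seconds;
#'   spans are half-open `[start_s, end_s)`.
#' @return A `data.frame` with columns `label`, `start_s`, `end_s`, sorted by
#'   start time.
#' @export
segment_table <- function(label = character(), start_s = numeric(),
                          end_s = numeric()) {
  seg <- data.frame(label = as.character(label), start_s = as.numeric(start_s),
                    end_s = as.numeric(end_s), stringsAsFactors = FALSE)
  if (nrow(seg)) {
    assert_that(all(seg$label %in% exercise_classes()),
                paste0("segment labels must be in {",
                       paste(exercise_classes(), collapse = ", "), "}"))
    assert_that(all(is.finite(seg$start_s)) && all(is.finite(seg$end_s)),
                "segment times must be finite")
    assert_that(all(seg$end_s > seg$start_s),
                "each segment must have end_s > start_s")
    seg <- seg[order(seg$start_s), , drop = FALSE]
    rownames(seg) <- NULL
    if (nrow(seg) > 1) {
      assert_that(all(seg$start_s[-1] >= seg$end_s[-nrow(seg)] - 1e-9),
                  "segments must be non-overlapping")
    }
  }
  seg
}

#' Construct a multi-node labeled recording
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param nodes List of exactly three [node_stream()] objects in the fixed
#'   order biceps, deltoid, triceps.
#' @param segments A segment table as returned by [segment_table()].
#' @param meta Named list of free-form metadata (dumbbell weight, gender, ...).
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, nodes, segments = segment_table(),
                      meta = list()) {
  assert_that(length(nodes) == 3, "a recording needs exactly 3 nodes")
  got <- vapply(nodes, function(n) n$node_name, character(1))
  assert_that(identical(got, node_names()),
              paste0("nodes must be ordered ", paste(node_names(), collapse = ", ")))
  segments <- segment_table(segments$label, segments$start_s, segments$end_s)
  rec <- structure(list(subject_id = as.character(subject_id), nodes = nodes,
                        segments = segments, meta = meta),
                   class = "recording")
  validate_recording(rec)
  rec
}

#' Validate a recording against its structural invariants
#'
#' Checks node identity and order, finiteness of samples, stream-span
#' agreement, the five-label vocabulary, segment ordering/overlap, and that
#' all segment spans lie inside the recorded time span.
#'
#' @param rec A [recording()].
#' @return `rec`, invisibly. Throws a validation error on breach.
#' @export
validate_recording <- function(rec) {
  assert_that(inherits(rec, "recording"), "not a recording object")
  for (n in rec$nodes) {
    assert_that(inherits(n, "node_stream"), "nodes must be node_stream objects")
    assert_that(all(is.finite(n$accel)) && all(is.finite(n$emg)),
                "stream samples must be finite")
  }
  span <- recording_span(rec)
  if (nrow(rec$segments)) {
    assert_that(min(rec$segments$start_s) >= -1e-9 &&
                  max(rec$segments$end_s) <= span + 1e-9,
                sprintf("segment spans must lie within the recorded %.3f s", span))
  }
  invisible(rec)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Length of the (common) stream span in seconds.
#' @export
recording_span <- function(rec) {
  n <- rec$nodes[[1]]
  nrow(n$accel) / n$accel_rate_hz
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, %.1f s, %d segment(s)\n",
              x$subject_id, recording_span(x), nrow(x$segments)))
  if (nrow(x$segments)) {
    tab <- table(x$segments$label)
    cat("  segments:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  }
  rates <- x$nodes[[1]]
  cat(sprintf("  nodes: %s (accel %g Hz, emg %g Hz)\n",
              paste(node_names(), collapse = ", "),
              rates$accel_rate_hz, rates$emg_rate_hz))
  invisible(x)
}

#' Write a recording to a directory of CSV channels plus a JSON manifest
#'
#' Emits one acceleration CSV (`t_s,ax_g,ay_g,az_g`) and one sEMG CSV
#' (`t_s,emg`) per node, a label CSV (`label,start_s,end_s`) and a
#' `manifest.json` tying them together. [read_recording()] inverts this
#' layout.
#'
#' @param rec A [recording()].
#' @param out_dir Directory to create/populate.
#' @return Path of the written manifest, invisibly.
#' @export
write_recording <- function(rec, out_dir) {
  validate_recording(rec)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io(paste0("cannot create output directory '", out_dir, "'"))
  nodes_meta <- vector("list", length(rec$nodes))
  for (i in seq_along(rec$nodes)) {
    n <- rec$nodes[[i]]
    acc_file <- paste0(n$node_name, "_accel.csv")
    emg_file <- paste0(n$node_name, "_emg.csv")
    ta <- (seq_len(nrow(n$accel)) - 1) / n$accel_rate_hz
    te <- (seq_along(n$emg) - 1) / n$emg_rate_hz
    data.table::fwrite(data.table::data.table(t_s = ta, ax_g = n$accel[, 1],
                                              ay_g = n$accel[, 2], az_g = n$accel[, 3]),
                       file.path(out_dir, acc_file))
    data.table::fwrite(data.table::data.table(t_s = te, emg = n$emg),
                       file.path(out_dir, emg_file))
    nodes_meta[[i]] <- list(name = n$node_name, accel_csv = acc_file,
                            emg_csv = emg_file, accel_rate_hz = n$accel_rate_hz,
                            emg_rate_hz = n$emg_rate_hz)
  }
  data.table::fwrite(rec$segments, file.path(out_dir, "labels.csv"))
  manifest <- list(subject_id = rec$subject_id, nodes = nodes_meta,
                   labels_csv = "labels.csv", meta = rec$meta)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

read_channel_csv <- function(path, cols) {
  if (!file.exists(path)) stop_io(paste0("channel file not found: '", path, "'"))
  x <- data.table::fread(path, showProgress = FALSE)
  assert_that(all(cols %in% names(x)),
              paste0("file '", path, "' must have columns ", paste(cols, collapse = ",")))
  x
}

#' Read a recording from a manifest written by [write_recording()]
#'
#' @param manifest_path Path to a `manifest.json`.
#' @return A validated [recording()].
#' @export
read_recording <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_io(paste0("manifest not found: '", manifest_path, "'"))
  }
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  base <- dirname(manifest_path)
  assert_that(!is.null(man$subject_id) && length(man$nodes) == 3,
              "manifest must declare subject_id and 3 nodes")
  nodes <- lapply(man$nodes, function(nm) {
    acc <- read_channel_csv(file.path(base, nm$accel_csv),
                            c("t_s", "ax_g", "ay_g", "az_g"))
    emg <- read_channel_csv(file.path(base, nm$emg_csv), c("t_s", "emg"))
    check_rate(acc$t_s, nm$accel_rate_hz, nm$accel_csv)
    check_rate(emg$t_s, nm$emg_rate_hz, nm$emg_csv)
    node_stream(nm$name, as.matrix(acc[, c("ax_g", "ay_g", "az_g")]),
                emg$emg, nm$accel_rate_hz, nm$emg_rate_hz)
  })
  lab_path <- file.path(base, man$labels_csv)
  if (!file.exists(lab_path)) stop_io(paste0("label file not found: '", lab_path, "'"))
  lab <- data.table::fread(lab_path, showProgress = FALSE,
                           colClasses = list(character = "label"))
  seg <- if (nrow(lab)) segment_table(lab$label, lab$start_s, lab$end_s) else segment_table()
  recording(man$subject_id, nodes, seg, meta = if (is.null(man$meta)) list() else man$meta)
}

# Declared rate must match the time stamps of the file (half-sample slack).
check_rate <- function(t_s, rate_hz, file) {
  if (length(t_s) < 2) return(invisible(TRUE))
  dt <- diff(range(t_s)) / (length(t_s) - 1)
  assert_that(abs(dt - 1 / rate_hz) < 0.5 / rate_hz / length(t_s) + 1e-9,
              sprintf("sample spacing in '%s' (%.6f s) inconsistent with declared rate %g Hz",
                      file, dt, rate_hz))
  invisible(TRUE)
}
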