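# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft nextn sd predict rnorm runif rlnorm setNames
#' @importFrom utils combn head tail
#' @importFrom MASS lda
#' @importFrom e1071 svm
#' @importFrom rpart rpart rpart.control
#' @importFrom jsonlite fromJSON write_json
#' @importFrom data.table fread fwrite
#' @importFrom signal butter
NULL

# Condition constructors: validation errors (bad inputs, contract breaches)
# vs I/O errors (missing/unwritable files). The CLI maps them to exit codes.
stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("fitfuse_validation_error", "error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("fitfuse_io_error", "error")))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_validation(msg)
  invisible(TRUE)
}

#' Exercise class vocabulary
#'
#' The five labels a segment may carry: biceps curl (`BC`), lateral raise
#' (`LR`), vertical raise (`VR`), frontal raise (`FR`) and isometric biceps
#' contraction (`IM`). The default *active* set used for feature extraction
#' and classification excludes `FR`.
#'
#' @return Character vector of labels.
#' @export
exercise_classes <- function() c("BC", "LR", "VR", "FR", "IM")

#' @rdname exercise_classes
#' @export
active_classes <- function() c("BC", "LR", "VR", "IM")

#' Sensing-node names in their fixed order
#'
#' Nodes are always ordered biceps, deltoid, triceps; feature layouts and
#' trained models rely on this order.
#'
#' @return Character vector of node names.
#' @export
node_names <- function() c("biceps", "deltoid", "triceps")

vnorm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of the fixed vector v by angles theta (vector) about
# unit axis k; returns length(theta) x 3 matrix.
rotate_about <- function(v, k, theta) {
  k <- k / vnorm(k)
  kv <- cross3(k, v)
  kdv <- sum(k * v)
  ct <- cos(theta)
  st <- sin(theta)
  outer(ct, v) + outer(st, kv) + outer(1 - ct, k * kdv)
}

# Derive a stream of child seeds from one integer seed, kept below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h + 1)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
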