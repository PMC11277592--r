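#' Assemble a modelling dataset
#'
#' Bundles a numeric feature matrix with either a binary outcome or a
#' right-censored time-to-event outcome into the container used by all
#' selection and evaluation functions.
#'
#' @param X Numeric matrix, subjects in rows and features in columns. Must be
#'   free of missing values.
#' @param y Binary outcome vector (0/1) for the logistic family. Exactly one
#'   of `y` or (`time`, `event`) must be supplied.
#' @param time Positive observed times (minimum of event and censoring time)
#'   for the Cox family.
#' @param event Event indicator (1 = event observed, 0 = censored).
#' @param feature_ids Character vector of stable feature identifiers; defaults
#'   to `colnames(X)`, or `f`-prefixed indices when the matrix is unnamed.
#'
#' @return An object of class `sieve_data` with elements `x`, `feature_ids`,
#'   `family` (`"logistic"` or `"cox"`) and the outcome vectors.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' d <- sieve_data(X, y = rep(0:1, 5))
#' d$family
#' @export
sieve_data <- function(X, y = NULL, time = NULL, event = NULL,
                       feature_ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("feature matrix must be numeric")
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 subjects")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(X)
    if (is.null(feature_ids)) feature_ids <- sprintf("f%05d", seq_len(ncol(X)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(X)) {
    stop("feature_ids length does not match ncol(X)")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  colnames(X) <- feature_ids

  has_bin <- !is.null(y)
  has_surv <- !is.null(time) || !is.null(event)
  if (has_bin == has_surv) {
    stop("supply exactly one outcome: either `y`, or both `time` and `event`")
  }
  if (has_bin) {
    y <- as.numeric(y)
    if (length(y) != n) stop("outcome length does not match nrow(X)")
    if (anyNA(y) || !all(y %in% c(0, 1))) stop("`y` must be 0/1 with no NA")
    out <- list(x = X, feature_ids = feature_ids, family = "logistic", y = y)
  } else {
    if (is.null(time) || is.null(event)) stop("survival outcome needs both `time` and `event`")
    time <- as.numeric(time); event <- as.numeric(event)
    if (length(time) != n || length(event) != n) stop("outcome length does not match nrow(X)")
    if (anyNA(time) || any(time <= 0)) stop("`time` must be positive with no NA")
    if (anyNA(event) || !all(event %in% c(0, 1))) stop("`event` must be 0/1 with no NA")
    out <- list(x = X, feature_ids = feature_ids, family = "cox",
                time = time, event = event)
  }
  structure(out, class = "sieve_data")
}

#' @export
print.sieve_data <- function(x, ...) {
  cat("<sieve_data> ", nrow(x$x), " subjects x ", ncol(x$x), " features, ",
      x$family, " outcome", sep = "")
  if (x$family == "logistic") {
    cat(" (", sum(x$y), " responses)\n", sep = "")
  } else {
    cat(" (", sum(x$event), " events, ",
        round(100 * mean(x$event == 0), 1), "% censored)\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.sieve_data <- function(x) dim(x$x)
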