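# Delimited-text dataset I/O and structured-text model persistence.
# Feature ids are always strings (e.g. microarray probe ids such as
# "209604_s_at"), never positional integers, so persisted models remain
# portable across column reorderings.

#' Load a dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row of feature ids and one row per
#' subject, extracts the outcome column(s), and returns a validated
#' [sieve_data] object. Exactly one outcome family must be specified:
#' either `outcome` (binary column) or both `time` and `event`.
#'
#' @param path Path to the delimited text file (separator auto-detected).
#' @param outcome Name of the binary 0/1 outcome column.
#' @param time,event Names of the observed-time and event-indicator
#'   columns for a survival outcome.
#' @return A [sieve_data] object.
#' @export
load_dataset <- function(path, outcome = NULL, time = NULL, event = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(outcome) && (!is.null(time) || !is.null(event))) {
    stop("specify either a binary `outcome` or a survival (`time`, `event`) pair, not both")
  }
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  nm <- names(df)
  if (anyDuplicated(nm)) {
    stop("duplicate column name(s) in header: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  want <- c(outcome, time, event)
  miss <- setdiff(want, nm)
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  feat_cols <- setdiff(nm, want)
  if (!length(feat_cols)) stop("no feature columns left after removing outcome columns")
  bad_type <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
  if (length(bad_type)) {
    stop("non-numeric feature column(s): ", paste(bad_type, collapse = ", "))
  }
  X <- as.matrix(df[feat_cols])
  bad_rows <- which(!stats::complete.cases(df))
  if (length(bad_rows)) {
    stop("missing values in row(s): ", paste(bad_rows, collapse = ", "))
  }
  if (!is.null(outcome)) {
    if (!is.null(time) || !is.null(event)) {
      stop("specify either a binary `outcome` or a survival (`time`, `event`) pair, not both")
    }
    sieve_data(X, y = df[[outcome]])
  } else {
    if (is.null(time) || is.null(event)) {
      stop("survival outcome needs both `time` and `event` column names")
    }
    sieve_data(X, time = df[[time]], event = df[[event]])
  }
}

#' Write a dataset (and optionally its truth set) as delimited text
#'
#' @param data A [sieve_data] object.
#' @param path Output CSV path; outcome columns are named `y`, or `time`
#'   and `event`.
#' @param truth Optional `truth_set`; written alongside as a two-column
#'   table `(feature_id, beta)` with suffix `_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, truth = NULL) {
  stopifnot(inherits(data, "sieve_data"))
  df <- as.data.frame(data$x)
  if (data$family == "logistic") {
    df$y <- data$y
  } else {
    df$time <- data$time
    df$event <- data$event
  }
  data.table::fwrite(df, path)
  if (!is.null(truth)) {
    data.table::fwrite(data.frame(feature_id = truth$true_ids,
                                  beta = truth$true_betas),
                       sub("\\.csv$|$", "_truth.csv", path))
  }
  invisible(path)
}

#' Persist a fitted prediction model as structured text
#'
#' Saves the model (feature ids, coefficients, family, selection settings,
#' package version) as JSON — portable and auditable, unlike binary
#' serialization.
#'
#' @param model A `sieve_selection`, `sieve_fit`, or `penalized_fit`.
#' @param path Output path.
#' @param seed Optional seed recorded for reproducibility.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, seed = NULL) {
  if (inherits(model, "sieve_selection")) {
    fit <- model$fit
    if (is.null(fit)) stop("selection has no fitted model to save")
    obj <- list(type = "stepwise", family = model$family,
                alpha_in = model$alpha_in, alpha_out = model$alpha_out,
                coefficients = as.list(fit$coefficients),
                p_values = as.list(fit$p_value))
  } else if (inherits(model, "sieve_fit")) {
    obj <- list(type = "fit", family = model$family,
                coefficients = as.list(model$coefficients),
                p_values = as.list(model$p_value))
  } else if (inherits(model, "penalized_fit")) {
    obj <- list(type = model$penalty, family = model$family,
                lambda = model$lambda, alpha = model$alpha,
                coefficients = as.list(model$coefficients))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  obj$package <- "resieve"
  obj$version <- as.character(utils::packageVersion("resieve"))
  obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a persisted prediction model
#'
#' @param path Path to a JSON file written by [save_model()].
#' @return A `resieve_model` with named `coefficients` and `family`,
#'   usable with [risk_score()].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  cf <- unlist(obj$coefficients)
  structure(list(coefficients = cf, family = obj$family, type = obj$type,
                 seed = obj$seed, version = obj$version),
            class = "resieve_model")
}

#' @export
print.resieve_model <- function(x, ...) {
  cat("<resieve_model> ", x$type, " (", x$family, "), ",
      sum(names(x$coefficients) != "(Intercept)"), " feature(s)\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
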