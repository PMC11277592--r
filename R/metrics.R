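# Risk-score evaluation. The risk score is the linear predictor of the
# fitted model (no intercept); higher scores mean worse outcome (higher
# response probability, or shorter survival). Binary accuracy is the ROC
# AUC; survival accuracy is Harrell's concordance and the significance of a
# univariate Cox fit on the score.

#' Linear-predictor risk scores
#'
#' Computes the linear predictor `beta'Z` over the model's selected
#' features (one score per subject), excluding any
#' intercept (a location shift leaves AUC and concordance unchanged).
#'
#' @param fit A fitted model carrying named `coefficients` — a `sieve_fit`,
#'   a `sieve_selection`, a `penalized_fit`, or any list with a named
#'   `coefficients` vector.
#' @param X Feature matrix with column names covering the model's features
#'   (a [sieve_data] object is also accepted).
#' @return Numeric risk-score vector of length `nrow(X)`.
#' @export
risk_score <- function(fit, X) {
  if (inherits(fit, "sieve_selection")) fit <- fit$fit
  if (is.null(fit)) stop("model fit is NULL; cannot score")
  if (inherits(X, "sieve_data")) X <- X$x
  X <- as.matrix(X)
  beta <- fit$coefficients
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  if (!length(beta)) return(rep(0, nrow(X)))
  miss <- setdiff(names(beta), colnames(X))
  if (length(miss)) {
    stop("feature(s) in model but absent from data: ",
         paste(miss, collapse = ", "))
  }
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' ROC area under the curve
#'
#' Mann–Whitney AUC of a risk score against a binary outcome:
#' `P(r_case > r_control) + 0.5 P(tie)`. Constant scores therefore give 0.5.
#'
#' @param scores Numeric risk scores.
#' @param y Binary 0/1 outcome; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' ROC curve points
#'
#' The ROC curve of a risk score as a two-column table suitable for
#' plotting.
#'
#' @inheritParams roc_auc
#' @return A data frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(scores, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the subject with the shorter observed
#' time (which must be an event time) carries the higher risk score; score
#' ties count one half. Pairs where the shorter time is censored are
#' unusable.
#'
#' @param scores Numeric risk scores (higher = worse prognosis).
#' @param time Observed times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (sum(event) == 0) stop("no events: no usable pairs for concordance")
  cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0) {
    stop("no usable pairs for concordance")
  }
  as.numeric(cf$concordance)
}

#' Significance of the risk score in a univariate Cox model
#'
#' Fits a Cox proportional hazards model of `(time, event)` on the risk
#' score alone and returns `-log10` of the coefficient's two-sided Wald
#' p-value — large values mean the score strongly orders survival.
#'
#' @inheritParams harrell_c
#' @return Non-negative `-log10(p)`; computed on the log scale so very
#'   strong scores do not underflow to `Inf`.
#' @export
riskscore_neglog10p <- function(scores, time, event) {
  if (stats::sd(scores) == 0) stop("constant risk scores carry no information")
  fit <- fit_cox(matrix(scores, ncol = 1, dimnames = list(NULL, "score")),
                 time, event)
  z <- abs(fit$coefficients[[1L]] / fit$se[[1L]])
  # -log10 p for a two-sided normal test, kept on the log scale
  -(stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}
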