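# Unpenalized maximum-likelihood engines for low-dimensional covariate
# subsets. Logistic fits run through a compiled Newton-Raphson; Cox fits run
# through survival::coxph.fit with the Efron tie correction. Both expose
# per-coefficient Wald z-tests, which drive the stepwise insertion/deletion
# decisions.

# scale-aware blow-up guard: a Wald SE this many times larger than the
# information scale of its column indicates separation (logistic) or a
# monotone partial likelihood (Cox), where the MLE sits at infinity
.SE_BLOWUP <- 15

.new_sieve_fit <- function(coef, se, loglik, converged, family, n, iter,
                           cov = NULL) {
  z <- coef / se
  if (!is.null(cov)) dimnames(cov) <- list(names(coef), names(coef))
  structure(list(coefficients = coef,
                 se = se,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 cov = cov,
                 loglik = loglik,
                 converged = converged,
                 family = family,
                 n = n,
                 iter = iter),
            class = "sieve_fit")
}

.check_full_rank <- function(Xd, what = "design") {
  qd <- qr(Xd)
  if (qd$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qd$pivot[(qd$rank + 1L):ncol(Xd)]]
    stop("rank-deficient ", what, "; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.col_scale <- function(Xd) {
  s <- apply(Xd, 2L, stats::sd)
  s[s == 0] <- 1
  s
}

#' Fit an unpenalized logistic regression by Newton--Raphson
#'
#' Maximizes the Bernoulli log-likelihood
#' \deqn{\ell_1(\beta_0,\beta)=\sum_i [y_i(\beta_0+\beta^T Z_i) -
#'   \log\{1+e^{\beta_0+\beta^T Z_i}\}]}
#' over the intercept and the coefficients of the supplied covariate subset.
#' The intercept is always included and is never part of variable selection.
#'
#' @param X Numeric matrix of covariates (n x k), or `NULL` for an
#'   intercept-only model.
#' @param y Binary 0/1 response vector.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton iterations before the fit is declared
#'   non-convergent.
#'
#' @return A `sieve_fit`: named `coefficients` (first element
#'   `"(Intercept)"`), Wald standard errors `se`, two-sided normal `p_value`
#'   per coefficient, the coefficient covariance `cov` (inverse observed
#'   information), the maximized `loglik`, and a `converged` flag.
#'   Complete or quasi-complete separation is reported as `converged = FALSE`
#'   rather than as a spuriously valid fit.
#' @seealso [fit_cox()], [forward_stepwise()]
#' @examples
#' y <- rep(c(0, 1), c(70, 30))
#' fit_logistic(NULL, y)$coefficients  # log(30/70)
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("`y` must be 0/1 with no NA")
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0) else X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) does not match length(y)")
  if (anyNA(X)) stop("X contains missing values")
  k <- ncol(X)
  if (k >= n) stop("more covariates than subjects (k >= n)")
  if (is.null(colnames(X)) && k > 0L) colnames(X) <- paste0("x", seq_len(k))
  Xd <- cbind("(Intercept)" = 1, X)
  .check_full_rank(Xd)

  res <- logit_newton_cpp(Xd, y, numeric(ncol(Xd)), tol, as.integer(max_iter))
  coef <- drop(res$coefficients); names(coef) <- colnames(Xd)
  se <- drop(res$se); names(se) <- colnames(Xd)
  converged <- isTRUE(res$converged)
  # separation: likelihood flattens out while SEs explode on the information
  # scale of the column
  if (converged && any(se * .col_scale(Xd) > .SE_BLOWUP, na.rm = TRUE)) {
    converged <- FALSE
  }
  .new_sieve_fit(coef, se, res$loglik, converged, "logistic", n, res$iter,
                 cov = res$cov)
}

#' Fit an unpenalized Cox proportional hazards model
#'
#' Maximizes the Cox log-partial-likelihood over the supplied covariate
#' subset, with the Efron approximation for tied event times. The Cox model
#' has no intercept, so `X` must contain at least one covariate.
#'
#' @param X Numeric covariate matrix (n x k), k >= 1.
#' @param time Positive observed times.
#' @param event Event indicator (1 = event, 0 = censored); at least one
#'   event is required.
#' @param tol Convergence tolerance passed to the partial-likelihood Newton
#'   iterations.
#' @param max_iter Maximum iterations.
#'
#' @return A `sieve_fit` with named `coefficients`, `se`, `p_value`, `cov`,
#'   the log-partial-likelihood `loglik` at the optimum, and `converged`. A
#'   covariate that perfectly orders the events (monotone likelihood) yields
#'   `converged = FALSE`.
#' @seealso [fit_logistic()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 60, 1)
#' tt <- rexp(60, 0.1 * exp(0.7 * x[, 1]))
#' fit_cox(x, tt, rep(1, 60))$coefficients
#' @export
fit_cox <- function(X, time, event, tol = 1e-9, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) < 1L) stop("Cox model needs at least one covariate (no intercept term)")
  if (anyNA(X)) stop("X contains missing values")
  time <- as.numeric(time); event <- as.numeric(event)
  n <- length(time)
  if (nrow(X) != n || length(event) != n) stop("outcome length does not match nrow(X)")
  if (any(time <= 0) || anyNA(time)) stop("`time` must be positive")
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
  if (sum(event) == 0) stop("no events observed; Cox model cannot be fitted")
  if (ncol(X) >= n) stop("more covariates than subjects (k >= n)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  # Cox fits are invariant to column shifts, so rank must be checked on the
  # centered matrix; a constant column carries no information at all
  Xc <- sweep(X, 2L, colMeans(X))
  .check_full_rank(structure(Xc, dimnames = dimnames(X)), "design (after centering)")

  ysurv <- survival::Surv(time, event)
  ctrl <- survival::coxph.control(eps = tol, iter.max = as.integer(max_iter))
  res <- survival::coxph.fit(X, ysurv, strata = NULL, offset = NULL,
                             init = NULL, control = ctrl,
                             weights = rep(1, n), method = "efron",
                             rownames = NULL)
  coef <- res$coefficients; names(coef) <- colnames(X)
  se <- sqrt(diag(as.matrix(res$var))); names(se) <- colnames(X)
  converged <- all(is.finite(coef)) && all(is.finite(se)) &&
    res$iter < as.integer(max_iter) &&
    !any(se * .col_scale(X) > .SE_BLOWUP)
  .new_sieve_fit(coef, se, res$loglik[2L], converged, "cox", n, res$iter,
                 cov = as.matrix(res$var))
}

#' @export
print.sieve_fit <- function(x, ...) {
  cat("<sieve_fit> ", x$family, " model, n = ", x$n,
      ", loglik = ", format(x$loglik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `z value` = x$coefficients / x$se, `Pr(>|z|)` = x$p_value)
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# Lean internal fitters used by the stepwise scan loop: no input validation,
# no naming, warm starts. Return minimal lists or NULL on failure.
.logit_ml <- function(Xd, y, init = NULL, tol = 1e-8, max_iter = 100L) {
  if (is.null(init)) init <- numeric(ncol(Xd))
  res <- logit_newton_cpp(Xd, y, init, tol, max_iter)
  if (isTRUE(res$singular)) return(NULL)
  conv <- isTRUE(res$converged)
  se <- drop(res$se)
  list(coef = drop(res$coefficients), se = se, loglik = res$loglik,
       converged = conv)
}

.cox_ml <- function(X, ysurv, init = NULL, control = NULL) {
  if (is.null(control)) {
    control <- survival::coxph.control(eps = 1e-9, iter.max = 100L)
  }
  res <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(X, ysurv, strata = NULL, offset = NULL, init = init,
                          control = control, weights = rep(1, nrow(X)),
                          method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  coef <- res$coefficients
  if (any(!is.finite(coef))) return(NULL)
  v <- diag(as.matrix(res$var))
  if (any(!is.finite(v)) || any(v <= 0)) return(NULL)
  list(coef = coef, se = sqrt(v), loglik = res$loglik[2L],
       converged = res$iter < control$iter.max)
}
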