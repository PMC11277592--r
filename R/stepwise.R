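# Forward stepwise selection driven by Wald significance thresholds:
# alpha_in governs insertion of the most significant remaining candidate,
# alpha_out (>= alpha_in) governs deletion of covariates that lose
# significance in the growing joint model.

#' Forward stepwise variable selection with significance thresholds
#'
#' Starting from an intercept-only model (logistic) or an empty model (Cox),
#' each step fits every remaining candidate jointly with the current model
#' and inserts the candidate with the smallest Wald p-value, provided it is
#' below `alpha_in`. After every insertion, previously included covariates
#' whose joint-model p-value exceeds `alpha_out` are deleted one at a time
#' (least significant first, with refitting), except the covariate inserted
#' in the same step. The procedure stops when no candidate qualifies or
#' `max_selected` is reached; a last unprotected deletion sweep then
#' guarantees every retained coefficient satisfies p <= `alpha_out`.
#'
#' Candidates whose augmented fit is rank deficient or fails to converge
#' (e.g. under complete separation) are ineligible at that step. Ties in the
#' minimal p-value break towards the lowest original feature index. A
#' feature deleted in the immediately preceding sweep cannot be re-inserted
#' at the identical model state, which (together with `max_selected`)
#' prevents insert/delete cycling.
#'
#' @param data A [sieve_data] object.
#' @param candidates Character vector of feature ids to select from;
#'   defaults to all features.
#' @param alpha_in Insertion threshold in \[0, 1\]; a candidate enters only
#'   if its p-value is strictly below it. `alpha_in = 0` therefore selects
#'   nothing.
#' @param alpha_out Deletion threshold, `alpha_out >= alpha_in`.
#' @param max_selected Safety cap on the number of retained features.
#'
#' @return A `sieve_selection`: `selected` (feature ids in insertion order),
#'   `fit` (the final joint [fit_logistic()]/[fit_cox()] refit on exactly the
#'   selected set; `NULL` for an empty Cox selection), and `trace`, a
#'   data frame of per-step `(action, feature, p_value)` records.
#' @seealso [joint_refit()], [repeated_sieving()]
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(200 * 10), 200, 10)
#' y <- rbinom(200, 1, plogis(2 * X[, 3]))
#' forward_stepwise(sieve_data(X, y = y), alpha_in = 0.01, alpha_out = 0.02)
#' @export
forward_stepwise <- function(data, candidates = data$feature_ids,
                             alpha_in = 0.01, alpha_out = 0.02,
                             max_selected = 50L) {
  stopifnot(inherits(data, "sieve_data"))
  if (length(candidates) < 1L) stop("empty candidate list")
  miss <- setdiff(candidates, data$feature_ids)
  if (length(miss)) stop("unknown candidate feature(s): ", paste(miss, collapse = ", "))
  if (!(alpha_in >= 0 && alpha_in <= 1) || !(alpha_out >= 0 && alpha_out <= 1)) {
    stop("alpha thresholds must lie in [0, 1]")
  }
  if (alpha_out < alpha_in) stop("alpha_out must be >= alpha_in")

  eng <- .stepwise_engine(data)
  cand_idx <- sort(match(unique(candidates), data$feature_ids))

  sel <- integer(0)           # current model, insertion order
  cur <- NULL                 # lean fit of current model
  trace <- list()
  step <- 0L
  last_deleted <- NULL        # list(idx=, state=sorted sel) cycle guard
  any_eligible_ever <- FALSE

  repeat {
    remaining <- setdiff(cand_idx, sel)
    if (!length(remaining) || length(sel) >= max_selected) break

    scan <- eng$scan(sel, cur, remaining)
    pvec <- scan$p
    if (!is.null(last_deleted) && identical(sort(sel), last_deleted$state)) {
      pvec[remaining == last_deleted$idx] <- NA_real_
    }
    if (all(is.na(pvec))) break
    any_eligible_ever <- TRUE
    best <- which.min(pvec)   # NAs skipped; first minimum = lowest index
    if (!(pvec[best] < alpha_in)) break

    step <- step + 1L
    inserted <- remaining[best]
    sel <- c(sel, inserted)
    cur <- scan$fits[[best]]
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, action = "insert",
      feature = data$feature_ids[inserted], p_value = pvec[best])

    # deletion sweep, protecting the covariate inserted this step
    repeat {
      pj <- eng$model_p(cur)
      deletable <- sel != inserted
      if (!any(deletable & pj > alpha_out)) break
      worst <- which.max(ifelse(deletable, pj, -Inf))
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, action = "delete",
        feature = data$feature_ids[sel[worst]], p_value = pj[worst])
      dropped <- sel[worst]
      sel <- sel[-worst]
      last_deleted <- list(idx = dropped, state = sort(sel))
      cur <- eng$fit(sel)
      if (is.null(cur)) break
    }
    if (is.null(cur)) {
      warning("joint refit failed during deletion sweep; stopping early")
      break
    }
  }

  # final unprotected sweep so that every retained p-value is <= alpha_out
  while (length(sel) && !is.null(cur)) {
    pj <- eng$model_p(cur)
    if (all(pj <= alpha_out)) break
    worst <- which.max(pj)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, action = "delete",
      feature = data$feature_ids[sel[worst]], p_value = pj[worst])
    sel <- sel[-worst]
    cur <- if (length(sel)) eng$fit(sel) else NULL
  }

  if (!length(sel) && !any_eligible_ever) {
    warning("no candidate produced a convergent augmented fit; empty selection")
  }

  selected <- data$feature_ids[sel]
  fit <- if (length(selected) || data$family == "logistic") {
    joint_refit(data, selected)
  } else {
    NULL
  }
  trace <- if (length(trace)) {
    do.call(rbind, trace)
  } else {
    data.frame(step = integer(0), action = character(0),
               feature = character(0), p_value = numeric(0))
  }
  structure(list(selected = selected, fit = fit, trace = trace,
                 alpha_in = alpha_in, alpha_out = alpha_out,
                 family = data$family),
            class = "sieve_selection")
}

#' Refit the joint model on a fixed feature set
#'
#' One unpenalized maximum-likelihood fit on exactly the given features.
#' This is the model whose coefficients are reported, serialized, and used
#' for risk scoring.
#'
#' @param data A [sieve_data] object.
#' @param selected Character vector of feature ids (may be empty for the
#'   logistic family, giving the intercept-only model).
#' @return A `sieve_fit`.
#' @export
joint_refit <- function(data, selected) {
  stopifnot(inherits(data, "sieve_data"))
  miss <- setdiff(selected, data$feature_ids)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  if (data$family == "logistic") {
    Xs <- if (length(selected)) data$x[, selected, drop = FALSE] else NULL
    fit_logistic(Xs, data$y)
  } else {
    if (!length(selected)) stop("empty Cox model has no parameters to fit")
    fit_cox(data$x[, selected, drop = FALSE], data$time, data$event)
  }
}

#' @export
print.sieve_selection <- function(x, ...) {
  cat("<sieve_selection> ", length(x$selected), " feature(s) retained (",
      x$family, ", alpha_in = ", x$alpha_in, ", alpha_out = ", x$alpha_out,
      ")\n", sep = "")
  if (length(x$selected)) {
    cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

# Family-specific engine bound to one dataset: lean fits, candidate scans,
# and per-covariate p-values for the current model. Indices are columns of
# data$x; lean fits carry coefficients in (intercept,) model-column order.
.stepwise_engine <- function(data) {
  X <- data$x
  if (data$family == "logistic") {
    y <- data$y
    fit <- function(sel, init = NULL) {
      .logit_ml(cbind(1, X[, sel, drop = FALSE]), y, init = init)
    }
    scan <- function(sel, cur, remaining) {
      base <- cbind(1, X[, sel, drop = FALSE])
      init <- if (!is.null(cur) && cur$converged) c(cur$coef, 0) else NULL
      fits <- vector("list", length(remaining))
      p <- rep(NA_real_, length(remaining))
      for (i in seq_along(remaining)) {
        f <- .logit_ml(cbind(base, X[, remaining[i]]), y, init = init)
        if (!is.null(f) && f$converged) {
          last <- length(f$coef)
          p[i] <- 2 * stats::pnorm(-abs(f$coef[last] / f$se[last]))
          fits[[i]] <- f
        }
      }
      list(p = p, fits = fits)
    }
    model_p <- function(cur) {
      # covariate p-values, skipping the intercept
      idx <- seq_along(cur$coef)[-1L]
      2 * stats::pnorm(-abs(cur$coef[idx] / cur$se[idx]))
    }
  } else {
    ysurv <- survival::Surv(data$time, data$event)
    ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100L)
    fit <- function(sel, init = NULL) {
      .cox_ml(X[, sel, drop = FALSE], ysurv, init = init, control = ctrl)
    }
    scan <- function(sel, cur, remaining) {
      base <- X[, sel, drop = FALSE]
      init <- if (!is.null(cur) && cur$converged) c(cur$coef, 0) else NULL
      fits <- vector("list", length(remaining))
      p <- rep(NA_real_, length(remaining))
      for (i in seq_along(remaining)) {
        f <- .cox_ml(cbind(base, X[, remaining[i]]), ysurv, init = init,
                     control = ctrl)
        if (!is.null(f) && f$converged) {
          last <- length(f$coef)
          p[i] <- 2 * stats::pnorm(-abs(f$coef[last] / f$se[last]))
          fits[[i]] <- f
        }
      }
      list(p = p, fits = fits)
    }
    model_p <- function(cur) {
      2 * stats::pnorm(-abs(cur$coef / cur$se))
    }
  }
  list(fit = fit, scan = scan, model_p = model_p)
}

#' Post-hoc certificate for a stepwise selection
#'
#' Verifies, on the final joint model, that (i) every retained coefficient
#' has Wald p-value at most `alpha_out`, and (ii) no excluded candidate
#' would enter at `alpha_in` when added alone to the final model (candidates
#' with non-convergent augmented fits count as ineligible).
#'
#' @param data A [sieve_data] object.
#' @param selection A `sieve_selection` from [forward_stepwise()].
#' @param candidates The candidate set the selection was run on.
#' @return A list with logical elements `retained_ok` and `exclusion_ok`.
#' @export
selection_certificate <- function(data, selection,
                                  candidates = data$feature_ids) {
  stopifnot(inherits(selection, "sieve_selection"))
  sel <- selection$selected
  retained_ok <- TRUE
  if (length(sel)) {
    pv <- selection$fit$p_value
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    retained_ok <- all(pv <= selection$alpha_out)
  }
  exclusion_ok <- TRUE
  for (f in setdiff(candidates, sel)) {
    fit <- tryCatch(joint_refit(data, c(sel, f)), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    if (fit$p_value[[f]] < selection$alpha_in) {
      exclusion_ok <- FALSE
      break
    }
  }
  list(retained_ok = retained_ok, exclusion_ok = exclusion_ok)
}
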