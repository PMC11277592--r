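# Head-to-head study runner: repeated sieving versus L1 (lasso) and L1+L2
# (elastic net) penalized comparators over independent simulated
# replicates, summarized as mean selection counts and mean train/validation
# prediction metrics.

#' Fit a penalized comparator model
#'
#' Solves the L1- or L1+L2-penalized logistic/Cox objective by coordinate
#' descent (glmnet) on standardized training features. The penalty weight
#' `lambda` is chosen by internal k-fold cross-validation at the CV
#' minimum; for the elastic net the L1:L2 mixing parameter is searched over
#' a fixed grid `{0.1, ..., 0.9}` jointly with `lambda`, using common fold
#' assignments. The selected set is the features with nonzero coefficients,
#' and risk scores use the penalized coefficients.
#'
#' @param data Training [sieve_data].
#' @param penalty `"lasso"` (pure L1) or `"elasticnet"` (L1+L2 mix).
#' @param nfolds Cross-validation folds (default 10).
#' @param alpha_grid Mixing grid for the elastic net.
#' @param nlambda Length of the lambda path.
#' @param lambda_min_ratio Smallest lambda as a fraction of the largest
#'   (`NULL` = solver default). Raising it truncates the slow, dense end of
#'   the path; keep the cross-validated minimum interior.
#' @param seed Optional seed for the fold assignment.
#' @return A `penalized_fit`: named nonzero `coefficients` (plus
#'   `"(Intercept)"` for the logistic family), `selected` ids, `lambda`,
#'   `alpha`, `penalty`, `family`.
#' @export
fit_penalized <- function(data, penalty = c("lasso", "elasticnet"),
                          nfolds = 10L, alpha_grid = seq(0.1, 0.9, by = 0.1),
                          nlambda = 100L, lambda_min_ratio = NULL,
                          seed = NULL) {
  stopifnot(inherits(data, "sieve_data"))
  penalty <- match.arg(penalty)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data$x)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  if (data$family == "logistic") {
    yy <- data$y
    fam <- "binomial"
  } else {
    yy <- survival::Surv(data$time, data$event)
    fam <- "cox"
  }
  alphas <- if (penalty == "lasso") 1 else alpha_grid
  best <- NULL
  cv_args <- list(x = data$x, y = yy, family = fam, nfolds = nfolds,
                  foldid = foldid, nlambda = nlambda, standardize = TRUE)
  if (!is.null(lambda_min_ratio)) {
    cv_args$lambda.min.ratio <- lambda_min_ratio
  }
  for (a in alphas) {
    cv <- do.call(glmnet::cv.glmnet, c(cv_args, list(alpha = a)))
    cvmin <- min(cv$cvm)
    if (is.null(best) || cvmin < best$cvmin) {
      best <- list(cv = cv, alpha = a, cvmin = cvmin)
    }
  }
  cf <- as.matrix(stats::coef(best$cv, s = "lambda.min"))[, 1L]
  nz <- cf[cf != 0]
  selected <- setdiff(names(nz), "(Intercept)")
  structure(list(coefficients = nz, selected = selected,
                 lambda = best$cv$lambda.min, alpha = best$alpha,
                 penalty = penalty, family = data$family),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("<penalized_fit> ", x$penalty, " (", x$family, "), ",
      length(x$selected), " nonzero feature(s), lambda = ",
      signif(x$lambda, 4), ", alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

.subset_data <- function(data, idx) {
  if (data$family == "logistic") {
    sieve_data(data$x[idx, , drop = FALSE], y = data$y[idx])
  } else {
    sieve_data(data$x[idx, , drop = FALSE], time = data$time[idx],
               event = data$event[idx])
  }
}

.trial_metrics <- function(family, fit, train, validation) {
  score_or_na <- function(d) {
    tryCatch(risk_score(fit, d), error = function(e) NULL)
  }
  st <- score_or_na(train); sv <- score_or_na(validation)
  if (family == "logistic") {
    auc_of <- function(s, d) {
      if (is.null(s) || stats::sd(s) == 0) return(0.5)
      roc_auc(s, d$y)
    }
    c(auc_train = auc_of(st, train), auc_validation = auc_of(sv, validation))
  } else {
    m_of <- function(s, d) {
      if (is.null(s) || stats::sd(s) == 0) {
        return(c(neglog10p = 0, cindex = 0.5))
      }
      c(neglog10p = riskscore_neglog10p(s, d$time, d$event),
        cindex = harrell_c(s, d$time, d$event))
    }
    mt <- m_of(st, train); mv <- m_of(sv, validation)
    c(neglog10p_train = mt[["neglog10p"]],
      neglog10p_validation = mv[["neglog10p"]],
      cindex_train = mt[["cindex"]],
      cindex_validation = mv[["cindex"]])
  }
}

#' Run one simulated benchmarking replicate
#'
#' Generates one dataset, splits it 50--50, fits every requested method on
#' the training half, and evaluates selection counts against the planted
#' truth and risk-score metrics on both halves. An empty or degenerate
#' model scores at chance level (AUC/C-index 0.5, `-log10 p` 0). A method
#' that errors on a replicate is recorded with `NA` metrics rather than
#' dropped silently.
#'
#' @param simcfg A [sim_config()] (with any censoring window already
#'   calibrated, or calibratable on the fly).
#' @param sievecfg A [sieve_control()] for the sieving method.
#' @param methods Subset of `c("sieve", "lasso", "en", "oracle")`; the
#'   oracle refits the true features directly and serves as an internal
#'   upper benchmark.
#' @param rep_seed Integer seed for this replicate (drives data generation,
#'   the split, the sieve permutations, and the CV folds).
#' @param nlambda,lambda_min_ratio Lambda-path settings forwarded to
#'   [fit_penalized()].
#' @return A data frame with one row per method: selection counts and the
#'   family-appropriate train/validation metrics.
#' @export
run_trial <- function(simcfg, sievecfg = sieve_control(),
                      methods = c("sieve", "lasso", "en"),
                      rep_seed = 1L, nlambda = 100L,
                      lambda_min_ratio = NULL) {
  stopifnot(inherits(simcfg, "sim_config"))
  methods <- match.arg(methods, c("sieve", "lasso", "en", "oracle"),
                       several.ok = TRUE)
  simcfg$seed <- as.integer(rep_seed)
  sim <- simulate_dataset(simcfg)
  split <- holdout_split(simcfg$n, seed = rep_seed + 1L)
  train <- .subset_data(sim$data, split$train)
  validation <- .subset_data(sim$data, split$validation)
  family <- train$family

  metric_names <- if (family == "logistic") {
    c("auc_train", "auc_validation")
  } else {
    c("neglog10p_train", "neglog10p_validation",
      "cindex_train", "cindex_validation")
  }
  rows <- lapply(methods, function(method) {
    fit_sel <- tryCatch({
      if (method == "sieve") {
        ctl <- sievecfg; ctl$seed <- as.integer(rep_seed + 2L)
        rep <- repeated_sieving(train, ctl)
        list(fit = rep$final, selected = rep$final$selected)
      } else if (method == "oracle") {
        f <- joint_refit(train, sim$truth$true_ids)
        list(fit = f, selected = sim$truth$true_ids)
      } else {
        f <- fit_penalized(train,
                           penalty = if (method == "lasso") "lasso" else "elasticnet",
                           seed = rep_seed + 3L, nlambda = nlambda,
                           lambda_min_ratio = lambda_min_ratio)
        list(fit = f, selected = f$selected)
      }
    }, error = function(e) {
      warning("method '", method, "' failed on replicate seed ", rep_seed,
              ": ", conditionMessage(e))
      NULL
    })
    if (is.null(fit_sel)) {
      met <- stats::setNames(rep(NA_real_, length(metric_names)), metric_names)
      tot <- NA_integer_; tru <- NA_integer_
    } else {
      met <- .trial_metrics(family, fit_sel$fit, train, validation)
      tot <- length(fit_sel$selected)
      tru <- length(intersect(fit_sel$selected, sim$truth$true_ids))
    }
    cbind(data.frame(method = method, rep_seed = rep_seed,
                     total_selections = tot, true_selections = tru),
          as.data.frame(as.list(met)))
  })
  do.call(rbind, rows)
}

#' Run the full benchmarking study
#'
#' Repeats [run_trial()] over `N` independent replicates (sub-seeds drawn
#' from the master seed) and aggregates per-method means, mirroring the
#' layout of a selection-and-prediction summary table. For censored
#' survival configurations the censoring window is calibrated once and
#' shared across replicates.
#'
#' @inheritParams run_trial
#' @param N Number of replicates.
#' @param seed Master seed.
#' @return A `sieve_study`: `summary` (per-method means), `replicates` (the
#'   full per-replicate records), `N`, and the configurations. A replicate
#'   on which any method failed is excluded from every method's means
#'   (pairwise exclusion keeps the means comparable); `summary$n_used`
#'   reports the replicates actually averaged.
#' @export
run_study <- function(simcfg, sievecfg = sieve_control(),
                      methods = c("sieve", "lasso", "en"),
                      N = 100L, seed = 1L, nlambda = 100L,
                      lambda_min_ratio = NULL) {
  stopifnot(N >= 1L)
  if (simcfg$family == "survival" && !is.null(simcfg$censor_target) &&
      is.null(simcfg$censor_a)) {
    sim0 <- simulate_dataset(simcfg) # calibrates the window once
    simcfg <- sim0$cfg
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, N)
  reps <- do.call(rbind, lapply(rep_seeds, function(s) {
    run_trial(simcfg, sievecfg, methods = methods, rep_seed = s,
              nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
  }))
  num_cols <- setdiff(names(reps), c("method", "rep_seed"))
  # pairwise exclusion: a replicate where any method failed is dropped for
  # every method, so the reported means stay comparable across methods
  bad_seeds <- unique(reps$rep_seed[!stats::complete.cases(reps[num_cols])])
  kept <- reps[!(reps$rep_seed %in% bad_seeds), , drop = FALSE]
  if (length(bad_seeds)) {
    warning(length(bad_seeds), " replicate(s) excluded because a method failed")
  }
  summary <- do.call(rbind, lapply(unique(reps$method), function(mth) {
    sub <- kept[kept$method == mth, num_cols, drop = FALSE]
    out <- as.data.frame(as.list(colMeans(sub)))
    cbind(data.frame(method = mth, n_used = nrow(sub)), out)
  }))
  structure(list(summary = summary, replicates = reps, N = N,
                 simcfg = simcfg, sievecfg = sievecfg, seed = seed),
            class = "sieve_study")
}

#' @export
print.sieve_study <- function(x, ...) {
  cat("<sieve_study> ", x$N, " replicate(s), family = ", x$simcfg$family,
      ", n = ", x$simcfg$n, ", m = ", x$simcfg$m, "\n", sep = "")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write a study summary as a delimited table plus a JSON report
#'
#' @param study A `sieve_study` from [run_study()].
#' @param path Output path for the tab-separated summary grid; a JSON
#'   report with the full configuration, seed, and per-replicate records is
#'   written alongside with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "sieve_study"))
  utils::write.table(study$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  obj <- list(package = "resieve",
              version = as.character(utils::packageVersion("resieve")),
              seed = study$seed, N = study$N,
              sim_config = unclass(study$simcfg),
              sieve_control = unclass(study$sievecfg),
              summary = study$summary, replicates = study$replicates)
  jsonlite::write_json(obj, sub("\\.[^.]*$|$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
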