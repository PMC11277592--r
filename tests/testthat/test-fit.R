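test_that("logistic MLE matches closed forms and a grid oracle", {
  # intercept-only model: logit of the response rate
  f0 <- fit_logistic(NULL, rep(c(1, 0), c(30, 70)))
  expect_equal(unname(f0$coefficients), log(30 / 70), tolerance = 1e-8)

  # 2x2 design, counts a=40 b=10 c=10 d=40: slope = log odds ratio
  x <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  f <- fit_logistic(matrix(x, ncol = 1), y)
  expect_equal(unname(f$coefficients[2]), log(16), tolerance = 1e-8)

  # independent check: maximize the hand-written likelihood numerically
  opt <- optim(c(0, 0), function(b) -bf_logistic_loglik(b[1], b[2], x, y),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(f$coefficients), opt$par, tolerance = 1e-5)
  expect_equal(f$loglik, -opt$value, tolerance = 1e-8)
})

test_that("logistic fit agrees with stats::glm on random designs", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 80; k <- 3
    X <- matrix(rnorm(n * k), n, k)
    y <- rbinom(n, 1, plogis(0.5 * X[, 1] - 0.3 * X[, 2]))
    f <- fit_logistic(X, y)
    g <- glm(y ~ X, family = binomial())
    sg <- summary(g)$coefficients
    expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-7)
    expect_equal(unname(f$se), unname(sg[, 2]), tolerance = 1e-6)
    expect_equal(unname(f$p_value), unname(sg[, 4]), tolerance = 1e-5)
    expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  }
})

test_that("null logistic p-values are approximately uniform", {
  set.seed(99)
  p <- replicate(300, {
    x <- matrix(rnorm(60), ncol = 1)
    y <- rbinom(60, 1, 0.5)
    fit_logistic(x, y)$p_value[[2]]
  })
  expect_gt(ks.test(p, "punif")$p.value, 1e-3)
})

test_that("logistic degenerate inputs are flagged, not returned as valid", {
  # complete separation
  x <- c(rep(0, 20), rep(1, 20))
  f <- fit_logistic(matrix(x, ncol = 1), x)
  expect_false(f$converged)
  # rank deficiency names the offending column
  y <- rbinom(40, 1, 0.5)
  expect_error(fit_logistic(cbind(a = x, b = x), y), "b")
  # too many covariates
  expect_error(fit_logistic(matrix(rnorm(20 * 25), 20, 25), rbinom(20, 1, 0.5)),
               "k >= n")
})

test_that("logistic fit is invariant to affine covariate rescaling", {
  set.seed(7)
  X <- matrix(rnorm(200), 100, 2)
  y <- rbinom(100, 1, plogis(X[, 1]))
  f1 <- fit_logistic(X, y)
  X2 <- X; X2[, 1] <- 10 * X2[, 1] + 3
  f2 <- fit_logistic(X2, y)
  expect_equal(f2$p_value[[2]], f1$p_value[[2]], tolerance = 1e-6)
  expect_equal(f2$coefficients[[2]], f1$coefficients[[2]] / 10, tolerance = 1e-6)
})

test_that("Cox MLE matches a dense grid search of the partial likelihood", {
  set.seed(3)
  z <- rnorm(6)
  tt <- 1:6 # no censoring, no ties
  f <- fit_cox(matrix(z, ncol = 1), tt, rep(1, 6))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, bf_cox_partial_loglik, numeric(1), z = z, time = tt)
  expect_equal(unname(f$coefficients), grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(f$loglik, max(ll), tolerance = 1e-6)
})

test_that("Cox fit agrees with survival::coxph (Efron ties)", {
  set.seed(11)
  n <- 90
  X <- matrix(rnorm(n * 2), n, 2)
  tt <- ceiling(rexp(n, 0.1 * exp(0.6 * X[, 1])))  # integer times force ties
  ev <- rbinom(n, 1, 0.8)
  f <- fit_cox(X, tt, ev)
  cp <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "efron")
  expect_equal(unname(f$coefficients), unname(coef(cp)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(cp)))), tolerance = 1e-6)
  expect_equal(f$loglik, cp$loglik[2], tolerance = 1e-8)
})

test_that("Cox degenerate inputs error or flag non-convergence", {
  tt <- 1:6
  # monotone likelihood: covariate perfectly orders the event times
  expect_warning(f <- fit_cox(matrix(as.numeric(1:6), ncol = 1), tt,
                              rep(1, 6)))
  expect_false(f$converged)
  # constant covariate: no information
  expect_error(fit_cox(matrix(1.0, 6, 1), tt, rep(1, 6)), "rank-deficient")
  # no events
  expect_error(fit_cox(matrix(rnorm(6), ncol = 1), tt, rep(0, 6)), "no events")
})

test_that("Cox estimate depends on time ranks only", {
  set.seed(4)
  z <- matrix(rnorm(50), 50, 1)
  tt <- rexp(50, 0.1 * exp(0.5 * z))
  ev <- rbinom(50, 1, 0.8); ev[1] <- 1
  f1 <- fit_cox(z, tt, ev)
  f2 <- fit_cox(z, log(tt + 1), ev)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("null Cox estimates center on zero over replicates", {
  set.seed(21)
  betas <- replicate(60, {
    z <- matrix(rnorm(60), 60, 1)
    fit_cox(z, rexp(60, 0.1), rbinom(60, 1, 0.8))$coefficients[[1]]
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("returned estimates are local maxima of their likelihoods", {
  set.seed(13)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(X[, 1]))
  f <- fit_logistic(X, y)
  ll_log <- function(b) {
    eta <- b[1] + X %*% b[2:3]
    sum(y * eta - log1p(exp(eta)))
  }
  b_hat <- unname(f$coefficients)
  for (i in 1:20) {
    expect_lte(ll_log(b_hat + rnorm(3, sd = 1e-3)), f$loglik + 1e-12)
  }

  tt <- rexp(n, 0.1 * exp(0.5 * X[, 1])); ev <- rep(1, n)
  fc <- fit_cox(X[, 1, drop = FALSE], tt, ev)
  ll_cox <- function(b) bf_cox_partial_loglik(b, X[, 1], tt)
  for (i in 1:20) {
    expect_lte(ll_cox(unname(fc$coefficients) + rnorm(1, sd = 1e-3)),
               fc$loglik + 1e-12)
  }
})
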