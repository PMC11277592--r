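# Independent brute-force oracles used to validate the package's metric and
# likelihood computations. These deliberately share no code with R/.

# Mann-Whitney AUC by O(n^2) pair counting, ties count one half.
bf_auc <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(controls))
}

# Harrell's C by usable-pair enumeration. Pair (i, j) is usable when the
# subject with the strictly shorter observed time had an event; at tied
# times an event "precedes" a censoring. Tied observed event times are not
# usable. Score ties on usable pairs count one half.
bf_cindex <- function(scores, time, event) {
  n <- length(time)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] == event[j]) next
        short <- if (event[i] == 1) i else j
      } else {
        short <- if (time[i] < time[j]) i else j
      }
      long <- if (short == i) j else i
      if (event[short] != 1) next
      usable <- usable + 1
      conc <- conc + (scores[short] > scores[long]) +
        0.5 * (scores[short] == scores[long])
    }
  }
  if (usable == 0) stop("no usable pairs")
  conc / usable
}

# Bernoulli log-likelihood, written independently of the package.
bf_logistic_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Breslow-free partial log-likelihood for untied times, one covariate.
bf_cox_partial_loglik <- function(beta, z, time) {
  s <- 0
  for (i in seq_along(time)) {
    risk <- time >= time[i]
    s <- s + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  s
}

# Small random censored survival sample with tied times (integer grid).
rand_censored <- function(n, seed) {
  set.seed(seed)
  list(time = sample(1:8, n, replace = TRUE),
       event = rbinom(n, 1, 0.7),
       scores = sample(seq(-2, 2, by = 0.5), n, replace = TRUE))
}

# Quick planted-signal binary dataset.
planted_binary <- function(n, m, truth_col, beta, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  y <- rbinom(n, 1, plogis(beta * X[, truth_col]))
  sieve_data(X, y = y)
}
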