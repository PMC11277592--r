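test_that("feature generator honors the block covariance structure", {
  cfg <- sim_config(n = 4000, m = 100, block_len = 20, rho = 0.2, m1 = 6,
                    family = "binary", seed = 1)
  set.seed(cfg$seed)
  X <- gen_features(cfg)
  expect_equal(dim(X), c(4000, 100))
  expect_equal(unname(apply(X, 2, sd)[1:5]), rep(1, 5), tolerance = 0.1)

  C <- cor(X)
  within <- c(C[1:20, 1:20][upper.tri(diag(20))])
  cross <- c(C[1:20, 21:40])
  expect_equal(mean(within), 0.2, tolerance = 0.03)
  expect_lt(abs(mean(cross)), 0.03)

  # rho = 0 gives independent features
  cfg0 <- sim_config(n = 4000, m = 40, rho = 0, m1 = 2, family = "binary",
                     seed = 2)
  set.seed(2)
  X0 <- gen_features(cfg0)
  off <- cor(X0)[upper.tri(diag(40))]
  expect_lt(max(abs(off)), 0.08)

  # determinism under a fixed seed
  set.seed(3); A <- gen_features(cfg0)
  set.seed(3); B <- gen_features(cfg0)
  expect_identical(A, B)
})

test_that("sample covariance approaches the target as n grows", {
  cfg_small <- sim_config(n = 300, m = 40, rho = 0.2, m1 = 2,
                          family = "binary")
  cfg_big <- sim_config(n = 5000, m = 40, rho = 0.2, m1 = 2,
                        family = "binary")
  target <- matrix(0, 40, 40)
  for (b in 0:1) target[b * 20 + 1:20, b * 20 + 1:20] <- 0.2
  diag(target) <- 1
  set.seed(4)
  d_small <- norm(cov(gen_features(cfg_small)) - target, "F")
  d_big <- norm(cov(gen_features(cfg_big)) - target, "F")
  expect_lt(d_big, d_small)
})

test_that("true features are planted pairwise with alternating signs", {
  cfgb <- sim_config(family = "binary")
  tb <- place_true_features(cfgb)
  expect_equal(tb$true_betas, c(2, -2, 2, -2, 2, -2))
  expect_identical(tb$true_ids,
                   sprintf("f%05d", c(1, 2, 21, 22, 41, 42)))

  cfgs <- sim_config(family = "survival")
  expect_equal(place_true_features(cfgs)$true_betas,
               c(0.7, -0.7, 0.7, -0.7, 0.7, -0.7))

  cfg2 <- sim_config(m = 40, m1 = 2, family = "binary")
  t2 <- place_true_features(cfg2)
  expect_length(t2$true_ids, 2)

  # randomized placement keeps each pair inside one correlation block
  set.seed(5)
  tr <- place_true_features(cfgb, randomize = TRUE)
  idx <- as.integer(sub("f", "", tr$true_ids))
  blk <- (idx - 1) %/% cfgb$block_len
  expect_equal(blk[c(1, 3, 5)], blk[c(2, 4, 6)])
  expect_length(unique(blk), 3)
})

test_that("binary outcomes follow the logistic model", {
  cfg <- sim_config(family = "binary")
  truth <- place_true_features(cfg)
  # zero covariates give response probability exactly one half
  set.seed(6)
  y0 <- gen_binary_outcome(matrix(0, 20000, 6), truth)
  expect_equal(mean(y0), 0.5, tolerance = 0.02)
  # alternating signs + symmetric Gaussians: marginal response rate 1/2
  set.seed(7)
  Z <- gen_features(sim_config(n = 20000, m = 60, family = "binary"))[, truth$true_ids]
  y <- gen_binary_outcome(Z, truth)
  expect_equal(mean(y), 0.5, tolerance = 0.02)
})

test_that("survival outcomes follow the exponential hazard model", {
  cfg <- sim_config(family = "survival")
  truth <- place_true_features(cfg)
  truth0 <- truth; truth0$true_betas <- rep(0, 6)
  set.seed(8)
  out <- gen_survival_outcome(matrix(0, 20000, 6), truth0, cfg)
  expect_true(all(out$event == 1))
  expect_equal(mean(out$time), 10, tolerance = 0.3) # 1 / h0
})

test_that("censoring calibration hits its target and is reproducible", {
  cfg <- sim_config(family = "survival", censor_target = 0.30)
  cal30 <- calibrate_censoring(cfg, 0.30)
  expect_equal(cal30$achieved, 0.30, tolerance = 0.005)
  cal30b <- calibrate_censoring(cfg, 0.30)
  expect_identical(cal30$a, cal30b$a)

  cal10 <- calibrate_censoring(cfg, 0.10, anchor_a = cal30$a)
  expect_equal(cal10$achieved, 0.10, tolerance = 0.005)
  expect_identical(cal10$a, cal30$a)

  # lighter censoring needs a longer accrual window
  cal50 <- calibrate_censoring(cfg, 0.50)
  expect_lt(cal50$a, cal30$a)

  # an impossible anchored target reports the bracketing failure
  expect_error(calibrate_censoring(cfg, 0.9, anchor_a = cal30$a),
               "not bracketed")

  # independent verification draws under the calibrated windows
  cfg$censor_a <- cal30$a
  cfg$seed <- 9L
  cfg$n <- 10000L; cfg$m <- 60L
  sim <- simulate_dataset(cfg)
  expect_lt(abs(mean(sim$data$event == 0) - 0.30), 0.015)

  cfg$censor_b <- cal10$b
  cfg$censor_target <- 0.10
  sim10 <- simulate_dataset(cfg)
  expect_lt(abs(mean(sim10$data$event == 0) - 0.10), 0.015)
})

test_that("uncalibrated censored generation demands calibration", {
  cfg <- sim_config(family = "survival", censor_target = 0.30)
  truth <- place_true_features(cfg)
  expect_error(gen_survival_outcome(matrix(0, 5, 6), truth, cfg),
               "calibrat")
})

test_that("hold-out split is uniform, disjoint, and reproducible", {
  s <- holdout_split(400, seed = 10)
  expect_length(s$train, 200)
  expect_length(s$validation, 200)
  expect_setequal(c(s$train, s$validation), 1:400)

  s5 <- holdout_split(5, seed = 11)
  expect_length(s5$train, 3)
  expect_length(s5$validation, 2)

  expect_identical(holdout_split(100, seed = 12), holdout_split(100, seed = 12))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(m = 101, block_len = 20), "divisible")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(m1 = 5), "even")
  expect_error(sim_config(m = 40, m1 = 6), "blocks")
  expect_error(sim_config(family = "survival", censor_target = 1.2), "0, 1")
})
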