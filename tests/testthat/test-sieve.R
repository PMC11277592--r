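test_that("block partition covers features exactly with a remainder block", {
  ids <- sprintf("f%05d", 1:10000)
  b <- partition_blocks(ids, 50)
  expect_length(b, 200)
  expect_true(all(lengths(b) == 50))
  expect_identical(unlist(b), ids)

  b2 <- partition_blocks(sprintf("g%03d", 1:103), 50)
  expect_identical(lengths(b2), c(50L, 50L, 3L))

  expect_length(partition_blocks(ids[1:50], 50), 1)
  expect_warning(b3 <- partition_blocks(ids[1:10], 50), "single block")
  expect_length(b3, 1)
})

test_that("sieving is deterministic given a seed", {
  d <- planted_binary(n = 120, m = 100, truth_col = 10, beta = 2, seed = 81)
  ctl <- sieve_control(block_size = 20, permutations = 3, seed = 5)
  s1 <- sieve_one_permutation(d, ctl, seed = 9)
  s2 <- sieve_one_permutation(d, ctl, seed = 9)
  expect_identical(s1, s2)
  r1 <- repeated_sieving(d, ctl)
  r2 <- repeated_sieving(d, ctl)
  expect_identical(r1$pool, r2$pool)
  expect_identical(r1$final$selected, r2$final$selected)
})

test_that("the candidate pool is monotone in the number of permutations", {
  d <- planted_binary(n = 120, m = 150, truth_col = 10, beta = 2, seed = 82)
  ctl2 <- sieve_control(block_size = 25, permutations = 2, seed = 6)
  ctl5 <- sieve_control(block_size = 25, permutations = 5, seed = 6)
  r2 <- repeated_sieving(d, ctl2)
  r5 <- repeated_sieving(d, ctl5)
  expect_true(all(r2$pool %in% r5$pool))
  # cumulative union sizes are non-decreasing within a round
  expect_true(all(diff(r5$pool_trajectory[[1]]) >= 0))
})

test_that("with one block and one permutation sieving collapses to stepwise", {
  d <- planted_binary(n = 150, m = 30, truth_col = 4, beta = 2, seed = 83)
  ctl <- sieve_control(block_size = 50, permutations = 1,
                       alpha_in = 0.05, alpha_out = 0.1,
                       final_alpha_in = 0.01, final_alpha_out = 0.02, seed = 7)
  expect_warning(r <- repeated_sieving(d, ctl), "single block")
  sieved <- forward_stepwise(d, alpha_in = 0.05, alpha_out = 0.1)$selected
  expect_setequal(r$pool, sieved)
  direct <- forward_stepwise(d, candidates = sort(sieved),
                             alpha_in = 0.01, alpha_out = 0.02)
  expect_identical(r$final$selected, direct$selected)
})

test_that("correlated true pairs are recovered better when sharing a block", {
  # two correlated features that only predict jointly (opposite signs)
  gen <- function(seed) {
    set.seed(seed)
    n <- 150; m <- 40; rho <- 0.7
    X <- matrix(rnorm(n * m), n, m)
    X[, 2] <- rho * X[, 1] + sqrt(1 - rho^2) * X[, 2]
    y <- rbinom(n, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
    sieve_data(X, y = y)
  }
  ctl <- sieve_control(block_size = 20, permutations = 1,
                       alpha_in = 0.01, alpha_out = 0.02)
  joint_same <- joint_split <- 0
  for (seed in 1:8) {
    d <- gen(840 + seed)
    same <- sieve_one_permutation(d, ctl, order = d$feature_ids)
    apart <- sieve_one_permutation(d, ctl,
      order = d$feature_ids[c(1, 3:21, 2, 22:40)])
    joint_same <- joint_same + all(c("f00001", "f00002") %in% same)
    joint_split <- joint_split + all(c("f00001", "f00002") %in% apart)
  }
  expect_gte(joint_same, joint_split)
  expect_gte(joint_same, 6)
})

test_that("more permutations cannot hurt joint recovery of a split pair", {
  set.seed(85)
  n <- 150; m <- 60
  X <- matrix(rnorm(n * m), n, m)
  X[, 31] <- 0.7 * X[, 1] + sqrt(1 - 0.49) * X[, 31]
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 2 * X[, 31]))
  d <- sieve_data(X, y = y)
  hit <- function(P, seed) {
    ctl <- sieve_control(block_size = 30, permutations = P, seed = seed,
                         first_permutation_identity = TRUE)
    r <- repeated_sieving(d, ctl)
    all(c("f00001", "f00031") %in% r$pool)
  }
  h1 <- mean(vapply(1:6, function(s) hit(1, s), logical(1)))
  h6 <- mean(vapply(1:6, function(s) hit(6, s), logical(1)))
  expect_gte(h6, h1)
})

test_that("an unproductive sieve yields an empty, flagged final model", {
  set.seed(86)
  X <- matrix(rnorm(60 * 40), 60, 40)
  d <- sieve_data(X, y = rbinom(60, 1, 0.5))
  ctl <- sieve_control(block_size = 20, permutations = 2,
                       alpha_in = 1e-8, alpha_out = 2e-8, seed = 8)
  expect_warning(r <- repeated_sieving(d, ctl), "empty")
  expect_length(r$final$selected, 0)
  expect_true(r$empty_pool)
})

test_that("the final model satisfies its certificate and lies in the pool", {
  d <- planted_binary(n = 200, m = 120, truth_col = 60, beta = 2, seed = 87)
  ctl <- sieve_control(block_size = 30, permutations = 4,
                       final_alpha_in = 0.01, final_alpha_out = 0.02, seed = 9)
  r <- repeated_sieving(d, ctl)
  expect_true(all(r$final$selected %in% r$pool))
  if (length(r$final$selected)) {
    pv <- r$final$fit$p_value
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    expect_true(all(pv <= ctl$final_alpha_out))
  }
})

test_that("sieve reports serialize to JSON with config and seed", {
  d <- planted_binary(n = 120, m = 40, truth_col = 4, beta = 2, seed = 88)
  ctl <- sieve_control(block_size = 20, permutations = 2, seed = 10,
                       final_alpha_in = 0.05, final_alpha_out = 0.1)
  r <- repeated_sieving(d, ctl)
  path <- withr::local_tempfile(fileext = ".json")
  write_sieve_report(r, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$control$seed, 10)
  expect_identical(unlist(obj$selected), r$final$selected)
})
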