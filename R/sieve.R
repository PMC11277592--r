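# Repeated sieving: permute the feature order, partition into small blocks,
# run forward stepwise within each block, pool the union of selections over
# many permutations, then fit the final model by forward stepwise on the
# pooled candidates under (usually stricter) final thresholds.

#' Control parameters for repeated sieving
#'
#' @param block_size Features per block (`m0`); small enough for an
#'   unpenalized stepwise fit to be fast and stable. Default 50.
#' @param permutations Number of feature-order permutations `P` pooled per
#'   sieving round.
#' @param alpha_in,alpha_out Insertion/deletion thresholds used within each
#'   block.
#' @param final_alpha_in,final_alpha_out Thresholds for the final stepwise
#'   fit on the pooled candidates.
#' @param pool_cap If the pooled candidate set exceeds this size and rounds
#'   remain, another sieving round is applied to the pool before the final
#'   fit. Default 1000.
#' @param max_rounds Maximum sieving rounds. Default 2.
#' @param max_selected Safety cap forwarded to the final stepwise fit.
#' @param first_permutation_identity If `TRUE` (default) the first
#'   "permutation" of round one keeps the original feature order, so the
#'   natural blocking of the data is always sieved once.
#' @param seed Optional integer master seed. Each permutation receives its
#'   own sub-seed drawn from the master stream, so results are reproducible
#'   and individual permutations are independent computational units.
#' @return A `sieve_control` list.
#' @export
sieve_control <- function(block_size = 50L, permutations = 100L,
                          alpha_in = 0.01, alpha_out = 0.02,
                          final_alpha_in = 0.0025, final_alpha_out = 0.005,
                          pool_cap = 1000L, max_rounds = 2L,
                          max_selected = 50L,
                          first_permutation_identity = TRUE,
                          seed = NULL) {
  stopifnot(block_size >= 2L, permutations >= 1L, max_rounds >= 1L,
            pool_cap >= 1L, max_selected >= 1L)
  if (alpha_out < alpha_in) stop("alpha_out must be >= alpha_in")
  if (final_alpha_out < final_alpha_in) {
    stop("final_alpha_out must be >= final_alpha_in")
  }
  structure(list(block_size = as.integer(block_size),
                 permutations = as.integer(permutations),
                 alpha_in = alpha_in, alpha_out = alpha_out,
                 final_alpha_in = final_alpha_in,
                 final_alpha_out = final_alpha_out,
                 pool_cap = as.integer(pool_cap),
                 max_rounds = as.integer(max_rounds),
                 max_selected = as.integer(max_selected),
                 first_permutation_identity =
                   isTRUE(first_permutation_identity),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sieve_control")
}

#' Partition an ordered feature list into contiguous blocks
#'
#' @param feature_order Character vector: a permutation of the feature ids.
#' @param block_size Target block size `m0`. When the number of features is
#'   not a multiple of `block_size`, the last block holds the remainder
#'   (features are never dropped). If `block_size` exceeds the number of
#'   features a single block is returned with a warning.
#' @return A list of character vectors that exactly partition
#'   `feature_order`.
#' @examples
#' length(partition_blocks(sprintf("f%03d", 1:103), 50))  # sizes 50, 50, 3
#' @export
partition_blocks <- function(feature_order, block_size) {
  m <- length(feature_order)
  stopifnot(m >= 1L, block_size >= 1L)
  if (block_size > m) {
    warning("block_size exceeds the number of features; using a single block")
    return(list(feature_order))
  }
  idx <- ceiling(seq_len(m) / block_size)
  unname(split(feature_order, idx))
}

#' Sieve one permutation of the feature order
#'
#' Draws a uniform random permutation of the candidate features (or uses the
#' order given), partitions it into blocks, runs [forward_stepwise()] within
#' each block under the block-level thresholds, and returns the union of the
#' per-block selections. A block whose stepwise run fails contributes the
#' empty set.
#'
#' @param data A [sieve_data] object (training data).
#' @param control A [sieve_control()] object.
#' @param features Candidate pool; defaults to all features.
#' @param order Optional explicit feature order (overrides the random draw).
#' @param seed Optional seed for the permutation draw.
#' @return Character vector of sieved feature ids.
#' @export
sieve_one_permutation <- function(data, control = sieve_control(),
                                  features = data$feature_ids,
                                  order = NULL, seed = NULL) {
  stopifnot(inherits(data, "sieve_data"))
  if (is.null(order)) {
    if (!is.null(seed)) set.seed(seed)
    order <- sample(features)
  }
  blocks <- partition_blocks(order, control$block_size)
  sieved <- character(0)
  for (b in blocks) {
    res <- tryCatch(
      forward_stepwise(data, candidates = b,
                       alpha_in = control$alpha_in,
                       alpha_out = control$alpha_out,
                       max_selected = control$max_selected),
      error = function(e) NULL)
    if (!is.null(res)) sieved <- c(sieved, res$selected)
  }
  unique(sieved)
}

#' Repeated sieving
#'
#' Runs [sieve_one_permutation()] `P` times on the training data and pools
#' the union of all sieved features. If the pool still exceeds `pool_cap`
#' and rounds remain, a further sieving round (same settings) is applied to
#' the pooled features only. The final prediction model is then fitted by
#' [forward_stepwise()] on the pooled candidates under
#' `(final_alpha_in, final_alpha_out)`, with candidates presented in
#' original feature order so the result is deterministic given the pool.
#'
#' @param data A [sieve_data] object (training data).
#' @param control A [sieve_control()] object.
#' @return A `sieve_report`: `final` (the final `sieve_selection`), `pool`
#'   (the pooled candidate ids after the last round), `pool_trajectory`
#'   (per round, the cumulative union size after each permutation),
#'   `rounds`, `control`, and `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n = 150, m = 200, family = "binary",
#'                                    seed = 1))
#' rep <- repeated_sieving(sim$data, sieve_control(permutations = 3, seed = 2))
#' rep$final$selected
#' }
#' @export
repeated_sieving <- function(data, control = sieve_control()) {
  stopifnot(inherits(data, "sieve_data"), inherits(control, "sieve_control"))
  if (!is.null(control$seed)) set.seed(control$seed)

  pool <- data$feature_ids
  trajectory <- list()
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    sieved <- character(0)
    sizes <- integer(control$permutations)
    for (p in seq_len(control$permutations)) {
      perm_seed <- sample.int(.Machine$integer.max, 1L)
      ord <- if (p == 1L && rounds == 1L && control$first_permutation_identity) {
        pool
      } else {
        NULL
      }
      sieved <- union(sieved,
                      sieve_one_permutation(data, control, features = pool,
                                            order = ord, seed = perm_seed))
      sizes[p] <- length(sieved)
    }
    trajectory[[rounds]] <- sizes
    pool <- sieved
    if (length(pool) <= control$pool_cap || rounds >= control$max_rounds) break
  }

  flagged_empty <- length(pool) == 0L
  if (flagged_empty) {
    warning("sieving produced an empty candidate pool; final model is empty")
    final <- structure(list(selected = character(0),
                            fit = if (data$family == "logistic") {
                              joint_refit(data, character(0))
                            } else NULL,
                            trace = data.frame(step = integer(0),
                                               action = character(0),
                                               feature = character(0),
                                               p_value = numeric(0)),
                            alpha_in = control$final_alpha_in,
                            alpha_out = control$final_alpha_out,
                            family = data$family),
                       class = "sieve_selection")
  } else {
    pool <- pool[order(match(pool, data$feature_ids))]
    final <- forward_stepwise(data, candidates = pool,
                              alpha_in = control$final_alpha_in,
                              alpha_out = control$final_alpha_out,
                              max_selected = control$max_selected)
  }

  structure(list(final = final, pool = pool,
                 pool_trajectory = trajectory, rounds = rounds,
                 empty_pool = flagged_empty,
                 control = control, seed = control$seed),
            class = "sieve_report")
}

#' @export
print.sieve_report <- function(x, ...) {
  cat("<sieve_report> ", x$rounds, " round(s), ",
      x$control$permutations, " permutation(s)/round, block size ",
      x$control$block_size, "\n", sep = "")
  cat("  pooled candidates: ", length(x$pool), "\n", sep = "")
  cat("  final model: ", length(x$final$selected), " feature(s)\n", sep = "")
  if (length(x$final$selected)) {
    cat("  ", paste(x$final$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a sieve report to a structured text file
#'
#' Writes the selected features with their coefficients and p-values, the
#' pool trajectory, and the configuration (including the seed) as JSON, so
#' a run can be audited and reproduced.
#'
#' @param report A `sieve_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sieve_report <- function(report, path) {
  stopifnot(inherits(report, "sieve_report"))
  fit <- report$final$fit
  obj <- list(
    package = "resieve",
    version = as.character(utils::packageVersion("resieve")),
    family = report$final$family,
    control = unclass(report$control),
    seed = report$seed,
    rounds = report$rounds,
    pool = report$pool,
    pool_trajectory = report$pool_trajectory,
    selected = report$final$selected,
    coefficients = if (!is.null(fit)) as.list(fit$coefficients),
    p_values = if (!is.null(fit)) as.list(fit$p_value))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
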