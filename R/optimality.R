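#' Default parameter grid for the optimality analysis
#'
#' Value-guided axis from 0 to an upper bound scaled to each task's
#' parameter range (21 points) crossed with a directed axis from -2 to 2
#' (21 points). Side bias and the random-exploration weight are held at 0.
#'
#' @param task Task id.
#' @param n_value,n_directed Number of grid points per axis.
#' @return Tibble with columns `value_guided` and `directed`.
#' @export
default_grid <- function(task, n_value = 21L, n_directed = 21L) {
  task <- check_task(task)
  v_max <- switch(task, restless = 1, twoarmed = 1, horizon = 1)
  tidyr::expand_grid(
    value_guided = seq(0, v_max, length.out = n_value),
    directed = seq(-2, 2, length.out = n_directed)
  )
}

grid_params_object <- function(task, value_guided, directed) {
  switch(task,
    restless = restless_params(value_guided, directed),
    twoarmed = twoarmed_params(0, value_guided, directed, variant = "improved"),
    horizon = horizon_params(
      long = c(side_bias = 0, value_guided = value_guided, directed = directed),
      variant = "improved"
    )
  )
}

#' Mean earned reward over a parameter grid
#'
#' For every grid cell, simulates choices with the cell's parameters on the
#' fixed reward set and records the mean earned reward per free choice,
#' averaged over `n_reps` repetitions. Repetition seeds are shared across
#' cells so that cell contrasts are paired. The restless bandit simulates
#' `restless_trials` choices (50 by default, matching the optimality
#' analysis; the full 200-trial round is available by configuration).
#'
#' @param task Task id.
#' @param rewardset A `reward_set` for the task.
#' @param grid Tibble of `value_guided` x `directed` cells.
#' @param learner_cfg Optional [learner_config()].
#' @param n_reps Simulation repetitions per cell.
#' @param seed Integer seed.
#' @param restless_trials Number of simulated restless choices per rep.
#' @return A list of class `optimality_grid`: `grid` (tibble with
#'   `mean_reward` and `se` per cell), `best` (argmax row), `n_reps`,
#'   `task`, `seed`.
#' @export
reward_grid <- function(task, rewardset, grid = default_grid(task),
                        learner_cfg = NULL, n_reps = 200L, seed = 1L,
                        restless_trials = 50L) {
  task <- check_task(task)
  stopifnot(inherits(rewardset, "reward_set"), nrow(grid) >= 1L,
            rewardset$task == task)
  rep_seeds <- vapply(seq_len(n_reps), function(r) derive_seed(seed, "rep", r),
                      integer(1))
  res <- matrix(NA_real_, nrow(grid), n_reps)
  for (ci in seq_len(nrow(grid))) {
    params <- grid_params_object(task, grid$value_guided[ci], grid$directed[ci])
    for (r in seq_len(n_reps)) {
      ses <- simulate_session(rewardset, params, learner_cfg,
                              seed = rep_seeds[r],
                              n_trials = if (task == "restless") restless_trials else NULL)
      res[ci, r] <- mean(ses$reward[ses$forced == 0L])
    }
  }
  out <- grid
  out$mean_reward <- rowMeans(res)
  out$se <- apply(res, 1L, sd) / sqrt(n_reps)
  structure(
    list(grid = out, best = out[which.max(out$mean_reward), ],
         rep_rewards = res,  # cells x reps, shared rep seeds enable paired contrasts
         n_reps = as.integer(n_reps), task = task, seed = as.integer(seed)),
    class = "optimality_grid"
  )
}

#' @export
print.optimality_grid <- function(x, ...) {
  cat(sprintf("<optimality_grid: %s, %d cells x %d reps>\nbest cell:\n",
              x$task, nrow(x$grid), x$n_reps))
  print(x$best)
  invisible(x)
}

#' Information value of forced exploration in the Horizon task
#'
#' For every unequal-information long-horizon round, compares the best-arm
#' estimate from the forced-trial sample means before vs after
#' deterministically choosing the less-explored arm on the first free choice
#' and observing its reward. Reports the fraction of eligible rounds on
#' which the estimate of the better arm flips, and, among flips, the
#' fraction in which the post-flip estimate matches the truly better arm
#' (by latent means).
#'
#' @param rewardset A Horizon `reward_set`.
#' @return A list of class `info_value_report`: `flip_fraction`,
#'   `improve_fraction` (NA when there are no flips), `n_eligible`,
#'   `n_flips`.
#' @export
horizon_info_value <- function(rewardset) {
  stopifnot(inherits(rewardset, "reward_set"), rewardset$task == "horizon")
  rounds <- rewardset$rounds
  elig <- rounds[rounds$horizon == "long" & rounds$info == "unequal", ]
  if (nrow(elig) == 0L) stop("no unequal-information long-horizon rounds",
                             call. = FALSE)
  rms <- reward_matrices(rewardset)
  lms <- latent_matrices(rewardset)
  flips <- 0L; improved <- 0L
  for (i in seq_len(nrow(elig))) {
    rd <- elig[i, ]
    rm_ <- rms[[as.character(rd$round)]]
    forced_arms <- as.integer(rd[paste0("f", 1:4)])
    forced_rewards <- rm_[cbind(1:4, forced_arms)]
    feats <- horizon_features(forced_arms, forced_rewards)
    best_before <- which.max(feats$means)
    less <- rd$less_sampled_arm
    r5 <- rm_[5L, less]
    sums <- feats$means * feats$counts
    sums[less] <- sums[less] + r5
    counts <- feats$counts
    counts[less] <- counts[less] + 1L
    best_after <- which.max(sums / counts)
    if (best_after != best_before) {
      flips <- flips + 1L
      true_best <- which.max(lms[[as.character(rd$round)]][5L, ])
      if (best_after == true_best) improved <- improved + 1L
    }
  }
  structure(
    list(flip_fraction = flips / nrow(elig),
         improve_fraction = if (flips > 0L) improved / flips else NA_real_,
         n_eligible = nrow(elig), n_flips = flips),
    class = "info_value_report"
  )
}

#' @export
print.info_value_report <- function(x, ...) {
  cat(sprintf("forced exploration flipped the best-arm estimate on %.1f%% of %d rounds",
              100 * x$flip_fraction, x$n_eligible))
  if (!is.na(x$improve_fraction)) {
    cat(sprintf("; %.1f%% of flips improved accuracy", 100 * x$improve_fraction))
  }
  cat("\n")
  invisible(x)
}
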