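#' Configuration for the restless-bandit reward walk
#'
#' The four-armed restless bandit pays out from latent arm means that follow
#' a mean-reverting random walk,
#' \eqn{\mu_{t+1} = \lambda \mu_t + (1 - \lambda)\theta + \epsilon_t},
#' with innovation noise \eqn{\epsilon_t \sim N(0, \sigma_{innov}^2)}.
#' Realized rewards add observation noise around the latent mean.
#'
#' @param decay_rate Decay rate \eqn{\lambda} of the walk, in (0, 1].
#' @param decay_center Long-run center \eqn{\theta} of the walk (reward units).
#' @param innovation_sd Standard deviation of the per-trial innovations.
#' @param reward_noise_sd Standard deviation of the observation noise added to
#'   the latent mean when a reward is realized.
#' @param n_arms Number of arms (>= 2).
#' @param n_trials Number of choices in the single round.
#' @param initial_means Optional numeric vector of starting latent means, one
#'   per arm. When `NULL`, starts are drawn uniformly in \[30, 70\].
#' @param integer_rewards Round realized rewards to integers and clip to
#'   \[1, 99\] (slot-machine point display); latent means keep full precision.
#' @param min_best_arm_changes Reward sets are re-sampled until the identity of
#'   the best arm changes at least this many times across trials.
#' @param max_best_run Maximum number of consecutive trials a single arm may
#'   stay the best arm.
#' @return A list of class `restless_config`.
#' @export
restless_config <- function(decay_rate = 0.9836,
                            decay_center = 50,
                            innovation_sd = 2.8,
                            reward_noise_sd = 4,
                            n_arms = 4L,
                            n_trials = 200L,
                            initial_means = NULL,
                            integer_rewards = TRUE,
                            min_best_arm_changes = 5L,
                            max_best_run = 80L) {
  if (decay_rate <= 0 || decay_rate > 1) {
    stop("`decay_rate` must lie in (0, 1]", call. = FALSE)
  }
  n_arms <- check_count(n_arms, "n_arms", min = 2L)
  n_trials <- check_count(n_trials, "n_trials")
  check_nonneg(innovation_sd, "innovation_sd")
  check_nonneg(reward_noise_sd, "reward_noise_sd")
  if (!is.null(initial_means) && length(initial_means) != n_arms) {
    stop("`initial_means` must have one entry per arm", call. = FALSE)
  }
  structure(
    list(
      decay_rate = decay_rate, decay_center = decay_center,
      innovation_sd = innovation_sd, reward_noise_sd = reward_noise_sd,
      n_arms = n_arms, n_trials = n_trials, initial_means = initial_means,
      integer_rewards = integer_rewards,
      min_best_arm_changes = as.integer(min_best_arm_changes),
      max_best_run = as.integer(max_best_run)
    ),
    class = "restless_config"
  )
}

#' Design of the Horizon task reward set
#'
#' Rounds cross horizon length (1 vs 6 free choices after 4 forced choices)
#' with the information condition (unequal \[1, 3\] vs equal \[2, 2\] forced
#' sampling). Within-round arm means are stable; every cell of the design
#' uses the same multiset of absolute mean differences, and the side of the
#' better arm and of the less-sampled arm are counterbalanced so that both
#' arms are equally rewarding on grand average.
#'
#' @param n_rounds Number of scored rounds; must be divisible by
#'   `4 * length(mean_differences)` so the design can be balanced.
#' @param mean_differences Absolute mean reward gaps used in every cell.
#' @param reward_noise_sd Standard deviation of the observation noise.
#' @param horizon_lengths Named vector of free-choice counts for the short and
#'   long horizon.
#' @param mean_center Midpoint of the two arm means (reward units).
#' @param integer_rewards Round and clip realized rewards (see
#'   [restless_config()]).
#' @return A list of class `horizon_design`.
#' @export
horizon_design <- function(n_rounds = 80L,
                           mean_differences = c(30, 20, 12, 8, 4),
                           reward_noise_sd = 4,
                           horizon_lengths = c(short = 1L, long = 6L),
                           mean_center = 50,
                           integer_rewards = TRUE) {
  n_rounds <- check_count(n_rounds, "n_rounds", min = 4L)
  if (length(mean_differences) == 0) {
    stop("`mean_differences` must be non-empty", call. = FALSE)
  }
  if (n_rounds %% (4L * length(mean_differences)) != 0L) {
    stop("`n_rounds` must divide evenly into 4 cells x gaps", call. = FALSE)
  }
  reps <- n_rounds / (4L * length(mean_differences))
  if (reps %% 2L != 0L) {
    stop("gap repetitions per cell must be even for side counterbalancing",
         call. = FALSE)
  }
  check_nonneg(reward_noise_sd, "reward_noise_sd")
  structure(
    list(
      n_rounds = n_rounds, mean_differences = as.numeric(mean_differences),
      reward_noise_sd = reward_noise_sd,
      horizon_lengths = horizon_lengths, mean_center = mean_center,
      integer_rewards = integer_rewards
    ),
    class = "horizon_design"
  )
}

#' Design of the drifting two-armed bandit reward set
#'
#' Thirty rounds of ten choices; within a round each arm's latent mean is
#' either stable or follows an unconstrained random walk (all four
#' combinations occur). Initial mean gaps are biased toward
#' `target_mean_diff`, and rounds are re-sampled until the within-round
#' average absolute gap does not exceed `max_mean_diff`.
#'
#' @param n_rounds Number of rounds.
#' @param trials_per_round Choices per round.
#' @param max_mean_diff Upper bound on the per-round average absolute latent
#'   mean difference between the two arms.
#' @param target_mean_diff Center of the distribution of initial mean gaps.
#' @param gap_sd Spread of the initial mean gap around `target_mean_diff`.
#' @param drift_sd Per-step standard deviation of a drifting arm's walk.
#' @param reward_noise_sd Observation noise standard deviation.
#' @param mean_center Center of the midpoint of the two initial means.
#' @param integer_rewards Round and clip realized rewards.
#' @return A list of class `twoarmed_design`.
#' @export
twoarmed_design <- function(n_rounds = 30L,
                            trials_per_round = 10L,
                            max_mean_diff = 15,
                            target_mean_diff = 8,
                            gap_sd = 4,
                            drift_sd = 2,
                            reward_noise_sd = 4,
                            mean_center = 50,
                            integer_rewards = TRUE) {
  n_rounds <- check_count(n_rounds, "n_rounds", min = 4L)
  trials_per_round <- check_count(trials_per_round, "trials_per_round", min = 2L)
  if (max_mean_diff < 0) stop("`max_mean_diff` must be >= 0", call. = FALSE)
  check_nonneg(drift_sd, "drift_sd")
  check_nonneg(reward_noise_sd, "reward_noise_sd")
  structure(
    list(
      n_rounds = n_rounds, trials_per_round = trials_per_round,
      max_mean_diff = max_mean_diff, target_mean_diff = target_mean_diff,
      gap_sd = gap_sd, drift_sd = drift_sd,
      reward_noise_sd = reward_noise_sd, mean_center = mean_center,
      integer_rewards = integer_rewards
    ),
    class = "twoarmed_design"
  )
}

new_reward_set <- function(task, rewards, rounds, config, seed) {
  structure(
    list(task = task, rewards = rewards, rounds = rounds,
         config = config, seed = as.integer(seed)),
    class = "reward_set"
  )
}

#' @export
print.reward_set <- function(x, ...) {
  cat(sprintf("<reward_set: %s task>\n", x$task))
  cat(sprintf("  rounds: %d, trials: %d, arms: %d (seed %d)\n",
              nrow(x$rounds), nrow(x$rewards) / length(unique(x$rewards$arm)),
              length(unique(x$rewards$arm)), x$seed))
  invisible(x)
}

realize_rewards <- function(means, noise_sd, integer_rewards) {
  r <- means + rnorm(length(means), 0, noise_sd)
  if (integer_rewards) r <- pmin(99, pmax(1, round(r)))
  r
}

#' Generate the restless-bandit reward set
#'
#' Samples the mean-reverting latent walks and realized rewards. Candidate
#' walks are re-sampled until the best arm changes identity at least
#' `min_best_arm_changes` times and no arm stays best longer than
#' `max_best_run` consecutive trials, so that exploration stays worthwhile
#' over the whole round.
#'
#' @param cfg A [restless_config()].
#' @param seed Integer seed; identical `(cfg, seed)` give identical sets.
#' @return A `reward_set` with one round of `cfg$n_trials` trials.
#' @export
generate_restless_rewardset <- function(cfg = restless_config(), seed = 1L) {
  stopifnot(inherits(cfg, "restless_config"))
  with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      mu0 <- cfg$initial_means %||% runif(cfg$n_arms, 30, 70)
      mu <- matrix(NA_real_, cfg$n_trials, cfg$n_arms)
      mu[1L, ] <- mu0
      if (cfg$n_trials > 1L) {
        for (t in 2:cfg$n_trials) {
          mu[t, ] <- cfg$decay_rate * mu[t - 1L, ] +
            (1 - cfg$decay_rate) * cfg$decay_center +
            rnorm(cfg$n_arms, 0, cfg$innovation_sd)
        }
      }
      best <- max.col(mu, ties.method = "first")
      changes <- sum(diff(best) != 0L)
      runs <- rle(best)$lengths
      relax <- cfg$innovation_sd == 0 || cfg$n_trials < 10L
      if (relax ||
          (changes >= cfg$min_best_arm_changes &&
           max(runs) <= cfg$max_best_run)) {
        rewards <- tibble::tibble(
          round = 1L,
          trial = rep(seq_len(cfg$n_trials), times = cfg$n_arms),
          arm = rep(seq_len(cfg$n_arms), each = cfg$n_trials),
          latent_mean = as.vector(mu)
        )
        rewards$reward <- realize_rewards(rewards$latent_mean,
                                          cfg$reward_noise_sd,
                                          cfg$integer_rewards)
        rounds <- tibble::tibble(round = 1L, n_trials = cfg$n_trials,
                                 condition = "restless")
        return(new_reward_set("restless", rewards, rounds, cfg, seed))
      }
    }
    stop("could not satisfy the best-arm turnover filter in 1000 attempts",
         call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the Horizon task reward set
#'
#' Builds the fully crossed horizon-by-information design with balanced gap
#' multisets and counterbalanced sides, then realizes noisy rewards for every
#' (round, trial, arm) cell. Forced-choice schedules (four per round) are part
#' of the round table.
#'
#' @param design A [horizon_design()].
#' @param seed Integer seed.
#' @return A `reward_set`; `$rounds` holds horizon, information condition,
#'   gap, better arm, less-sampled arm and the forced schedule `f1..f4`.
#' @export
generate_horizon_rewardset <- function(design = horizon_design(), seed = 1L) {
  stopifnot(inherits(design, "horizon_design"))
  with_seed(seed, {
    gaps <- design$mean_differences
    reps <- design$n_rounds / (4L * length(gaps))
    cells <- expand.grid(horizon = c("short", "long"),
                         info = c("equal", "unequal"),
                         stringsAsFactors = FALSE)
    rounds <- list()
    for (ci in seq_len(nrow(cells))) {
      for (g in gaps) {
        # counterbalance better side (and, for unequal info, the less-sampled
        # side) across the repetitions of each gap within a cell
        sides <- rep(c(1L, 2L), length.out = reps)
        less <- rep(c(1L, 2L, 2L, 1L), length.out = reps)
        for (k in seq_len(reps)) {
          rounds[[length(rounds) + 1L]] <- tibble::tibble(
            horizon = cells$horizon[ci], info = cells$info[ci],
            gap = g, better_arm = sides[k],
            less_sampled_arm = if (cells$info[ci] == "unequal") less[k] else NA_integer_
          )
        }
      }
    }
    rounds <- dplyr::bind_rows(rounds)
    rounds <- rounds[sample.int(nrow(rounds)), ]  # fixed permutation under seed
    rounds$round <- seq_len(nrow(rounds))
    rounds$n_free <- as.integer(design$horizon_lengths[rounds$horizon])
    rounds$n_trials <- 4L + rounds$n_free

    # forced schedules: permutation of [2,2] or three of the more-sampled arm
    sched <- t(vapply(seq_len(nrow(rounds)), function(i) {
      if (rounds$info[i] == "equal") {
        sample(c(1L, 1L, 2L, 2L))
      } else {
        more <- 3L - rounds$less_sampled_arm[i]
        sample(c(rep(more, 3L), rounds$less_sampled_arm[i]))
      }
    }, integer(4)))
    colnames(sched) <- paste0("f", 1:4)
    rounds <- dplyr::bind_cols(rounds, tibble::as_tibble(sched))

    max_trials <- max(rounds$n_trials)
    rewards <- tidyr::expand_grid(round = rounds$round, trial = seq_len(max_trials),
                                  arm = 1:2)
    rewards <- dplyr::inner_join(
      rewards,
      rounds[, c("round", "n_trials", "gap", "better_arm")],
      by = "round"
    )
    rewards <- rewards[rewards$trial <= rewards$n_trials, ]
    rewards$latent_mean <- design$mean_center +
      ifelse(rewards$arm == rewards$better_arm, rewards$gap / 2, -rewards$gap / 2)
    rewards$reward <- realize_rewards(rewards$latent_mean,
                                      design$reward_noise_sd,
                                      design$integer_rewards)
    rewards <- rewards[order(rewards$round, rewards$trial, rewards$arm),
                       c("round", "trial", "arm", "latent_mean", "reward")]
    rounds <- rounds[, c("round", "horizon", "info", "gap", "better_arm",
                         "less_sampled_arm", "n_free", "n_trials",
                         paste0("f", 1:4))]
    new_reward_set("horizon", tibble::as_tibble(rewards), rounds, design, seed)
  })
}

#' Generate the two-armed bandit reward set
#'
#' Allocates the four drift conditions (stable/stable, stable/drift,
#' drift/stable, drift/drift) across rounds as evenly as possible, samples
#' initial means biased toward the target gap, lets drifting arms follow a
#' random walk, and rejects any round whose average absolute latent gap
#' exceeds the design bound.
#'
#' @param design A [twoarmed_design()].
#' @param seed Integer seed.
#' @return A `reward_set`; `$rounds` records each round's drift condition.
#' @export
generate_twoarmed_rewardset <- function(design = twoarmed_design(), seed = 1L) {
  stopifnot(inherits(design, "twoarmed_design"))
  with_seed(seed, {
    conds <- c("stable/stable", "stable/drift", "drift/stable", "drift/drift")
    alloc <- rep(conds, length.out = design$n_rounds)
    alloc <- alloc[sample.int(length(alloc))]
    nt <- design$trials_per_round
    rounds <- tibble::tibble(
      round = seq_len(design$n_rounds), condition = alloc,
      drift1 = grepl("^drift", alloc), drift2 = grepl("drift$", alloc),
      n_trials = nt
    )
    reward_rows <- vector("list", design$n_rounds)
    for (i in seq_len(design$n_rounds)) {
      for (try in seq_len(200L)) {
        center <- rnorm(1, design$mean_center, 3)
        gap <- abs(rnorm(1, design$target_mean_diff, design$gap_sd))
        sign <- sample(c(-1, 1), 1)
        m0 <- center + sign * c(gap / 2, -gap / 2)
        mu <- matrix(rep(m0, each = nt), nt, 2)
        for (a in 1:2) {
          if (c(rounds$drift1[i], rounds$drift2[i])[a] && nt > 1L) {
            mu[, a] <- m0[a] + cumsum(c(0, rnorm(nt - 1L, 0, design$drift_sd)))
          }
        }
        if (mean(abs(mu[, 1] - mu[, 2])) <= design$max_mean_diff) break
        if (try == 200L) stop("could not satisfy the mean-gap bound",
                              call. = FALSE)
      }
      reward_rows[[i]] <- tibble::tibble(
        round = i, trial = rep(seq_len(nt), 2L), arm = rep(1:2, each = nt),
        latent_mean = as.vector(mu)
      )
    }
    rewards <- dplyr::bind_rows(reward_rows)
    rewards$reward <- realize_rewards(rewards$latent_mean,
                                      design$reward_noise_sd,
                                      design$integer_rewards)
    rewards <- rewards[order(rewards$round, rewards$trial, rewards$arm), ]
    new_reward_set("twoarmed", tibble::as_tibble(rewards), rounds, design, seed)
  })
}

#' Write / read a reward set as CSV
#'
#' The flat file joins per-trial rewards with the round-level condition
#' columns; one header row, UTF-8, "." decimal.
#'
#' @param rs A `reward_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reward_set <- function(rs, path) {
  stopifnot(inherits(rs, "reward_set"))
  flat <- dplyr::left_join(rs$rewards, rs$rounds, by = "round")
  flat <- dplyr::mutate(flat, task = rs$task, .before = 1L)
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
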