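# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the default test run stays fast.

tiny_horizon <- function(seed = 3, noise = 4) {
  generate_horizon_rewardset(
    horizon_design(n_rounds = 16L, mean_differences = c(30, 4),
                   reward_noise_sd = noise),
    seed = seed
  )
}

tiny_twoarmed <- function(seed = 3, n_rounds = 8L) {
  generate_twoarmed_rewardset(twoarmed_design(n_rounds = n_rounds), seed = seed)
}

tiny_restless <- function(seed = 3, n_trials = 60L) {
  generate_restless_rewardset(restless_config(n_trials = n_trials), seed = seed)
}

# A hand-assembled single-round Horizon reward set with fully controlled
# rewards; `rewards` is a (trial x arm) matrix, forced schedule f.
manual_horizon_set <- function(rewards, forced, latent = NULL,
                               horizon = "long", info = "unequal") {
  nt <- nrow(rewards)
  if (is.null(latent)) latent <- rewards
  rounds <- tibble::tibble(
    round = 1L, horizon = horizon, info = info,
    gap = abs(mean(latent[, 1]) - mean(latent[, 2])),
    better_arm = which.max(colMeans(latent)),
    less_sampled_arm = {
      cnt <- tabulate(forced, nbins = 2L)
      if (cnt[1] == cnt[2]) NA_integer_ else which.min(cnt)
    },
    n_free = nt - 4L, n_trials = nt,
    f1 = forced[1], f2 = forced[2], f3 = forced[3], f4 = forced[4]
  )
  rw <- tibble::tibble(
    round = 1L,
    trial = rep(seq_len(nt), 2L),
    arm = rep(1:2, each = nt),
    latent_mean = c(latent[, 1], latent[, 2]),
    reward = c(rewards[, 1], rewards[, 2])
  )
  banditmetrics:::new_reward_set("horizon", rw, rounds,
                                 list(manual = TRUE), 0L)
}

# Build a session tibble directly from vectors (for hand oracles).
manual_session <- function(task, round, trial, choice, reward,
                           forced = 0L, condition = "manual",
                           subject = 1L, session = 1L) {
  tibble::tibble(
    subject = subject, session = session, task = task,
    round = round, trial = trial,
    condition = rep_len(condition, length(trial)),
    forced = rep_len(forced, length(trial)),
    choice = choice, reward = reward
  )
}
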