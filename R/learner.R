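#' Fixed generative parameters of the Kalman-filter learner
#'
#' These quantities are set to the values of the reward-generating process
#' and are never fitted: the innovation variance and observation-noise
#' variance of the Kalman filter, the decay rate and decay center of the
#' diffusion step, and the prior mean/variance over arm values.
#'
#' @param innov_var Innovation variance \eqn{\sigma_{innov}^2} (reward units
#'   squared) added to every arm's posterior variance each trial.
#' @param noise_var Observation noise variance \eqn{\sigma_{noise}^2}.
#' @param decay_rate Decay rate \eqn{\lambda} of the diffusion step.
#' @param decay_center Decay center toward which posterior means are pulled.
#' @param prior_mean Prior mean over arm values at the start of a round.
#' @param prior_var Prior variance over arm values at the start of a round.
#' @param apply_diffusion_to_means If `TRUE` (restless bandit only), posterior
#'   means decay toward `decay_center` between trials.
#' @return A list of class `learner_config`.
#' @export
learner_config <- function(innov_var, noise_var, decay_rate = 1,
                           decay_center = 50, prior_mean = 50, prior_var,
                           apply_diffusion_to_means = FALSE) {
  check_nonneg(innov_var, "innov_var")
  check_nonneg(noise_var, "noise_var")
  check_nonneg(prior_var, "prior_var")
  if (decay_rate <= 0 || decay_rate > 1) {
    stop("`decay_rate` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(innov_var = innov_var, noise_var = noise_var,
         decay_rate = decay_rate, decay_center = decay_center,
         prior_mean = prior_mean, prior_var = prior_var,
         apply_diffusion_to_means = isTRUE(apply_diffusion_to_means)),
    class = "learner_config"
  )
}

#' Default learner configuration per task
#'
#' Restless bandit: the generating walk's innovation variance (7.84), reward
#' noise variance (16), decay rate .9836 and center 50; the prior variance is
#' the stationary variance of the walk, `innov_var / (1 - lambda^2)`.
#' Two-armed bandit: innovation variance equal to the per-step drift variance,
#' no diffusion of the means, and a prior variance equal to the drift
#' variance accumulated over one round. The Horizon task learns by plain
#' averaging and takes no Kalman configuration.
#'
#' @param task `"restless"` or `"twoarmed"`.
#' @param drift_sd Two-armed per-step drift sd (used for both variances).
#' @param trials_per_round Two-armed round length (scales the prior variance).
#' @return A `learner_config`.
#' @export
default_learner_config <- function(task, drift_sd = 2, trials_per_round = 10L) {
  task <- check_task(task)
  switch(task,
    restless = learner_config(
      innov_var = 2.8^2, noise_var = 16, decay_rate = 0.9836,
      decay_center = 50, prior_mean = 50,
      prior_var = 2.8^2 / (1 - 0.9836^2),
      apply_diffusion_to_means = TRUE
    ),
    twoarmed = learner_config(
      innov_var = drift_sd^2, noise_var = 16, decay_rate = 1,
      decay_center = 50, prior_mean = 50,
      prior_var = drift_sd^2 * trials_per_round,
      apply_diffusion_to_means = FALSE
    ),
    stop("the horizon task does not use a Kalman learner", call. = FALSE)
  )
}

#' Initialize Kalman beliefs over arms
#'
#' @param n_arms Number of arms.
#' @param cfg A [learner_config()] supplying the prior mean and variance.
#' @return A list of class `kalman_belief` with numeric vectors `mean` and
#'   `var`, one entry per arm.
#' @export
kalman_belief <- function(n_arms, cfg) {
  n_arms <- check_count(n_arms, "n_arms", min = 2L)
  structure(
    list(mean = rep(cfg$prior_mean, n_arms), var = rep(cfg$prior_var, n_arms)),
    class = "kalman_belief"
  )
}

#' Kalman-filter belief update after one observed reward
#'
#' The chosen arm's gain is
#' \eqn{K = (V + \sigma_{innov}^2) / (V + \sigma_{innov}^2 + \sigma_{noise}^2)};
#' its mean moves toward the reward by fraction K and its variance becomes
#' \eqn{(1 - K)(V + \sigma_{innov}^2)}. Unchosen arms keep their mean and
#' gain \eqn{\sigma_{innov}^2} of variance.
#'
#' @param belief A `kalman_belief`.
#' @param chosen_arm 1-based arm index.
#' @param reward Observed reward.
#' @param cfg A [learner_config()].
#' @return The updated `kalman_belief`.
#' @export
kalman_update <- function(belief, chosen_arm, reward, cfg) {
  stopifnot(inherits(belief, "kalman_belief"))
  n <- length(belief$mean)
  if (chosen_arm < 1L || chosen_arm > n) stop("invalid `chosen_arm`", call. = FALSE)
  if (any(belief$var < 0)) stop("belief variances must be >= 0", call. = FALSE)
  pred_var <- belief$var + cfg$innov_var
  k <- pred_var[chosen_arm] / (pred_var[chosen_arm] + cfg$noise_var)
  belief$mean[chosen_arm] <- belief$mean[chosen_arm] +
    k * (reward - belief$mean[chosen_arm])
  belief$var <- pred_var
  belief$var[chosen_arm] <- (1 - k) * pred_var[chosen_arm]
  belief
}

#' Diffusion step applied to posterior means between trials
#'
#' Restless bandit only: every arm's posterior mean decays toward the decay
#' center, `mean <- lambda * mean + (1 - lambda) * center`. Variances are not
#' touched here (the innovation-variance inflation lives in the Kalman
#' update).
#'
#' @inheritParams kalman_update
#' @return The updated `kalman_belief`.
#' @export
diffusion_prior_step <- function(belief, cfg) {
  stopifnot(inherits(belief, "kalman_belief"))
  if (!cfg$apply_diffusion_to_means) {
    stop("diffusion of the means is disabled for this task", call. = FALSE)
  }
  belief$mean <- cfg$decay_rate * belief$mean +
    (1 - cfg$decay_rate) * cfg$decay_center
  belief
}
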