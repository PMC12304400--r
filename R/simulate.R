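# Reshape a reward_set's long table into per-round [trial x arm] matrices for
# fast lookup during simulation and likelihood evaluation.
reward_matrices <- function(rs) {
  split_rewards <- split(rs$rewards, rs$rewards$round)
  lapply(split_rewards, function(d) {
    n_arms <- max(d$arm)
    m <- matrix(NA_real_, max(d$trial), n_arms)
    m[cbind(d$trial, d$arm)] <- d$reward
    m
  })
}

latent_matrices <- function(rs) {
  split_rewards <- split(rs$rewards, rs$rewards$round)
  lapply(split_rewards, function(d) {
    m <- matrix(NA_real_, max(d$trial), max(d$arm))
    m[cbind(d$trial, d$arm)] <- d$latent_mean
    m
  })
}

session_tibble <- function(subject, session, task, rows) {
  tibble::tibble(
    subject = subject, session = session, task = task,
    round = rows$round, trial = rows$trial, condition = rows$condition,
    forced = rows$forced, choice = rows$choice, reward = rows$reward
  )
}

#' Simulate one subject-session on a fixed reward set
#'
#' Runs the task's generative agent trial by trial: beliefs are updated by
#' the task's learning rule (Kalman filter with diffusion for the restless
#' bandit, Kalman filter for the two-armed bandit, plain averaging for the
#' Horizon task) and choices are sampled from the model's probabilities.
#' Horizon forced choices follow the reward set's forced schedule. Rewards
#' are read from the reward set, never re-sampled.
#'
#' For Horizon simulation the agent applies its long-horizon weights in long
#' rounds and its short-horizon weights in short rounds on every free choice,
#' with features recomputed from all observations so far. Improved-variant
#' parameter objects (long block only) apply the long block in both
#' conditions.
#'
#' @param rewardset A `reward_set`.
#' @param params A `restless_params`, `twoarmed_params` or `horizon_params`
#'   matching the reward set's task.
#' @param learner_cfg A [learner_config()]; defaults to
#'   [default_learner_config()] for the task (ignored for Horizon).
#' @param seed Integer seed for the choice sampling.
#' @param subject,session Identifiers stamped into the output.
#' @param n_trials Optional cap on the number of simulated restless trials
#'   (used by the optimality analyses).
#' @return A tibble with columns subject, session, task, round, trial,
#'   condition, forced, choice, reward.
#' @export
simulate_session <- function(rewardset, params, learner_cfg = NULL, seed = 1L,
                             subject = 1L, session = 1L, n_trials = NULL) {
  stopifnot(inherits(rewardset, "reward_set"))
  task <- rewardset$task
  ok <- switch(task,
    restless = inherits(params, "restless_params"),
    twoarmed = inherits(params, "twoarmed_params"),
    horizon = inherits(params, "horizon_params")
  )
  if (!ok) stop("`params` do not match the reward set's task", call. = FALSE)
  if (is.null(learner_cfg) && task != "horizon") {
    learner_cfg <- default_learner_config(task)
  }
  with_seed(seed, {
    switch(task,
      restless = simulate_restless(rewardset, params, learner_cfg,
                                   subject, session, n_trials),
      twoarmed = simulate_twoarmed(rewardset, params, learner_cfg,
                                   subject, session),
      horizon = simulate_horizon(rewardset, params, subject, session)
    )
  })
}

simulate_restless <- function(rs, params, cfg, subject, session, n_trials) {
  rm_ <- reward_matrices(rs)[[1]]
  nt <- if (is.null(n_trials)) nrow(rm_) else min(n_trials, nrow(rm_))
  n_arms <- ncol(rm_)
  belief <- kalman_belief(n_arms, cfg)
  choice <- integer(nt); reward <- numeric(nt)
  for (t in seq_len(nt)) {
    p <- ucb_choice_probs(belief, params, cfg)
    choice[t] <- sample.int(n_arms, 1L, prob = p)
    reward[t] <- rm_[t, choice[t]]
    belief <- kalman_update(belief, choice[t], reward[t], cfg)
    belief <- diffusion_prior_step(belief, cfg)
  }
  session_tibble(subject, session, "restless",
                 list(round = rep(1L, nt), trial = seq_len(nt),
                      condition = rep("restless", nt),
                      forced = rep(0L, nt), choice = choice, reward = reward))
}

simulate_twoarmed <- function(rs, params, cfg, subject, session) {
  rms <- reward_matrices(rs)
  variant <- params$variant
  weights <- c(value_diff = params$value_guided, directed = params$directed)
  if (variant == "original") weights <- c(weights, random = params$random)
  out <- vector("list", nrow(rs$rounds))
  for (i in seq_len(nrow(rs$rounds))) {
    rm_ <- rms[[i]]
    nt <- nrow(rm_)
    belief <- kalman_belief(2L, cfg)
    choice <- integer(nt); reward <- numeric(nt)
    for (t in seq_len(nt)) {
      x <- twoarmed_predictors(belief, variant)
      p1 <- logistic_choice_prob(x, params$side_bias, weights)
      choice[t] <- if (runif(1) < p1) 1L else 2L
      reward[t] <- rm_[t, choice[t]]
      belief <- kalman_update(belief, choice[t], reward[t], cfg)
    }
    out[[i]] <- list(round = rep(rs$rounds$round[i], nt), trial = seq_len(nt),
                     condition = rep(rs$rounds$condition[i], nt),
                     forced = rep(0L, nt), choice = choice, reward = reward)
  }
  rows <- lapply(c("round", "trial", "condition", "forced", "choice", "reward"),
                 function(f) unlist(lapply(out, `[[`, f)))
  names(rows) <- c("round", "trial", "condition", "forced", "choice", "reward")
  session_tibble(subject, session, "twoarmed", rows)
}

horizon_block <- function(params, horizon) {
  if (params$variant == "improved" || horizon == "long") params$long
  else params$short
}

simulate_horizon <- function(rs, params, subject, session) {
  rms <- reward_matrices(rs)
  out <- vector("list", nrow(rs$rounds))
  for (i in seq_len(nrow(rs$rounds))) {
    rd <- rs$rounds[i, ]
    rm_ <- rms[[as.character(rd$round)]] %||% rms[[i]]
    nt <- rd$n_trials
    forced_arms <- as.integer(rd[paste0("f", 1:4)])
    choice <- integer(nt); reward <- numeric(nt)
    choice[1:4] <- forced_arms
    reward[1:4] <- rm_[cbind(1:4, forced_arms)]
    # running sums/counts generalize the forced-trial averaging to later
    # free choices of a long round
    sums <- vapply(1:2, function(a) sum(reward[1:4][forced_arms == a]), numeric(1))
    counts <- tabulate(forced_arms, nbins = 2L)
    blk <- horizon_block(params, rd$horizon)
    w <- c(value_diff = unname(blk["value_guided"]),
           info_diff = unname(blk["directed"]))
    for (t in (4L + seq_len(rd$n_free))) {
      x <- c(value_diff = sums[1] / counts[1] - sums[2] / counts[2],
             info_diff = (counts[1] - counts[2]) / 4)
      p1 <- logistic_choice_prob(x, unname(blk["side_bias"]), w)
      choice[t] <- if (runif(1) < p1) 1L else 2L
      reward[t] <- rm_[t, choice[t]]
      sums[choice[t]] <- sums[choice[t]] + reward[t]
      counts[choice[t]] <- counts[choice[t]] + 1L
    }
    cond <- paste(rd$horizon, rd$info, sep = "/")
    out[[i]] <- list(round = rep(rd$round, nt), trial = seq_len(nt),
                     condition = rep(cond, nt),
                     forced = c(rep(1L, 4L), rep(0L, rd$n_free)),
                     choice = choice, reward = reward)
  }
  rows <- lapply(c("round", "trial", "condition", "forced", "choice", "reward"),
                 function(f) unlist(lapply(out, `[[`, f)))
  names(rows) <- c("round", "trial", "condition", "forced", "choice", "reward")
  session_tibble(subject, session, "horizon", rows)
}

#' Default group-level parameter scales of the synthetic cohort
#'
#' Group means sit at the scale of the improved-variant group effects
#' (two-armed and restless) with between-subject standard deviations at half
#' the mean's magnitude (floored at 0.05 to keep every parameter
#' identifiable); loadings on the two latent exploration factors follow the
#' standardized task loadings of the measurement models. The Horizon value
#' weight is expressed per point of value difference and calibrated so that
#' first free choices are stochastic but above chance.
#'
#' @return Tibble with columns task, parameter, mean, sd, factor, loading.
#' @export
default_parameter_scales <- function() {
  tibble::tribble(
    ~task, ~parameter, ~mean, ~sd, ~factor, ~loading,
    "horizon", "side_bias", 0, 0.3, NA_character_, 0,
    "horizon", "value_guided", 0.15, 0.075, "value", 0.597,
    "horizon", "directed", 0.32, 0.16, "directed", 0.137,
    "twoarmed", "side_bias", 0, 0.3, NA_character_, 0,
    "twoarmed", "value_guided", 0.13, 0.065, "value", 0.535,
    "twoarmed", "directed", 0.15, 0.075, "directed", 0.444,
    "restless", "value_guided", 0.15, 0.075, "value", 0.696,
    "restless", "directed", -0.41, 0.205, "directed", 0.891
  )
}

#' Specification of a synthetic two-session cohort
#'
#' Subject-level true parameters are generated from a two-factor latent
#' structure (value-guided and directed exploration) with configurable factor
#' correlation; session-specific true parameters correlate `rho` across
#' sessions. Each session's choices are simulated on a session-specific
#' reward set shared by all subjects.
#'
#' @param n_subjects Number of subjects.
#' @param rho Cross-session correlation of true parameters, in \[-1, 1\].
#' @param factor_cor Correlation between the two latent exploration factors.
#' @param scales Parameter-scale table as in [default_parameter_scales()].
#' @param tasks Subset of tasks to simulate.
#' @param n_sessions Number of sessions (2 for test-retest designs).
#' @param seed Integer master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 175L, rho = 0.7, factor_cor = 0.64,
                        scales = default_parameter_scales(),
                        tasks = TASKS, n_sessions = 2L, seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (abs(factor_cor) >= 1) stop("`factor_cor` must lie in (-1, 1)", call. = FALSE)
  if (any(abs(scales$loading) > 1)) {
    stop("loadings must lie in [-1, 1] (implied covariance must be PSD)",
         call. = FALSE)
  }
  tasks <- vapply(tasks, check_task, character(1))
  structure(
    list(n_subjects = n_subjects, rho = rho, factor_cor = factor_cor,
         scales = scales[scales$task %in% tasks, ],
         tasks = unname(tasks), n_sessions = check_count(n_sessions, "n_sessions"),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Draw the latent factor scores and true per-session parameters of a cohort
# without simulating any choices (the expensive part); the full generator
# builds on this.
cohort_truth <- function(spec) {
  sc <- spec$scales
  n <- spec$n_subjects
  with_seed(derive_seed(spec$seed, "cohort-truth"), {
    rot <- chol(matrix(c(1, spec$factor_cor, spec$factor_cor, 1), 2L))
    draw_factors <- function() {
      f <- matrix(rnorm(n * 2L), n, 2L) %*% rot
      colnames(f) <- c("value", "directed")
      f
    }
    # stable (cross-session) components: correlated factors plus one unique
    # component per parameter
    fac <- draw_factors()
    u_core <- matrix(rnorm(n * nrow(sc)), n, nrow(sc))
    truth <- list()
    for (s in seq_len(spec$n_sessions)) {
      # the session-level factor mixes the stable factor with session-specific
      # factor noise (same correlation structure), so that session-level
      # loadings equal the configured loadings while every score — factor and
      # uniqueness alike — correlates rho across sessions
      fac_s <- sqrt(spec$rho) * fac + sqrt(1 - spec$rho) * draw_factors()
      e <- matrix(rnorm(n * nrow(sc)), n, nrow(sc))
      u_s <- sqrt(spec$rho) * u_core + sqrt(1 - spec$rho) * e
      zs <- sapply(seq_len(nrow(sc)), function(p) {
        lam <- sc$loading[p]
        f <- if (is.na(sc$factor[p]) || lam == 0) 0 else lam * fac_s[, sc$factor[p]]
        f + sqrt(1 - lam^2) * u_s[, p]
      })
      th <- sweep(sweep(zs, 2L, sc$sd, `*`), 2L, sc$mean, `+`)
      is_tau <- sc$task == "restless" & sc$parameter == "value_guided"
      th[, is_tau] <- pmax(th[, is_tau], 0.01)
      truth[[s]] <- tibble::tibble(
        subject = rep(seq_len(n), times = nrow(sc)),
        session = s,
        task = rep(sc$task, each = n),
        parameter = rep(sc$parameter, each = n),
        value = as.vector(th)
      )
    }
    list(truth = dplyr::bind_rows(truth),
         factors = fac)
  })
}

# Assemble task-specific parameter objects from a named value vector.
params_from_values <- function(task, values) {
  switch(task,
    restless = restless_params(values[["value_guided"]], values[["directed"]]),
    twoarmed = twoarmed_params(values[["side_bias"]], values[["value_guided"]],
                               values[["directed"]], variant = "improved"),
    horizon = {
      long <- c(side_bias = values[["side_bias"]],
                value_guided = values[["value_guided"]],
                directed = values[["directed"]])
      # short-horizon behavior: same value sensitivity scaled down, directed
      # weight lowered by the long-minus-short group difference (0.81 on the
      # +/-0.5 information scale)
      short <- long
      short["value_guided"] <- 0.8 * long["value_guided"]
      short["directed"] <- long["directed"] - 0.81
      horizon_params(long = long, short = short, variant = "original")
    }
  )
}

#' Generate a synthetic two-session cohort
#'
#' True subject parameters follow
#' `theta = mean + sd * (sqrt(rho) * core + sqrt(1 - rho) * session_noise)`
#' where `core = loading * factor + sqrt(1 - loading^2) * unique` with the
#' two factors drawn with correlation `factor_cor`. The restless
#' value-guided weight (an inverse temperature) is floored at 0.01. All
#' sessions are simulated with [simulate_session()] on session-specific
#' reward sets shared across subjects; ground-truth parameters and factor
#' scores are retained for recovery and reliability scoring.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort_data` with elements `spec`, `factors`
#'   (true factor scores), `truth` (long tibble of true parameters per
#'   subject/session/task), `sessions` (all simulated trials), and
#'   `reward_sets` (per session, per task).
#' @export
generate_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  tf <- cohort_truth(spec)
  truth <- tf$truth
  fac <- tf$factors

  reward_sets <- lapply(seq_len(spec$n_sessions), function(s) {
    out <- list()
    if ("restless" %in% spec$tasks) {
      out$restless <- generate_restless_rewardset(
        restless_config(), seed = derive_seed(spec$seed, "rs-restless", s))
    }
    if ("horizon" %in% spec$tasks) {
      out$horizon <- generate_horizon_rewardset(
        horizon_design(), seed = derive_seed(spec$seed, "rs-horizon", s))
    }
    if ("twoarmed" %in% spec$tasks) {
      out$twoarmed <- generate_twoarmed_rewardset(
        twoarmed_design(), seed = derive_seed(spec$seed, "rs-twoarmed", s))
    }
    out
  })
  names(reward_sets) <- paste0("session", seq_len(spec$n_sessions))

  sessions <- vector("list", n * spec$n_sessions * length(spec$tasks))
  k <- 0L
  for (s in seq_len(spec$n_sessions)) {
    for (task in spec$tasks) {
      tt <- truth[truth$session == s & truth$task == task, ]
      wide <- split(setNames(tt$value, tt$parameter), tt$subject)
      for (i in seq_len(n)) {
        k <- k + 1L
        sessions[[k]] <- simulate_session(
          reward_sets[[s]][[task]],
          params_from_values(task, wide[[as.character(i)]]),
          seed = derive_seed(spec$seed, "sim", s, task, i),
          subject = i, session = s
        )
      }
    }
  }
  structure(
    list(spec = spec,
         factors = tibble::tibble(subject = seq_len(n),
                                  value = fac[, "value"],
                                  directed = fac[, "directed"]),
         truth = truth,
         sessions = dplyr::bind_rows(sessions),
         reward_sets = reward_sets),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data: %d subjects x %d sessions, tasks: %s>\n",
              x$spec$n_subjects, x$spec$n_sessions,
              paste(x$spec$tasks, collapse = ", ")))
  invisible(x)
}
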