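test_that("all-zero parameters give exactly n log 2 on two-armed data", {
  ta <- tiny_twoarmed()
  ses <- simulate_session(ta, twoarmed_params(0, 0.1, 0.1, variant = "improved"),
                          seed = 2)
  n <- nrow(ses)
  p0 <- twoarmed_params(0, 0, 0, variant = "improved")
  expect_equal(negative_log_likelihood(ses, p0), n * log(2), tolerance = 1e-12)
  p0o <- twoarmed_params(0, 0, 0, random = 0, variant = "original")
  expect_equal(negative_log_likelihood(ses, p0o), n * log(2), tolerance = 1e-12)
})

test_that("two-armed likelihood matches an independent spreadsheet-style oracle", {
  # hand-built 6-trial record; the oracle below re-derives the belief
  # trajectory and choice probabilities step by step with scalar arithmetic
  ses <- manual_session("twoarmed",
                        round = rep(1L, 6), trial = 1:6,
                        choice = c(1L, 2L, 1L, 1L, 2L, 1L),
                        reward = c(62, 41, 58, 49, 55, 60))
  cfg <- default_learner_config("twoarmed")
  b0 <- 0.2; wv <- 0.12; wd <- 0.3; wr <- 0.25

  oracle <- local({
    m <- c(50, 50); v <- c(40, 40)
    ll <- 0
    for (t in 1:6) {
      x_val <- m[1] - m[2]
      x_dir <- sqrt(v[1]) - sqrt(v[2])
      x_ran <- x_val / sqrt(v[1] + v[2])
      eta <- b0 + wv * x_val + wd * x_dir + wr * x_ran
      p1 <- 1 / (1 + exp(-eta))
      ch <- ses$choice[t]
      ll <- ll + log(if (ch == 1) p1 else 1 - p1)
      # Kalman update, written out
      pv <- v + 4                      # both arms gain the innovation variance
      k <- pv[ch] / (pv[ch] + 16)
      m[ch] <- m[ch] + k * (ses$reward[t] - m[ch])
      v <- pv
      v[ch] <- (1 - k) * pv[ch]
    }
    -ll
  })
  p <- twoarmed_params(b0, wv, wd, random = wr, variant = "original")
  expect_equal(negative_log_likelihood(ses, p, cfg), oracle, tolerance = 1e-9)
})

test_that("the generating parameters beat a 5-sd perturbation on restless data", {
  rs <- generate_restless_rewardset(seed = 6)
  truth <- restless_params(0.15, -0.41)
  ses <- simulate_session(rs, truth, seed = 3)
  nll_true <- negative_log_likelihood(ses, truth)
  pert <- restless_params(0.15 + 5 * 0.075, -0.41 + 5 * 0.205)
  expect_lt(nll_true, negative_log_likelihood(ses, pert))
})

test_that("logistic MLE agrees with the IRLS (glm) oracle to 1e-6", {
  ta <- tiny_twoarmed(n_rounds = 30L)
  ses <- simulate_session(ta, twoarmed_params(0.2, 0.15, 0.2,
                                              variant = "improved"), seed = 4)
  fit <- fit_mle(ses, variant = "improved", n_starts = 5, seed = 1)
  d <- banditmetrics:::twoarmed_design_matrix(
    ses, default_learner_config("twoarmed"), "improved")
  gfit <- glm(d$y ~ d$X, family = binomial())
  expect_equal(unname(fit$estimates),
               unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$log_lik, as.numeric(logLik(gfit)), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 300L)
})

test_that("null data recover null weights within the Wald interval", {
  ta <- generate_twoarmed_rewardset(seed = 8)
  ses <- simulate_session(ta, twoarmed_params(0, 0, 0, variant = "improved"),
                          seed = 12)
  fit <- fit_mle(ses, variant = "improved", seed = 1)
  for (p in names(fit$estimates)) {
    ci <- fit$estimates[p] + c(-1.96, 1.96) * fit$se[p]
    expect_true(ci[1] <= 0 && 0 <= ci[2])
  }
})

test_that("the larger nested variant never fits worse", {
  ta <- tiny_twoarmed(n_rounds = 30L)
  ses <- simulate_session(ta, twoarmed_params(0, 0.13, 0.15,
                                              variant = "improved"), seed = 6)
  imp <- fit_mle(ses, variant = "improved", seed = 1)
  orig <- fit_mle(ses, variant = "original", seed = 1)
  expect_gte(orig$log_lik, imp$log_lik - 1e-6)

  hz <- tiny_horizon()
  ph <- horizon_params(long = c(side_bias = 0, value_guided = 0.15,
                                directed = 0.3),
                       short = c(side_bias = 0, value_guided = 0.1,
                                 directed = -0.4),
                       variant = "original")
  sh <- simulate_session(hz, ph, seed = 6)
  fo <- fit_mle(sh, variant = "original", seed = 1)
  fi <- fit_mle(sh, variant = "improved", seed = 1)
  # the improved variant's likelihood is a component of the original's
  expect_gte(fo$log_lik, fi$log_lik - 1e-6)
  expect_lt(fi$n_obs, fo$n_obs)
})

test_that("horizon improved variant uses exactly the long-horizon first free choices", {
  hz <- tiny_horizon()
  ph <- horizon_params(long = c(side_bias = 0, value_guided = 0.15,
                                directed = 0.3),
                       variant = "improved")
  sh <- simulate_session(hz, ph, seed = 2)
  d <- banditmetrics:::horizon_design_matrix(sh, "long")
  n_long <- sum(hz$rounds$horizon == "long")
  expect_equal(d$n_obs, n_long)
  fit <- fit_mle(sh, variant = "improved", seed = 1)
  expect_equal(fit$n_obs, n_long)
})

test_that("fitting is deterministic given data and seed", {
  ta <- tiny_twoarmed()
  ses <- simulate_session(ta, twoarmed_params(0, 0.1, 0.1,
                                              variant = "improved"), seed = 3)
  expect_identical(fit_mle(ses, seed = 42), fit_mle(ses, seed = 42))
})

test_that("degenerate zero-probability choices are signaled, not clipped", {
  ses <- manual_session("twoarmed", round = rep(1L, 2), trial = 1:2,
                        choice = c(1L, 2L), reward = c(60, 40))
  # enormous side bias makes the second choice (arm 2) impossible
  p <- twoarmed_params(3000, 0, 0, variant = "improved")
  expect_error(negative_log_likelihood(ses, p), "probability zero")
})

test_that("hierarchical fit shrinks extreme subjects toward the group", {
  ta <- generate_twoarmed_rewardset(seed = 5)
  set.seed(99)
  truths <- rnorm(12, 0.15, 0.04)
  sims <- lapply(seq_along(truths), function(i) {
    simulate_session(ta, twoarmed_params(0, truths[i], 0.1,
                                         variant = "improved"),
                     seed = 400 + i, subject = i)
  })
  h <- fit_hierarchical(dplyr::bind_rows(sims), variant = "improved",
                        iterations = 8, seed = 2)
  value_mle <- h$mle$estimate[h$mle$parameter == "value_guided"]
  value_map <- h$subjects$estimate[h$subjects$parameter == "value_guided"]
  mu <- h$group$mean[h$group$parameter == "value_guided"]
  # pooling property: shrunken estimates vary less than the raw MLEs
  expect_lte(var(value_map), var(value_mle))
  # the most extreme MLE moves strictly toward the group mean
  ext <- which.max(abs(value_mle - mu))
  expect_lt(abs(value_map[ext] - mu), abs(value_mle[ext] - mu))
  expect_true(value_map[ext] > min(value_mle[ext], mu) - 1e-9 &&
                value_map[ext] < max(value_mle[ext], mu) + 1e-9)
  # intervals contain the point estimate
  expect_true(all(h$group$lower <= h$group$mean & h$group$mean <= h$group$upper))
})

test_that("group-level intervals cover the true mean in most replications", {
  rs <- generate_restless_rewardset(seed = 5)
  true_mu <- c(0.3, 0)
  reps <- 20L
  covered <- 0
  for (r in seq_len(reps)) {
    gp <- with_seed <- NULL
    set.seed(5000 + r)
    vg <- pmax(rnorm(12, true_mu[1], 0.1), 0.01)
    dr <- rnorm(12, true_mu[2], 0.3)
    sims <- lapply(1:12, function(i) {
      simulate_session(rs, restless_params(vg[i], dr[i]),
                       seed = r * 1000 + i, subject = i)
    })
    h <- fit_hierarchical(dplyr::bind_rows(sims), iterations = 10, seed = r)
    g <- h$group
    covered <- covered +
      (g$lower[1] <= true_mu[1] && true_mu[1] <= g$upper[1]) / 2 +
      (g$lower[2] <= true_mu[2] && true_mu[2] <= g$upper[2]) / 2
  }
  expect_gte(covered / reps, 0.85)
})
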