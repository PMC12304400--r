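cfg_r <- default_learner_config("restless")

test_that("kalman update matches hand evaluation of the gain equations", {
  # V = 16, innov = 7.84, noise = 16, prior mean 50, reward 60:
  # K = 23.84 / 39.84, mean = 50 + 10 K, var = (1 - K) * 23.84
  cfg <- learner_config(innov_var = 7.84, noise_var = 16, prior_mean = 50,
                        prior_var = 16)
  b <- kalman_belief(2L, cfg)
  b2 <- kalman_update(b, 1L, 60, cfg)
  k <- 23.84 / 39.84
  expect_equal(b2$mean[1], 50 + k * 10, tolerance = 1e-12)
  expect_equal(b2$var[1], (1 - k) * 23.84, tolerance = 1e-12)
  expect_equal(b2$mean[1], 55.9839, tolerance = 1e-4)
  expect_equal(b2$var[1], 9.5743, tolerance = 1e-4)
  # unchosen arm: mean unchanged, variance inflated by exactly innov_var
  expect_equal(b2$mean[2], 50)
  expect_equal(b2$var[2], 16 + 7.84, tolerance = 1e-12)
})

test_that("noiseless observations set the gain to one", {
  cfg <- learner_config(innov_var = 4, noise_var = 0, prior_mean = 50,
                        prior_var = 10)
  b <- kalman_update(kalman_belief(3L, cfg), 2L, 72.5, cfg)
  expect_equal(b$mean[2], 72.5, tolerance = 1e-12)
  expect_equal(b$var[2], 0, tolerance = 1e-12)
})

test_that("posterior mean stays between prior mean and reward; variance shrinks without innovation", {
  cfg <- learner_config(innov_var = 0, noise_var = 9, prior_mean = 40,
                        prior_var = 25)
  b <- kalman_belief(2L, cfg)
  for (r in c(55, 20, 80, 41)) {
    b_new <- kalman_update(b, 1L, r, cfg)
    expect_true(b_new$mean[1] >= min(b$mean[1], r) &&
                  b_new$mean[1] <= max(b$mean[1], r))
    expect_lte(b_new$var[1], b$var[1])
    b <- b_new
  }
})

test_that("diffusion step decays means toward the center and errors when disabled", {
  b <- kalman_belief(4L, cfg_r)
  b$mean <- c(50, 70, 30, 50)
  b2 <- diffusion_prior_step(b, cfg_r)
  expect_equal(b2$mean[1], 50)                         # fixed point
  expect_equal(b2$mean[2], 69.672, tolerance = 1e-9)   # 0.9836*70 + 0.0164*50
  expect_equal(b2$var, b$var)                          # variances untouched
  # repeated application converges monotonically toward the center
  m <- 70
  for (i in 1:50) {
    b$mean <- rep(m, 4)
    m_new <- diffusion_prior_step(b, cfg_r)$mean[1]
    expect_lt(m_new, m)
    expect_gt(m_new, 50)
    m <- m_new
  }
  cfg_off <- default_learner_config("twoarmed")
  expect_error(diffusion_prior_step(kalman_belief(2L, cfg_off), cfg_off),
               "disabled")
})

test_that("horizon features average forced rewards and scale the info difference", {
  f <- horizon_features(c(1L, 2L, 2L, 2L), c(40, 50, 60, 70))
  expect_equal(f$means, c(40, 60))
  expect_equal(f$value_diff, -20)
  expect_equal(f$info_diff, -0.5)
  # equal information
  expect_equal(horizon_features(c(1L, 1L, 2L, 2L), c(1, 2, 3, 4))$info_diff, 0)
  # order invariance
  perm <- c(3L, 1L, 4L, 2L)
  f2 <- horizon_features(c(1L, 2L, 2L, 2L)[perm], c(40, 50, 60, 70)[perm])
  expect_equal(f2$value_diff, f$value_diff)
  expect_equal(f2$info_diff, f$info_diff)
  expect_error(horizon_features(c(1L, 1L, 1L, 1L), c(1, 2, 3, 4)), "at least once")
  expect_error(horizon_features(c(1L, 2L), c(1, 2)), "4 forced")
})

test_that("UCB softmax probabilities match direct evaluation and are shift invariant", {
  b <- kalman_belief(4L, cfg_r)
  p0 <- ucb_choice_probs(b, restless_params(0, 0), cfg_r)
  expect_equal(p0, rep(0.25, 4), tolerance = 1e-12)

  cfg2 <- learner_config(innov_var = 0, noise_var = 16, prior_mean = 0,
                         prior_var = 4)
  b2 <- kalman_belief(2L, cfg2)
  b2$mean <- c(60, 50)
  p <- ucb_choice_probs(b2, restless_params(0.15, 0), cfg2)
  expect_equal(p[1], 1 / (1 + exp(-1.5)), tolerance = 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  b3 <- b2; b3$mean <- b2$mean + 100
  expect_equal(ucb_choice_probs(b3, restless_params(0.15, 0), cfg2), p,
               tolerance = 1e-12)
})

test_that("two-armed predictors follow the belief arithmetic and are antisymmetric", {
  cfg <- learner_config(innov_var = 0, noise_var = 16, prior_mean = 50,
                        prior_var = 1)
  b <- kalman_belief(2L, cfg)
  expect_equal(unname(twoarmed_predictors(b, "original")), c(0, 0, 0))
  b$mean <- c(55, 45); b$var <- c(16, 25)
  x <- twoarmed_predictors(b, "original")
  expect_equal(unname(x["value_diff"]), 10)
  expect_equal(unname(x["directed"]), -1)
  expect_equal(unname(x["random"]), 10 / sqrt(41), tolerance = 1e-9)
  expect_equal(unname(x["random"]), 1.5617, tolerance = 1e-4)
  # swapping the arms negates every predictor
  b_sw <- b; b_sw$mean <- rev(b$mean); b_sw$var <- rev(b$var)
  expect_equal(unname(twoarmed_predictors(b_sw, "original")), unname(-x))
  # improved variant drops the random predictor
  expect_named(twoarmed_predictors(b, "improved"), c("value_diff", "directed"))
  # degenerate zero total uncertainty
  b0 <- b; b0$var <- c(0, 0)
  expect_error(twoarmed_predictors(b0, "original"), "undefined")
})

test_that("logistic choice rule matches direct evaluation and is symmetric", {
  expect_equal(logistic_choice_prob(c(value_diff = 0), 0, c(value_diff = 0)), 0.5)
  p <- logistic_choice_prob(c(value_diff = 8, directed = 0), 0,
                            c(value_diff = 0.1, directed = 3))
  expect_equal(p, 1 / (1 + exp(-0.8)), tolerance = 1e-9)
  expect_equal(p, 0.6900, tolerance = 1e-4)
  for (i in 1:5) {
    x <- c(value_diff = rnorm(1), directed = rnorm(1))
    w <- c(value_diff = rnorm(1), directed = rnorm(1))
    expect_equal(logistic_choice_prob(x, 0, w) + logistic_choice_prob(-x, 0, w),
                 1, tolerance = 1e-12)
  }
  expect_error(logistic_choice_prob(c(a = 1), 0, c(b = 1)), "match")
})

test_that("parameter objects validate their variants", {
  expect_error(twoarmed_params(0, 1, 1, random = 1, variant = "improved"),
               "no random")
  expect_error(twoarmed_params(0, 1, 1, variant = "original"), "requires")
  expect_error(horizon_params(long = c(side_bias = 0, value_guided = 1,
                                       directed = 0),
                              variant = "original"),
               "short")
  hp <- horizon_params(long = c(side_bias = 0, value_guided = 2, directed = 1),
                       short = c(side_bias = 0, value_guided = 1.5,
                                 directed = 0.2),
                       variant = "original")
  expect_equal(horizon_strategy_scores(hp),
               c(value_guided = 0.5, directed = 0.8))
})
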