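test_that("a zero-weight agent chooses uniformly and switches at chance", {
  rs <- generate_restless_rewardset(seed = 2)
  ses <- simulate_session(rs, restless_params(0, 0), seed = 5)
  freq <- table(factor(ses$choice, levels = 1:4)) / nrow(ses)
  # binomial tolerance around 1/4 at n = 200
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 200)))
  expect_equal(switch_probability(ses), 0.75, tolerance = 0.12)

  ta <- generate_twoarmed_rewardset(seed = 2)
  st <- simulate_session(ta, twoarmed_params(0, 0, 0, variant = "improved"),
                         seed = 5)
  # consecutive uniform coin flips switch with probability one half
  expect_equal(switch_probability(st), 0.5, tolerance = 0.1)
})

test_that("a near-deterministic value-guided agent exploits a wide stable gap", {
  # one stable round with a 30-point gap: after the first observation of each
  # arm, a huge value weight keeps choosing the better arm
  rw <- tibble::tibble(
    round = 1L, trial = rep(1:10, 2L), arm = rep(1:2, each = 10L),
    latent_mean = rep(c(65, 35), each = 10L),
    reward = rep(c(65, 35), each = 10L)
  )
  rounds <- tibble::tibble(round = 1L, condition = "stable/stable",
                           drift1 = FALSE, drift2 = FALSE, n_trials = 10L)
  rs <- banditmetrics:::new_reward_set("twoarmed", rw, rounds, list(), 0L)
  hits <- vapply(1:20, function(s) {
    ses <- simulate_session(rs, twoarmed_params(0, 50, 0, variant = "improved"),
                            seed = s)
    sum(ses$choice == 1L)
  }, numeric(1))
  expect_true(all(hits >= 9))
})

test_that("horizon simulation honors the forced schedule and free-choice counts", {
  hz <- tiny_horizon()
  ph <- horizon_params(long = c(side_bias = 0, value_guided = 0.15,
                                directed = 0.3),
                       short = c(side_bias = 0, value_guided = 0.12,
                                 directed = -0.5),
                       variant = "original")
  ses <- simulate_session(hz, ph, seed = 4)
  for (r in hz$rounds$round) {
    d <- ses[ses$round == r, ]
    rd <- hz$rounds[hz$rounds$round == r, ]
    expect_equal(d$choice[1:4], as.integer(rd[paste0("f", 1:4)]))
    expect_equal(d$forced, c(rep(1L, 4), rep(0L, rd$n_free)))
    # rewards equal the reward-set entry for the chosen arm
    rm_ <- matrix(hz$rewards$reward[hz$rewards$round == r], ncol = 2,
                  byrow = TRUE)  # long table is ordered trial-major, arm-minor
    expect_equal(d$reward, rm_[cbind(d$trial, d$choice)])
  }
})

test_that("session simulation is reproducible and params must match the task", {
  rs <- tiny_restless()
  expect_identical(simulate_session(rs, restless_params(0.2, -0.3), seed = 8),
                   simulate_session(rs, restless_params(0.2, -0.3), seed = 8))
  expect_error(simulate_session(rs, twoarmed_params(0, 1, 1,
                                                    variant = "improved")),
               "do not match")
})

test_that("cohort truth follows the latent factor algebra", {
  # implied correlation between two tasks' parameters is L_i * L_j (same
  # factor), checked at N = 5000 within Monte-Carlo tolerance
  sp <- cohort_spec(n_subjects = 5000, rho = 0.7, factor_cor = 0.64, seed = 21)
  tr <- banditmetrics:::cohort_truth(sp)$truth
  t1 <- tr[tr$session == 1, ]
  val <- function(task, par) t1$value[t1$task == task & t1$parameter == par]
  sc <- default_parameter_scales()
  L <- function(task, par) sc$loading[sc$task == task & sc$parameter == par]
  r_emp <- cor(val("horizon", "value_guided"), val("twoarmed", "value_guided"))
  expect_equal(r_emp, L("horizon", "value_guided") * L("twoarmed", "value_guided"),
               tolerance = 0.05)
  r_emp2 <- cor(val("twoarmed", "directed"), val("restless", "directed"))
  expect_equal(r_emp2, L("twoarmed", "directed") * L("restless", "directed"),
               tolerance = 0.05)
  # cross-factor pairs pick up the factor correlation
  r_emp3 <- cor(val("restless", "value_guided"), val("restless", "directed"))
  expect_equal(r_emp3,
               L("restless", "value_guided") * L("restless", "directed") * 0.64,
               tolerance = 0.05)
  # cross-session correlation of every parameter approaches rho
  t2 <- tr[tr$session == 2, ]
  for (task in unique(sc$task)) {
    r12 <- cor(val(task, "value_guided"),
               t2$value[t2$task == task & t2$parameter == "value_guided"])
    expect_equal(r12, 0.7, tolerance = 0.06)
  }
})

test_that("zero loadings make cross-task true parameters independent", {
  sc <- default_parameter_scales()
  sc$loading <- 0
  sp <- cohort_spec(n_subjects = 4000, rho = 0.7, scales = sc, seed = 3)
  tr <- banditmetrics:::cohort_truth(sp)$truth
  t1 <- tr[tr$session == 1, ]
  a <- t1$value[t1$task == "horizon" & t1$parameter == "value_guided"]
  b <- t1$value[t1$task == "restless" & t1$parameter == "value_guided"]
  expect_lt(abs(cor(a, b)), 0.05)
})

test_that("rho = 1 duplicates true parameters across sessions and the cohort is reproducible", {
  sp <- cohort_spec(n_subjects = 8, rho = 1, tasks = "twoarmed", seed = 17)
  co <- generate_synthetic_cohort(sp)
  t1 <- co$truth[co$truth$session == 1, ]
  t2 <- co$truth[co$truth$session == 2, ]
  expect_equal(t1$value, t2$value, tolerance = 1e-12)
  co2 <- generate_synthetic_cohort(sp)
  expect_identical(co$sessions, co2$sessions)
  expect_identical(co$truth, co2$truth)
})

test_that("replaying simulated choices yields a finite likelihood at the generating parameters", {
  ta <- tiny_twoarmed()
  p <- twoarmed_params(0.1, 0.13, 0.15, variant = "improved")
  ses <- simulate_session(ta, p, seed = 9)
  nll <- negative_log_likelihood(ses, p)
  expect_true(is.finite(nll))
  expect_gt(nll, 0)
})
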