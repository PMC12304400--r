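test_that("switch probability counts within-round free-choice pairs", {
  ses <- manual_session("twoarmed", round = rep(1L, 5), trial = 1:5,
                        choice = c(1L, 1L, 2L, 2L, 1L), reward = rep(50, 5))
  expect_equal(switch_probability(ses), 0.5)  # 2 switches over 4 pairs
  const <- manual_session("twoarmed", round = rep(1L, 4), trial = 1:4,
                          choice = rep(1L, 4), reward = rep(50, 4))
  expect_equal(switch_probability(const), 0)
  alt <- manual_session("twoarmed", round = rep(1L, 4), trial = 1:4,
                        choice = c(1L, 2L, 1L, 2L), reward = rep(50, 4))
  expect_equal(switch_probability(alt), 1)
  # pairs never span rounds: two one-choice rounds have no eligible pair
  none <- manual_session("horizon", round = c(1L, 2L), trial = c(1L, 1L),
                         choice = c(1L, 2L), reward = c(50, 50))
  expect_error(switch_probability(none), "no eligible")
})

test_that("a uniform agent on four arms switches about three quarters of the time", {
  rs <- generate_restless_rewardset(seed = 4)
  ses <- simulate_session(rs, restless_params(0, 0), seed = 6)
  expect_equal(switch_probability(ses), 0.75, tolerance = 0.1)
})

test_that("p(optimal) follows the latent-mean argmax with ties counted as optimal", {
  rw <- tibble::tibble(
    round = 1L, trial = rep(1:5, 2L), arm = rep(1:2, each = 5L),
    latent_mean = c(60, 60, 40, 55, 50, 40, 60, 60, 45, 50),
    reward = 0
  )
  rounds <- tibble::tibble(round = 1L, condition = "manual", n_trials = 5L)
  rs <- banditmetrics:::new_reward_set("twoarmed", rw, rounds, list(), 0L)
  # trial latent means: (60,40) (60,60) (40,60) (55,45) (50,50)
  ses <- manual_session("twoarmed", round = rep(1L, 5), trial = 1:5,
                        choice = c(1L, 2L, 1L, 1L, 2L), reward = rep(0, 5))
  # optimal: yes (60>40), yes (tie), no, yes, yes (tie) -> 4/5
  expect_equal(p_optimal(ses, rs), 0.8)
})

test_that("chance inclusion threshold matches a brute-force binomial CDF oracle", {
  expect_equal(chance_inclusion_threshold(1, 2), 1L)
  # independent oracle: exact CDF by summation of binomial pmf terms
  oracle <- function(n, p, perc) {
    pmf <- vapply(0:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
                  numeric(1))
    min(which(cumsum(pmf) >= perc)) - 1L
  }
  expect_equal(chance_inclusion_threshold(300, 2), oracle(300, 0.5, 0.95))
  expect_equal(chance_inclusion_threshold(200, 4), oracle(200, 0.25, 0.95))
  expect_equal(chance_inclusion_threshold(80, 2, 0.99), oracle(80, 0.5, 0.99))
  # monotone in the number of trials
  th <- vapply(c(10, 50, 100, 200, 400), chance_inclusion_threshold,
               integer(1), n_arms = 2)
  expect_true(all(diff(th) >= 0))
  expect_error(chance_inclusion_threshold(10, 2, 1.5), "percentile")
})

test_that("icc matches the two-way ANOVA oracle on random tables", {
  aov_oracle <- function(wide) {
    n <- nrow(wide); k <- ncol(wide)
    df <- data.frame(value = as.vector(wide),
                     subject = factor(rep(seq_len(n), k)),
                     session = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(value ~ subject + session, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    c(c1 = (msr - mse) / (msr + (k - 1) * mse),
      a1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
  }
  set.seed(42)
  for (rep_ in 1:20) {
    wide <- matrix(rnorm(20, mean = 10, sd = 3), 10, 2)
    est <- icc(wide)
    orc <- aov_oracle(wide)
    expect_equal(est$consistency, unname(orc["c1"]), tolerance = 1e-10)
    expect_equal(est$agreement, unname(orc["a1"]), tolerance = 1e-10)
  }
})

test_that("consistency is shift invariant, agreement is not", {
  set.seed(7)
  s1 <- rnorm(12, 50, 5)
  perfect <- icc(cbind(s1, s1))
  expect_equal(perfect$consistency, 1, tolerance = 1e-12)
  expect_equal(perfect$agreement, 1, tolerance = 1e-12)
  shifted <- icc(cbind(s1, s1 + 10))
  expect_equal(shifted$consistency, 1, tolerance = 1e-12)
  expect_lt(shifted$agreement, 1)
  # adding a constant to one session leaves C,1 unchanged
  s2 <- s1 + rnorm(12, 0, 2)
  expect_equal(icc(cbind(s1, s2 + 7))$consistency,
               icc(cbind(s1, s2))$consistency, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(icc(cbind(s1, s2 + 7))$agreement,
                                icc(cbind(s1, s2))$agreement)))
})

test_that("degenerate icc inputs are flagged or rejected", {
  expect_error(icc(cbind(1:2, 1:2)), ">= 3 subjects")
  flat <- icc(cbind(rep(5, 4) + c(0.001, 0, 0, 0), rep(5, 4)))
  expect_true(is.list(flat))
})

test_that("difference scores are less reliable than their components", {
  # long and short scores share a common component; the difference cancels
  # the shared part and keeps the noise
  set.seed(11)
  n <- 400
  common <- rnorm(n)
  specific <- rnorm(n, sd = 0.5)
  make_session <- function() {
    long <- common + specific + rnorm(n, sd = 0.8)
    short <- common + rnorm(n, sd = 0.8)
    list(long = long, diff = long - short)
  }
  s1 <- make_session(); s2 <- make_session()
  icc_long <- icc(cbind(s1$long, s2$long))$consistency
  icc_diff <- icc(cbind(s1$diff, s2$diff))$consistency
  expect_lt(icc_diff, icc_long)
})

test_that("convergent matrix is symmetric, unit-diagonal and flags constants", {
  set.seed(3)
  m <- tibble::tibble(subject = 1:50, a = rnorm(50), b = rnorm(50),
                      c = rep(1, 50))
  cm <- convergent_matrix(m)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["a", "b"], cm["b", "a"])
  expect_true(is.na(cm["a", "c"]))
  expect_equal(attr(cm, "flagged"), "c")
  # independent columns at large N have near-zero correlation
  big <- tibble::tibble(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(abs(convergent_matrix(big)["x", "y"]), 0.05)
})

test_that("cross-task true-parameter correlations approach the loading products", {
  sp <- cohort_spec(n_subjects = 4000, rho = 0.7, factor_cor = 0.64, seed = 2)
  tr <- banditmetrics:::cohort_truth(sp)$truth
  t1 <- tr[tr$session == 1 & tr$parameter %in% c("value_guided", "directed"), ]
  t1$m <- paste0(t1$task, "_", t1$parameter)
  wide <- tidyr::pivot_wider(t1[, c("subject", "m", "value")],
                             names_from = "m", values_from = "value")
  cm <- convergent_matrix(wide)
  sc <- default_parameter_scales()
  L <- function(t, p) sc$loading[sc$task == t & sc$parameter == p]
  expect_equal(cm["horizon_value_guided", "restless_value_guided"],
               L("horizon", "value_guided") * L("restless", "value_guided"),
               tolerance = 0.06)
  expect_equal(cm["twoarmed_directed", "restless_directed"],
               L("twoarmed", "directed") * L("restless", "directed"),
               tolerance = 0.06)
})
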