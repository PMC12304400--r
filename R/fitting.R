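# ---- model designs -------------------------------------------------------
# The belief trajectories of all three models depend only on the observed
# choices and rewards, never on the free choice parameters. Each design
# therefore precomputes the per-trial features once; likelihood evaluation is
# then a vectorized softmax / logistic expression, which keeps multi-start
# optimization over hundreds of subjects cheap.

restless_design <- function(session, cfg) {
  nt <- nrow(session)
  n_arms <- max(session$choice)
  if (n_arms < 2L) n_arms <- 4L
  belief <- kalman_belief(n_arms, cfg)
  e_mat <- matrix(NA_real_, nt, n_arms)
  b_mat <- matrix(NA_real_, nt, n_arms)
  for (t in seq_len(nt)) {
    e_mat[t, ] <- belief$mean
    b_mat[t, ] <- sqrt(belief$var + cfg$innov_var)
    belief <- kalman_update(belief, session$choice[t], session$reward[t], cfg)
    belief <- diffusion_prior_step(belief, cfg)
  }
  list(task = "restless", E = e_mat, B = b_mat, choice = session$choice,
       n_obs = nt,
       par_names = c("value_guided", "directed"),
       lower = c(0, -20), upper = c(5, 20))
}

restless_nll <- function(theta, d, floor_p = 0) {
  u <- theta[1] * d$E + theta[2] * d$B
  u <- u - apply(u, 1L, max)
  eu <- exp(u)
  p <- eu[cbind(seq_len(d$n_obs), d$choice)] / rowSums(eu)
  if (floor_p > 0) p <- pmax(p, floor_p)
  -sum(log(p))
}

twoarmed_design_matrix <- function(session, cfg, variant) {
  rounds <- split(seq_len(nrow(session)), session$round)
  xs <- vector("list", length(rounds))
  for (ri in seq_along(rounds)) {
    idx <- rounds[[ri]]
    belief <- kalman_belief(2L, cfg)
    x <- matrix(NA_real_, length(idx), 3L)
    for (t in seq_along(idx)) {
      pv <- twoarmed_predictors(belief, "original")
      x[t, ] <- pv
      belief <- kalman_update(belief, session$choice[idx[t]],
                              session$reward[idx[t]], cfg)
    }
    xs[[ri]] <- x
  }
  x <- do.call(rbind, xs)
  colnames(x) <- c("value_guided", "directed", "random")
  if (variant == "improved") x <- x[, 1:2, drop = FALSE]
  par_names <- c("side_bias", colnames(x))
  list(task = "twoarmed", X = x, y = as.integer(session$choice == 1L),
       n_obs = nrow(x), par_names = par_names,
       lower = rep(-50, length(par_names)), upper = rep(50, length(par_names)))
}

logistic_nll <- function(theta, d, floor_p = 0) {
  eta <- theta[1] + drop(d$X %*% theta[-1])
  p <- plogis(eta)
  lik <- ifelse(d$y == 1L, p, 1 - p)
  if (floor_p > 0) lik <- pmax(lik, floor_p)
  -sum(log(lik))
}

# First free choice per round with forced-trial features; `horizon` selects
# rounds of one horizon condition ("long", "short", or "all").
horizon_design_matrix <- function(session, horizon = "long") {
  forced <- session[session$forced == 1L, ]
  free <- session[session$forced == 0L, ]
  first_free <- free[!duplicated(free$round), ]
  if (horizon != "all") {
    keep <- startsWith(first_free$condition, horizon)
    first_free <- first_free[keep, ]
  }
  if (nrow(first_free) == 0L) stop("no usable rounds", call. = FALSE)
  x <- matrix(NA_real_, nrow(first_free), 2L,
              dimnames = list(NULL, c("value_guided", "directed")))
  for (i in seq_len(nrow(first_free))) {
    fr <- forced[forced$round == first_free$round[i], ]
    feats <- horizon_features(fr$choice, fr$reward)
    x[i, ] <- c(feats$value_diff, feats$info_diff)
  }
  list(task = "horizon", X = x, y = as.integer(first_free$choice == 1L),
       n_obs = nrow(x), par_names = c("side_bias", "value_guided", "directed"),
       lower = rep(-50, 3L), upper = rep(50, 3L))
}

params_to_theta <- function(params, variant) {
  if (inherits(params, "restless_params")) {
    return(c(params$value_guided, params$directed))
  }
  if (inherits(params, "twoarmed_params")) {
    th <- c(params$side_bias, params$value_guided, params$directed)
    if (params$variant == "original") th <- c(th, params$random)
    return(th)
  }
  stop("unsupported params object", call. = FALSE)
}

#' Negative log-likelihood of a model on one session
#'
#' Sums `-log P(choice)` over the usable free choices: all 200 trials for the
#' restless bandit, all within-round choices for the two-armed bandit, and
#' the first free choice per round for the Horizon task (long-horizon rounds
#' only under the improved variant; both conditions, each with its own
#' parameter block, under the original variant). Forced trials contribute
#' belief updates only. A choice assigned probability zero under degenerate
#' parameters raises an error rather than being clipped.
#'
#' @param session A session tibble (see [simulate_session()]).
#' @param params A task parameter object matching the session's task.
#' @param learner_cfg A [learner_config()] (ignored for Horizon); defaults to
#'   the task's [default_learner_config()].
#' @param variant `"original"` or `"improved"`; for restless and for
#'   parameter objects carrying their own variant this is taken from the
#'   inputs.
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(session, params, learner_cfg = NULL,
                                    variant = NULL) {
  task <- session$task[1]
  if (is.null(learner_cfg) && task != "horizon") {
    learner_cfg <- default_learner_config(task)
  }
  nll <- if (task == "restless") {
    stopifnot(inherits(params, "restless_params"))
    restless_nll(params_to_theta(params), restless_design(session, learner_cfg))
  } else if (task == "twoarmed") {
    stopifnot(inherits(params, "twoarmed_params"))
    d <- twoarmed_design_matrix(session, learner_cfg, params$variant)
    logistic_nll(params_to_theta(params), d)
  } else if (task == "horizon") {
    stopifnot(inherits(params, "horizon_params"))
    blocks <- if (params$variant == "improved") "long" else c("short", "long")
    sum(vapply(blocks, function(h) {
      d <- horizon_design_matrix(session, h)
      blk <- params[[h]]
      logistic_nll(c(blk["side_bias"], blk["value_guided"], blk["directed"]), d)
    }, numeric(1)))
  } else {
    stop("unknown task id: ", task, call. = FALSE)
  }
  if (!is.finite(nll)) {
    stop("a choice had probability zero under these parameters", call. = FALSE)
  }
  nll
}

# Multi-start bounded optimization of one design's likelihood.
optimize_design <- function(d, nll_fun, n_starts, seed, floor_p = 1e-12) {
  obj <- function(th) nll_fun(th, d, floor_p = floor_p)
  k <- length(d$par_names)
  starts <- with_seed(seed, {
    m <- matrix(runif(n_starts * k, rep(d$lower, each = n_starts),
                      rep(d$upper, each = n_starts)), n_starts, k)
    m[1L, ] <- pmin(pmax(0, d$lower), d$upper)  # include a null start
    m
  })
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = d$lower, upper = d$upper,
            control = list(factr = 1e4, maxit = 200L)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0L) any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(par = setNames(rep(NA_real_, k), d$par_names),
                value = NA_real_, converged = FALSE, se = NULL))
  }
  # Newton polish: quasi-Newton stopping leaves ~1e-6 slack in the
  # parameters; a couple of damped Newton steps (numeric derivatives)
  # sharpen interior solutions to the optimizer's numerical floor
  if (all(best$par > d$lower + 1e-6 & best$par < d$upper - 1e-6)) {
    th <- best$par
    for (step in 1:3) {
      g <- num_grad(obj, th)
      h <- tryCatch(optimHess(th, obj), error = function(e) NULL)
      if (is.null(h)) break
      delta <- tryCatch(solve(h, g), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) break
      cand <- th - delta
      if (any(cand <= d$lower) || any(cand >= d$upper)) break
      if (obj(cand) <= obj(th)) th <- cand else break
    }
    if (obj(th) <= best$value) {
      best$par <- th
      best$value <- obj(th)
    }
  }
  se <- tryCatch(
    suppressWarnings(sqrt(diag(solve(optimHess(best$par, obj))))),
    error = function(e) rep(NA_real_, k)
  )
  list(par = setNames(best$par, d$par_names), value = best$value,
       converged = any_ok, se = setNames(se, d$par_names))
}

#' Maximum-likelihood fit of one subject-session
#'
#' Bounded multi-start optimization (best of `n_starts` L-BFGS-B runs with
#' starts drawn uniformly in the bounds under a fixed seed; one start is
#' always the null model). Choice probabilities are floored at 1e-12 inside
#' the optimizer only. Bounds: logistic weights in \[-50, 50\], the restless
#' inverse temperature in \[0, 5\] and the directed bonus in \[-20, 20\].
#'
#' @param session A session tibble for a single subject, session and task.
#' @param variant `"original"` or `"improved"`.
#' @param learner_cfg Optional [learner_config()].
#' @param n_starts Number of optimization starts (>= 5 recommended).
#' @param seed Seed for the start draws.
#' @return A list of class `fit_result`: `estimates` (named vector),
#'   `log_lik`, `converged`, `n_obs`, `variant`, `task`, `se`.
#' @export
fit_mle <- function(session, variant = c("improved", "original"),
                    learner_cfg = NULL, n_starts = 5L, seed = 1L) {
  variant <- match.arg(variant)
  task <- session$task[1]
  if (is.null(learner_cfg) && task != "horizon") {
    learner_cfg <- default_learner_config(task)
  }
  if (task == "restless") {
    d <- restless_design(session, learner_cfg)
    o <- optimize_design(d, restless_nll, n_starts, seed)
    est <- o$par; se <- o$se; nobs <- d$n_obs; val <- o$value; conv <- o$converged
  } else if (task == "twoarmed") {
    d <- twoarmed_design_matrix(session, learner_cfg, variant)
    o <- optimize_design(d, logistic_nll, n_starts, seed)
    est <- o$par; se <- o$se; nobs <- d$n_obs; val <- o$value; conv <- o$converged
  } else if (task == "horizon") {
    blocks <- if (variant == "improved") "long" else c("short", "long")
    est <- c(); se <- c(); nobs <- 0L; val <- 0; conv <- TRUE
    for (h in blocks) {
      d <- horizon_design_matrix(session, h)
      o <- optimize_design(d, logistic_nll, n_starts, derive_seed(seed, h))
      pre <- if (variant == "improved") "" else paste0(h, ".")
      names(o$par) <- paste0(pre, names(o$par))
      est <- c(est, o$par)
      se <- c(se, setNames(o$se, names(o$par)))
      nobs <- nobs + d$n_obs; val <- val + o$value; conv <- conv && o$converged
    }
  } else {
    stop("unknown task id: ", task, call. = FALSE)
  }
  structure(
    list(estimates = est, log_lik = -val, converged = conv, n_obs = nobs,
         variant = variant, task = task, se = se),
    class = "fit_result"
  )
}

#' Strategy scores of a fitted model
#'
#' Maps a [fit_mle()] result to the named exploration measures used in the
#' reliability and validity analyses: `value_guided` and `directed` (plus
#' `random` for the original two-armed variant). For the original Horizon
#' variant these are the long-minus-short weight differences; for the
#' improved variant the long-horizon weights themselves.
#'
#' @param fit A `fit_result`.
#' @return Named numeric vector of strategy scores.
#' @export
fit_scores <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  e <- fit$estimates
  if (fit$task == "horizon" && fit$variant == "original") {
    return(c(value_guided = unname(e["long.value_guided"] - e["short.value_guided"]),
             directed = unname(e["long.directed"] - e["short.directed"])))
  }
  keep <- intersect(c("value_guided", "directed", "random"), names(e))
  e[keep]
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s (%s), logLik %.2f on %d obs%s>\n",
              x$task, x$variant, x$log_lik, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$estimates, 4))
  invisible(x)
}

# Build the (design, nll) pair for one subject's session.
subject_design <- function(session, task, variant, learner_cfg, horizon_block) {
  if (task == "restless") {
    list(d = restless_design(session, learner_cfg), nll = restless_nll)
  } else if (task == "twoarmed") {
    list(d = twoarmed_design_matrix(session, learner_cfg, variant),
         nll = logistic_nll)
  } else {
    list(d = horizon_design_matrix(session, horizon_block), nll = logistic_nll)
  }
}

#' Hierarchical (partial-pooling) fit across subjects
#'
#' Penalized marginal optimization with independent Normal group
#' distributions per parameter: alternates subject-level MAP estimation
#' (likelihood plus Normal prior at the current group mean/variance) with
#' EM-style updates of the group moments, using a Laplace approximation to
#' each subject's posterior variance. Produces shrunken subject estimates
#' and group means with 95% intervals.
#'
#' For the Horizon task the improved variant pools the long-horizon block;
#' the original variant pools the short and long blocks separately and
#' reports both.
#'
#' @param sessions Trials for >= 2 subjects of a single task and session
#'   (one tibble; split internally by subject).
#' @param variant `"original"` or `"improved"`.
#' @param learner_cfg Optional [learner_config()].
#' @param iterations Maximum number of outer EM iterations.
#' @param tol Convergence tolerance on the largest group-mean change.
#' @param n_starts Multi-start count for the initial MLEs.
#' @param seed Integer seed.
#' @return A list of class `hierarchical_fit`: `group` (tibble with
#'   parameter, mean, sd, lower, upper of the 95% interval of the group
#'   mean), `subjects` (shrunken estimates), `mle` (unpooled estimates) and
#'   `diagnostics`.
#' @export
fit_hierarchical <- function(sessions, variant = c("improved", "original"),
                             learner_cfg = NULL, iterations = 15L, tol = 1e-3,
                             n_starts = 5L, seed = 1L) {
  variant <- match.arg(variant)
  task <- sessions$task[1]
  subjects <- unique(sessions$subject)
  if (length(subjects) < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (is.null(learner_cfg) && task != "horizon") {
    learner_cfg <- default_learner_config(task)
  }
  blocks <- if (task == "horizon" && variant == "original") {
    c("short", "long")
  } else if (task == "horizon") "long" else "none"

  group_out <- list(); subj_out <- list(); mle_out <- list()
  diags <- list(converged = TRUE, iterations = integer(0))
  for (blk in blocks) {
    designs <- lapply(subjects, function(s) {
      subject_design(sessions[sessions$subject == s, ], task, variant,
                     learner_cfg, blk)
    })
    k <- length(designs[[1]]$d$par_names)
    par_names <- designs[[1]]$d$par_names
    if (blk != "none") par_names <- paste0(blk, ".", par_names)

    mles <- t(vapply(seq_along(designs), function(i) {
      optimize_design(designs[[i]]$d, designs[[i]]$nll, n_starts,
                      derive_seed(seed, "mle", blk, i))$par
    }, numeric(k)))
    # robust initialization: unpenalized MLEs of weakly identified subjects
    # pile up at the bounds; exclude those from the starting group moments
    lo <- designs[[1]]$d$lower; hi <- designs[[1]]$d$upper
    interior <- mles > rep(lo + 1e-3, each = nrow(mles)) &
      mles < rep(hi - 1e-3, each = nrow(mles))
    mu <- vapply(seq_len(k), function(j) {
      v <- mles[interior[, j], j]
      if (length(v) >= 3L) median(v, na.rm = TRUE) else min(max(0, lo[j]), hi[j])
    }, numeric(1))
    s0 <- vapply(seq_len(k), function(j) {
      v <- mles[interior[, j], j]
      if (length(v) >= 3L) min(max(stats::mad(v, na.rm = TRUE)^2, 0.05), 2) else 1
    }, numeric(1))
    sig2 <- s0
    nu <- 2  # pseudo-subjects stabilizing the group-variance update

    maps <- matrix(rep(mu, each = nrow(mles)), nrow(mles), k)
    post_var <- matrix(1e-2, nrow(mles), k)
    iter_used <- 0L
    for (it in seq_len(iterations)) {
      iter_used <- it
      for (i in seq_along(designs)) {
        d <- designs[[i]]$d; nllf <- designs[[i]]$nll
        pen <- function(th) nllf(th, d, floor_p = 1e-12) +
          sum((th - mu)^2 / (2 * sig2))
        o <- tryCatch(
          optim(maps[i, ], pen, method = "L-BFGS-B",
                lower = d$lower, upper = d$upper),
          error = function(e) NULL
        )
        if (!is.null(o)) {
          maps[i, ] <- o$par
          h <- tryCatch(suppressWarnings(diag(solve(optimHess(o$par, pen)))),
                        error = function(e) rep(NA_real_, k))
          post_var[i, ] <- ifelse(is.finite(h) & h > 0, h, sig2)
        }
      }
      mu_new <- colMeans(maps)
      s_hat <- colMeans((maps - rep(mu_new, each = nrow(maps)))^2 + post_var)
      sig2_new <- pmax((nrow(maps) * s_hat + nu * s0) / (nrow(maps) + nu), 1e-6)
      delta <- max(abs(mu_new - mu))
      mu <- mu_new; sig2 <- sig2_new
      if (delta < tol) break
    }
    diags$converged <- diags$converged && delta < tol
    diags$iterations <- c(diags$iterations, iter_used)
    diags[[paste0("delta_", blk)]] <- delta

    se_mu <- sqrt(sig2 / length(subjects))
    group_out[[blk]] <- tibble::tibble(
      parameter = par_names, mean = mu, sd = sqrt(sig2),
      lower = mu - qnorm(0.975) * se_mu, upper = mu + qnorm(0.975) * se_mu
    )
    subj_out[[blk]] <- tibble::tibble(
      subject = rep(subjects, times = k),
      parameter = rep(par_names, each = length(subjects)),
      estimate = as.vector(maps)
    )
    mle_out[[blk]] <- tibble::tibble(
      subject = rep(subjects, times = k),
      parameter = rep(par_names, each = length(subjects)),
      estimate = as.vector(mles)
    )
  }
  structure(
    list(group = dplyr::bind_rows(group_out),
         subjects = dplyr::bind_rows(subj_out),
         mle = dplyr::bind_rows(mle_out),
         task = task, variant = variant, diagnostics = diags),
    class = "hierarchical_fit"
  )
}
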