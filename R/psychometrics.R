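#' Trial-by-trial switch probability
#'
#' Proportion of eligible consecutive free-choice pairs on which the chosen
#' arm differs from the previous free choice. Pairs never span round
#' boundaries, so in the Horizon task only within-round free choices are
#' compared and short-horizon rounds (a single free choice) contribute no
#' pairs.
#'
#' @param session A session tibble for one subject/session/task.
#' @return Proportion in \[0, 1\].
#' @export
switch_probability <- function(session) {
  free <- session[session$forced == 0L, ]
  pairs <- 0L; switches <- 0L
  for (d in split(free, free$round)) {
    if (nrow(d) < 2L) next
    ch <- d$choice[order(d$trial)]
    pairs <- pairs + length(ch) - 1L
    switches <- switches + sum(diff(ch) != 0L)
  }
  if (pairs == 0L) stop("no eligible consecutive free-choice pairs", call. = FALSE)
  switches / pairs
}

#' Proportion of optimal choices
#'
#' Fraction of free choices whose arm attains the maximal latent mean reward
#' on that trial; ties count as optimal.
#'
#' @param session A session tibble.
#' @param rewardset The `reward_set` the session was played on.
#' @return Proportion in \[0, 1\].
#' @export
p_optimal <- function(session, rewardset) {
  stopifnot(inherits(rewardset, "reward_set"))
  free <- session[session$forced == 0L, ]
  lm_ <- latent_matrices(rewardset)
  hits <- vapply(seq_len(nrow(free)), function(i) {
    m <- lm_[[as.character(free$round[i])]]
    mu <- m[free$trial[i], ]
    as.integer(mu[free$choice[i]] >= max(mu))
  }, integer(1))
  mean(hits)
}

#' Chance-performance inclusion threshold
#'
#' Smallest count k of optimal choices such that the binomial chance CDF
#' `P(X <= k)` with success probability `1 / n_arms` reaches the requested
#' percentile; subjects must exceed chance at this percentile to be included.
#'
#' @param n_trials Number of scored trials.
#' @param n_arms Number of arms (chance success probability `1/n_arms`).
#' @param percentile Percentile of the chance distribution, in (0, 1).
#' @return Integer threshold count.
#' @export
chance_inclusion_threshold <- function(n_trials, n_arms, percentile = 0.95) {
  n_trials <- check_count(n_trials, "n_trials")
  n_arms <- check_count(n_arms, "n_arms", min = 2L)
  if (percentile <= 0 || percentile >= 1) {
    stop("`percentile` must lie in (0, 1)", call. = FALSE)
  }
  k <- which(pbinom(0:n_trials, n_trials, 1 / n_arms) >= percentile)[1] - 1L
  as.integer(k)
}

#' Intraclass correlation for test-retest reliability
#'
#' Two-way mixed-effects single-measure ICCs from the ANOVA decomposition of
#' a subjects-by-sessions table: the consistency form
#' `ICC3(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)` and the absolute
#' agreement form, which additionally penalizes session mean differences via
#' the session mean square.
#'
#' @param values A data frame with columns `subject`, `session`, `value`, or
#'   a numeric matrix with one row per subject and one column per session.
#' @return A list of class `icc_estimate`: `consistency`, `agreement`,
#'   `n_subjects`, `n_sessions`, `ms` (the mean squares), and `degenerate`
#'   (TRUE when between-subject variance is zero and the ratio undefined).
#' @export
icc <- function(values) {
  if (is.data.frame(values)) {
    wide <- tapply(values$value, list(values$subject, values$session), mean)
  } else {
    wide <- as.matrix(values)
  }
  wide <- wide[complete.cases(wide), , drop = FALSE]
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 sessions", call. = FALSE)
  grand <- mean(wide)
  row_m <- rowMeans(wide); col_m <- colMeans(wide)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  degenerate <- ms_r <= .Machine$double.eps * abs(grand + 1)
  c1 <- if (degenerate && ms_e == 0) NA_real_ else
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  a1 <- if (degenerate && ms_e == 0) NA_real_ else
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  structure(
    list(consistency = c1, agreement = a1, n_subjects = n, n_sessions = k,
         ms = c(subjects = ms_r, sessions = ms_c, error = ms_e),
         degenerate = degenerate),
    class = "icc_estimate"
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC3(C,1) = %.3f, ICC3(A,1) = %.3f (n = %d, k = %d)%s\n",
              x$consistency, x$agreement, x$n_subjects, x$n_sessions,
              if (x$degenerate) " [degenerate: no between-subject variance]" else ""))
  invisible(x)
}

#' Cross-task convergent-validity correlation matrix
#'
#' Pairwise-complete Pearson correlations between the named measures of a
#' subject-by-measure table; symmetric with unit diagonal. Constant columns
#' yield `NA` entries and are reported in the `flagged` attribute.
#'
#' @param measures A data frame with one row per subject (a `subject` column
#'   is ignored if present) and one column per measure.
#' @param measure_names Columns to correlate; defaults to all non-identifier
#'   numeric columns.
#' @return Correlation matrix with attribute `flagged` (names of constant
#'   columns).
#' @export
convergent_matrix <- function(measures, measure_names = NULL) {
  df <- as.data.frame(measures)
  df <- df[, setdiff(names(df), c("subject", "session")), drop = FALSE]
  if (!is.null(measure_names)) df <- df[, measure_names, drop = FALSE]
  if (nrow(df) < 3L) stop("need >= 3 subjects", call. = FALSE)
  flagged <- names(df)[vapply(df, function(x) {
    stats::var(x, na.rm = TRUE) == 0 || all(is.na(x))
  }, logical(1))]
  m <- suppressWarnings(cor(as.matrix(df), use = "pairwise.complete.obs"))
  diag(m) <- 1
  attr(m, "flagged") <- flagged
  m
}

#' Per-subject measure table for a cohort
#'
#' Fits the requested model variant to every subject-session of a cohort by
#' maximum likelihood and assembles the strategy scores together with the
#' model-free measures (switch probability and p(optimal)) into a wide
#' subject-by-measure table, one row per subject and session. Measure columns
#' are named `<task>_<measure>`.
#'
#' @param cohort A `cohort_data`.
#' @param variant Model variant passed to [fit_mle()].
#' @param tasks Tasks to include (defaults to all simulated tasks).
#' @param n_starts,seed Passed to [fit_mle()].
#' @return A tibble: subject, session, then one column per measure.
#' @export
cohort_measures <- function(cohort, variant = "improved",
                            tasks = cohort$spec$tasks, n_starts = 5L,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  rows <- list()
  for (s in seq_len(cohort$spec$n_sessions)) {
    for (task in tasks) {
      dat <- cohort$sessions[cohort$sessions$session == s &
                               cohort$sessions$task == task, ]
      rs <- cohort$reward_sets[[s]][[task]]
      for (i in unique(dat$subject)) {
        di <- dat[dat$subject == i, ]
        fit <- fit_mle(di, variant = variant, n_starts = n_starts,
                       seed = derive_seed(seed, "mt", s, task, i))
        sc <- fit_scores(fit)
        vals <- c(sc, switch = switch_probability(di),
                  p_optimal = p_optimal(di, rs))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = i, session = s,
          measure = paste0(task, "_", names(vals)), value = unname(vals),
          converged = fit$converged
        )
      }
    }
  }
  long <- dplyr::bind_rows(rows)
  long$value[!long$converged] <- NA_real_
  tidyr::pivot_wider(long[, c("subject", "session", "measure", "value")],
                     names_from = "measure", values_from = "value")
}
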