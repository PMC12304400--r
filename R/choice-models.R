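#' Free parameters of the restless-bandit choice model
#'
#' Upper-confidence-bound softmax: utilities are
#' `value_guided * E_j + directed * sqrt(V_j + innov_var)`; `value_guided`
#' is the inverse temperature on expected value, `directed` the weight on the
#' uncertainty bonus (negative values mean uncertainty avoidance).
#'
#' @param value_guided Inverse temperature on posterior means.
#' @param directed Weight on the posterior uncertainty bonus.
#' @return A list of class `restless_params`.
#' @export
restless_params <- function(value_guided, directed) {
  stopifnot(is.finite(value_guided), is.finite(directed))
  structure(list(value_guided = value_guided, directed = directed),
            class = c("restless_params", "model_params"))
}

#' Free parameters of the two-armed bandit choice model
#'
#' Logistic regression on belief-derived predictors. The original variant
#' carries three predictors (value difference, relative uncertainty, and the
#' total-uncertainty-scaled value difference capturing random/Thompson
#' exploration); the improved variant drops the random-exploration term.
#'
#' @param side_bias Intercept (log-odds of choosing arm 1 with flat beliefs).
#' @param value_guided Weight on `E1 - E2`.
#' @param directed Weight on `sqrt(V1) - sqrt(V2)`.
#' @param random Weight on `(E1 - E2) / sqrt(V1 + V2)`; must be `NULL` for
#'   the improved variant.
#' @param variant `"original"` or `"improved"`.
#' @return A list of class `twoarmed_params`.
#' @export
twoarmed_params <- function(side_bias, value_guided, directed,
                            random = NULL, variant = c("original", "improved")) {
  variant <- match.arg(variant)
  if (variant == "improved" && !is.null(random)) {
    stop("the improved variant has no random-exploration weight", call. = FALSE)
  }
  if (variant == "original" && is.null(random)) {
    stop("the original variant requires a `random` weight", call. = FALSE)
  }
  structure(
    list(side_bias = side_bias, value_guided = value_guided,
         directed = directed, random = random, variant = variant),
    class = c("twoarmed_params", "model_params")
  )
}

#' Free parameters of the Horizon task choice model
#'
#' One logistic model per horizon condition (original variant), each with an
#' intercept (side bias), a weight on the forced-trial value difference and a
#' weight on the scaled information difference. Strategy scores of the
#' original variant are the long-minus-short weight differences; the improved
#' variant keeps only the long-horizon block.
#'
#' @param long Named numeric vector `c(side_bias=, value_guided=, directed=)`
#'   for the long horizon.
#' @param short Same for the short horizon; omit for the improved variant.
#' @param variant `"original"` or `"improved"`.
#' @return A list of class `horizon_params`.
#' @export
horizon_params <- function(long, short = NULL,
                           variant = c("original", "improved")) {
  variant <- match.arg(variant)
  need <- c("side_bias", "value_guided", "directed")
  check_block <- function(b, name) {
    if (!is.numeric(b) || !all(need %in% names(b))) {
      stop(sprintf("`%s` must be a named vector with %s", name,
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    b[need]
  }
  long <- check_block(long, "long")
  if (variant == "original") {
    short <- check_block(short, "short")
  } else if (!is.null(short)) {
    stop("the improved variant uses only the long-horizon block", call. = FALSE)
  }
  structure(list(long = long, short = short, variant = variant),
            class = c("horizon_params", "model_params"))
}

#' Strategy scores of the original Horizon model
#'
#' @param params A `horizon_params` of the original variant.
#' @return Named vector with `value_guided` and `directed` long-minus-short
#'   weight differences.
#' @export
horizon_strategy_scores <- function(params) {
  stopifnot(inherits(params, "horizon_params"))
  if (params$variant != "original") {
    stop("strategy difference scores exist only for the original variant",
         call. = FALSE)
  }
  c(value_guided = unname(params$long["value_guided"] - params$short["value_guided"]),
    directed = unname(params$long["directed"] - params$short["directed"]))
}

#' Forced-trial features of a Horizon round
#'
#' The expected value of each arm is the plain average of its forced-trial
#' rewards; the information difference is the difference in sampling counts
#' scaled to \{-0.5, 0, +0.5\}.
#'
#' @param forced_arms Integer vector (length 4) of forced arm indices (1/2).
#' @param forced_rewards Numeric vector (length 4) of the observed rewards.
#' @return List with `value_diff` (`E1 - E2`), `info_diff`
#'   (`(I1 - I2) / 4`), per-arm `means` and `counts`.
#' @export
horizon_features <- function(forced_arms, forced_rewards) {
  if (length(forced_arms) != 4L || length(forced_rewards) != 4L) {
    stop("exactly 4 forced trials are required", call. = FALSE)
  }
  counts <- tabulate(forced_arms, nbins = 2L)
  if (any(counts == 0L)) {
    stop("each arm must be forced-sampled at least once", call. = FALSE)
  }
  means <- vapply(1:2, function(a) mean(forced_rewards[forced_arms == a]),
                  numeric(1))
  list(value_diff = means[1] - means[2],
       info_diff = (counts[1] - counts[2]) / 4,
       means = means, counts = counts)
}

#' Choice probabilities of the restless-bandit UCB softmax
#'
#' @param belief A `kalman_belief`.
#' @param params A [restless_params()].
#' @param cfg A [learner_config()] (supplies the innovation variance that
#'   enters the uncertainty bonus).
#' @return Probability vector over arms (sums to 1). Invariant to adding a
#'   constant to all utilities (max-subtracted softmax).
#' @export
ucb_choice_probs <- function(belief, params, cfg) {
  stopifnot(inherits(belief, "kalman_belief"), inherits(params, "restless_params"))
  u <- params$value_guided * belief$mean +
    params$directed * sqrt(belief$var + cfg$innov_var)
  e <- exp(u - max(u))
  e / sum(e)
}

#' Belief-derived predictors of the two-armed bandit choice model
#'
#' @param belief A `kalman_belief` over exactly two arms.
#' @param variant `"original"` (adds the random-exploration predictor) or
#'   `"improved"`.
#' @return Named numeric vector: `value_diff`, `directed`, and (original
#'   variant) `random`.
#' @export
twoarmed_predictors <- function(belief, variant = c("original", "improved")) {
  variant <- match.arg(variant)
  stopifnot(inherits(belief, "kalman_belief"))
  if (length(belief$mean) != 2L) stop("exactly 2 arms required", call. = FALSE)
  value_diff <- belief$mean[1] - belief$mean[2]
  directed <- sqrt(belief$var[1]) - sqrt(belief$var[2])
  if (variant == "improved") {
    return(c(value_diff = value_diff, directed = directed))
  }
  tot <- belief$var[1] + belief$var[2]
  if (tot <= 0) {
    stop("total uncertainty is zero; random-exploration predictor undefined",
         call. = FALSE)
  }
  c(value_diff = value_diff, directed = directed, random = value_diff / sqrt(tot))
}

#' Logistic choice probability for arm 1
#'
#' `p = plogis(intercept + sum(weights * predictors))`, with weights matched
#' to predictors by name.
#'
#' @param predictors Named numeric vector of predictor values.
#' @param intercept Side-bias intercept.
#' @param weights Named numeric vector of regression weights; names must
#'   match `predictors` exactly.
#' @return Probability of choosing arm 1.
#' @export
logistic_choice_prob <- function(predictors, intercept, weights) {
  if (!setequal(names(predictors), names(weights))) {
    stop("predictor and weight names must match", call. = FALSE)
  }
  plogis(intercept + sum(weights[names(predictors)] * predictors))
}
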