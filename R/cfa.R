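#' Specify a confirmatory factor model
#'
#' @param factors Named list mapping each factor name to the character vector
#'   of indicators loading on it.
#' @param residual_pairs Optional list of length-2 character vectors naming
#'   indicator pairs whose residuals are allowed to covary (used to absorb
#'   same-task parameter trade-offs).
#' @return A list of class `cfa_model_spec`.
#' @export
cfa_model_spec <- function(factors, residual_pairs = list()) {
  if (length(factors) == 0L || is.null(names(factors))) {
    stop("`factors` must be a named list", call. = FALSE)
  }
  indicators <- unique(unlist(factors))
  for (pr in residual_pairs) {
    if (length(pr) != 2L || pr[1] == pr[2] || !all(pr %in% indicators)) {
      stop("residual pairs must name two distinct model indicators",
           call. = FALSE)
    }
  }
  structure(list(factors = factors, indicators = indicators,
                 residual_pairs = residual_pairs),
            class = "cfa_model_spec")
}

# Parameter packing for the CFA objective: free loadings per factor edge,
# lower-triangle factor correlations, residual variances, residual
# covariances. Factors are identified by unit variance.
cfa_par_layout <- function(spec) {
  edges <- do.call(rbind, lapply(names(spec$factors), function(f) {
    data.frame(indicator = spec$factors[[f]], factor = f,
               stringsAsFactors = FALSE)
  }))
  nf <- length(spec$factors)
  n_cor <- nf * (nf - 1L) / 2L
  p <- length(spec$indicators)
  n_rescov <- length(spec$residual_pairs)
  list(edges = edges, nf = nf, n_cor = n_cor, p = p, n_rescov = n_rescov,
       n_par = nrow(edges) + n_cor + p + n_rescov)
}

cfa_sigma <- function(theta, spec, layout) {
  p <- layout$p
  lambda <- matrix(0, p, layout$nf,
                   dimnames = list(spec$indicators, names(spec$factors)))
  lv <- theta[seq_len(nrow(layout$edges))]
  lambda[cbind(match(layout$edges$indicator, spec$indicators),
               match(layout$edges$factor, names(spec$factors)))] <- lv
  phi <- diag(layout$nf)
  if (layout$n_cor > 0L) {
    phi[lower.tri(phi)] <- theta[nrow(layout$edges) + seq_len(layout$n_cor)]
    phi[upper.tri(phi)] <- t(phi)[upper.tri(phi)]
  }
  resv <- theta[nrow(layout$edges) + layout$n_cor + seq_len(p)]
  theta_mat <- diag(resv, p)
  if (layout$n_rescov > 0L) {
    off <- theta[nrow(layout$edges) + layout$n_cor + p + seq_len(layout$n_rescov)]
    for (j in seq_along(spec$residual_pairs)) {
      idx <- match(spec$residual_pairs[[j]], spec$indicators)
      theta_mat[idx[1], idx[2]] <- theta_mat[idx[2], idx[1]] <- off[j]
    }
  }
  sigma <- lambda %*% phi %*% t(lambda) + theta_mat
  list(sigma = sigma, lambda = lambda, phi = phi, theta = theta_mat)
}

cfa_fml <- function(sigma, s) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(1e10)
  p <- nrow(s)
  sum(log(ev)) + sum(diag(s %*% solve(sigma))) -
    determinant(s, logarithm = TRUE)$modulus[1] - p
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Analyzes the correlation matrix of the indicators (factors identified by
#' unit variance, all loadings free, factor correlations free), minimizing
#' the ML discrepancy `log|Sigma| + tr(S Sigma^-1) - log|S| - p`. Reports
#' standardized loadings, factor correlations, residual (co)variances, the
#' model chi-square with degrees of freedom, CFI against the independence
#' baseline, RMSEA, BIC, and admissibility flags: solutions with a residual
#' variance at the lower bound (a Heywood case) or a failed optimizer are
#' flagged, never silently accepted.
#'
#' @param data Matrix or data frame of indicator scores (rows = subjects),
#'   or `NULL` if `sample_cov` is given.
#' @param spec A [cfa_model_spec()].
#' @param sample_cov Optional sample covariance/correlation matrix with
#'   dimnames covering the spec's indicators.
#' @param n Sample size (required with `sample_cov`).
#' @param n_starts Multi-start count for the optimizer.
#' @param seed Seed for the start jitter.
#' @return A list of class `cfa_fit` with `loadings` (standardized),
#'   `factor_cor`, `residual_var`, `residual_cov`, `chisq`, `df`, `cfi`,
#'   `rmsea`, `log_lik`, `bic`, `n`, `n_par`, `converged`, `admissible`,
#'   `heywood`.
#' @export
fit_cfa <- function(data = NULL, spec, sample_cov = NULL, n = NULL,
                    n_starts = 3L, seed = 1L) {
  stopifnot(inherits(spec, "cfa_model_spec"))
  if (is.null(sample_cov)) {
    data <- as.data.frame(data)[, spec$indicators, drop = FALSE]
    data <- data[complete.cases(data), , drop = FALSE]
    n <- nrow(data)
    sample_cov <- cov(as.matrix(data))
  } else {
    if (is.null(n)) stop("`n` is required with `sample_cov`", call. = FALSE)
    sample_cov <- sample_cov[spec$indicators, spec$indicators]
  }
  p <- length(spec$indicators)
  s <- cov2cor(sample_cov)
  if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("sample covariance is singular", call. = FALSE)
  }
  layout <- cfa_par_layout(spec)
  df <- p * (p + 1) / 2 - layout$n_par
  if (df < 0) stop("model is not identified (negative df)", call. = FALSE)

  lower <- c(rep(-2, nrow(layout$edges)), rep(-0.99, layout$n_cor),
             rep(1e-6, p), rep(-5, layout$n_rescov))
  upper <- c(rep(2, nrow(layout$edges)), rep(0.99, layout$n_cor),
             rep(10, p), rep(5, layout$n_rescov))
  base_start <- c(rep(0.5, nrow(layout$edges)), rep(0.3, layout$n_cor),
                  rep(0.5, p), rep(0, layout$n_rescov))
  obj <- function(th) cfa_fml(cfa_sigma(th, spec, layout)$sigma, s)
  starts <- with_seed(seed, {
    m <- matrix(rep(base_start, n_starts), n_starts, layout$n_par, byrow = TRUE)
    if (n_starts > 1L) {
      m[-1L, ] <- m[-1L, ] + rnorm((n_starts - 1L) * layout$n_par, 0, 0.15)
    }
    pmin(pmax(m, rep(lower, each = n_starts)), rep(upper, each = n_starts))
  })
  best <- NULL; any_ok <- FALSE
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500L)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (o$convergence == 0L) any_ok <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("CFA optimization failed from all starts", call. = FALSE)
  mats <- cfa_sigma(best$par, spec, layout)
  fmin <- max(best$value, 0)
  chisq <- (n - 1) * fmin
  # baseline (independence) model on the correlation matrix
  chisq_b <- -(n - 1) * determinant(s, logarithm = TRUE)$modulus[1]
  df_b <- p * (p - 1) / 2
  cfi <- if (max(chisq_b - df_b, chisq - df, 0) == 0) 1 else
    1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)
  rmsea <- if (df == 0) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))
  s_ml <- s * (n - 1) / n
  log_lik <- -(n / 2) * (p * log(2 * pi) +
                           determinant(mats$sigma, logarithm = TRUE)$modulus[1] +
                           sum(diag(s_ml %*% solve(mats$sigma))))
  bic <- -2 * log_lik + layout$n_par * log(n)
  resv <- diag(mats$theta)
  heywood <- any(resv <= 1e-4)
  std_load <- sweep(mats$lambda, 1L, sqrt(diag(mats$sigma)), `/`)
  structure(
    list(loadings = std_load, factor_cor = mats$phi,
         residual_var = setNames(resv, spec$indicators),
         residual_cov = mats$theta - diag(resv),
         implied_cor = mats$sigma,
         chisq = chisq, df = df, cfi = cfi, rmsea = rmsea,
         log_lik = log_lik, bic = bic, n = n, n_par = layout$n_par,
         converged = any_ok, heywood = heywood,
         admissible = any_ok && !heywood, spec = spec),
    class = "cfa_fit"
  )
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit: chisq(%d) = %.3f, CFI = %.3f, RMSEA = %.3f, BIC = %.1f (n = %d)>\n",
              x$df, x$chisq, x$cfi, x$rmsea, x$bic, x$n))
  if (!x$admissible) {
    cat(sprintf("  NOT admissible (%s)\n",
                if (x$heywood) "Heywood case: residual variance at bound"
                else "optimizer did not converge"))
  }
  cat("standardized loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' BIC-approximate Bayes factor between two CFA fits
#'
#' Approximates the Bayes factor of model A over model B on the same data by
#' `exp((BIC_B - BIC_A) / 2)`; values above 1 favor A. The approximation is
#' BIC-based (a unit-information-prior argument), which the report labels
#' explicitly.
#'
#' @param fit_a,fit_b Two `cfa_fit` objects fitted to the same sample.
#' @return List with `bf_ab`, `log10_bf_ab`, `delta_bic`, `method`.
#' @export
compare_models_bf <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "cfa_fit"), inherits(fit_b, "cfa_fit"))
  if (fit_a$n != fit_b$n) stop("fits use different sample sizes", call. = FALSE)
  delta <- fit_b$bic - fit_a$bic
  list(bf_ab = exp(delta / 2), log10_bf_ab = delta / (2 * log(10)),
       delta_bic = delta, method = "BIC approximation (unit-information prior)")
}

#' Default exploration measurement-model specs
#'
#' The two-factor structural model loads the three tasks' value-guided
#' parameters on one factor and the three directed parameters on a second,
#' correlated factor, with correlated residuals for parameter pairs
#' estimated from the same task; the one-factor alternative loads all six
#' indicators on a single exploration factor.
#'
#' @param two_factor If `FALSE`, returns the one-factor alternative.
#' @return A [cfa_model_spec()].
#' @export
exploration_cfa_spec <- function(two_factor = TRUE) {
  value_ind <- paste0(c("horizon", "twoarmed", "restless"), "_value_guided")
  dir_ind <- paste0(c("horizon", "twoarmed", "restless"), "_directed")
  pairs <- lapply(c("horizon", "twoarmed", "restless"), function(t) {
    paste0(t, c("_value_guided", "_directed"))
  })
  if (two_factor) {
    cfa_model_spec(list(value = value_ind, directed = dir_ind),
                   residual_pairs = pairs)
  } else {
    cfa_model_spec(list(exploration = c(value_ind, dir_ind)),
                   residual_pairs = pairs)
  }
}
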