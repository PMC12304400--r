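#' @importFrom stats optim optimHess rnorm runif sd cor var qnorm pbinom
#' @importFrom stats plogis median setNames complete.cases cov2cor aov
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic operations in the package funnel through this so that
# (config, seed) -> output is a pure function.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  raw <- utils::head(utils::tail(strtoi(charToRaw(digest_string(key)), 16L), 6L), 6L)
  as.integer((sum(raw * 7L^(seq_along(raw))) + as.integer(seed)) %% .Machine$integer.max)
}

# Small stable string hash (no external digest dependency): DJB2 variant.
digest_string <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x%08x", h %/% 2^16, h %% 2^16)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a non-negative number", name), call. = FALSE)
  }
  as.numeric(x)
}

# Central-difference gradient (used to polish optimizer solutions).
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    hj <- h * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    (f(xp) - f(xm)) / (2 * hj)
  }, numeric(1))
}

TASKS <- c("restless", "horizon", "twoarmed")

check_task <- function(task) {
  if (!is.character(task) || length(task) != 1L || !task %in% TASKS) {
    stop("`task` must be one of: ", paste(TASKS, collapse = ", "), call. = FALSE)
  }
  task
}
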