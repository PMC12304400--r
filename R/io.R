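SESSION_COLUMNS <- c("subject", "session", "task", "round", "trial",
                     "condition", "forced", "choice", "reward")

#' Write session data to CSV
#'
#' One row per trial with the documented schema (subject, session, task,
#' round, trial, condition, forced 0/1, choice as 1-based arm index,
#' reward); header row, UTF-8, "." decimal.
#'
#' @param sessions A session tibble (one or many subjects).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(sessions, path) {
  missing <- setdiff(SESSION_COLUMNS, names(sessions))
  if (length(missing) > 0L) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(sessions[, SESSION_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate session data from CSV
#'
#' Checks the header against the documented schema, rejects malformed rows
#' (missing values, non-positive arm indices, unknown task ids) with their
#' line numbers, and verifies that trial indices are contiguous from 1
#' within every subject/session/task/round block.
#'
#' @param path CSV file path.
#' @return A validated session tibble.
#' @export
read_session_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(SESSION_COLUMNS, names(raw))
  if (length(missing) > 0L) {
    stop("session file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, SESSION_COLUMNS]
  line <- seq_len(nrow(raw)) + 1L  # header occupies line 1
  bad <- !raw$task %in% TASKS
  if (any(bad)) {
    stop("unknown task id on line(s): ",
         paste(utils::head(line[bad], 5L), collapse = ", "), call. = FALSE)
  }
  malformed <- !complete.cases(raw) | raw$choice < 1L | raw$trial < 1L |
    !raw$forced %in% c(0L, 1L)
  if (any(malformed)) {
    stop("malformed row(s) at line(s): ",
         paste(utils::head(line[malformed], 5L), collapse = ", "), call. = FALSE)
  }
  key <- interaction(raw$subject, raw$session, raw$task, raw$round, drop = TRUE)
  for (d in split(raw$trial, key)) {
    if (!identical(sort(d), seq_along(d))) {
      stop("non-contiguous trial indices within a round", call. = FALSE)
    }
  }
  tibble::as_tibble(raw)
}

#' Write a long-format parameter table to CSV
#'
#' One row per subject, session, task, variant and parameter.
#'
#' @param table A tibble with those columns plus `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default pipeline configuration
#'
#' A demo-scale configuration of the full measurement pipeline: cohort size,
#' latent structure, model variants, recovery/optimality scales and stage
#' toggles. All scales are configurable; the defaults complete a full run at
#' desk scale.
#'
#' @param n_subjects Cohort size.
#' @param seed Global seed; every stage derives its own stream from it.
#' @param tasks Tasks to simulate and analyze.
#' @param stages Named logical list toggling pipeline stages.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(n_subjects = 60L, seed = 1L, tasks = TASKS,
                               stages = list()) {
  st <- list(simulate = TRUE, fit = TRUE, psychometrics = TRUE,
             recovery = TRUE, optimality = TRUE, latent = TRUE)
  st[names(stages)] <- stages
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      tasks = tasks, rho = 0.7, factor_cor = 0.64,
      variants = c("improved", "original"),
      recovery = list(n_subjects = 60L, n_starts = 5L),
      optimality = list(n_value = 5L, n_directed = 5L, n_reps = 20L),
      stages = st
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  known <- names(cfg)
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(y)) {
    if (is.list(cfg[[k]]) && is.list(y[[k]])) {
      cfg[[k]][names(y[[k]])] <- y[[k]]
    } else {
      cfg[[k]] <- y[[k]]
    }
  }
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  cfg$seed <- as.integer(cfg$seed)
  cfg$variants <- match.arg(cfg$variants, c("improved", "original"),
                            several.ok = TRUE)
  cfg$tasks <- vapply(cfg$tasks, check_task, character(1), USE.NAMES = FALSE)
  cfg
}

config_hash <- function(config) {
  digest_string(paste(deparse(config[order(names(config))]), collapse = ""))
}
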