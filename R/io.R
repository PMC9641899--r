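trial_cols <- c("subject", "session", "block", "trial", "group_range_deg",
                "stimulus_deg", "response_deg")

#' Read a trial table from CSV
#'
#' Expects the columns `subject, session, block, trial, group_range_deg,
#' stimulus_deg, response_deg` (plus optional `error_deg`, `excluded`).
#' Directions are validated to lie in \[0, 360); errors are recomputed as
#' the wrapped response-minus-stimulus difference; rows are sorted by
#' subject, block, trial.
#'
#' @param path Path to a CSV file.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(trial_cols, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("stimulus_deg", "response_deg")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] >= 360)
    if (length(bad) > 0) {
      stop(sprintf("%s out of [0, 360) at data row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  dup <- df |>
    dplyr::count(.data$subject, .data$session, .data$block, .data$trial) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated trial index within (subject, session, block)",
         call. = FALSE)
  }
  df$error_deg <- circ_dist(df$response_deg, df$stimulus_deg)
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  dplyr::arrange(df, .data$subject, .data$block, .data$trial)
}

#' Write a trial table to CSV
#'
#' @param trials Trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(dplyr::select(
    trials, dplyr::any_of(c(trial_cols, "error_deg", "excluded"))
  ), path)
  invisible(path)
}

#' Run the standard analysis pipeline
#'
#' Correct idiosyncratic cardinal bias, apply the exclusion cascade, fit the
#' requested descriptive models, compare them by AIC when more than one is
#' fitted, and build the joint bias map. When `out_dir` is given, writes the
#' corrected trials, population-parameter summaries, comparison table and
#' map as CSV plus a JSON summary; file names carry the seed and a hash of
#' the configuration.
#'
#' @param trials Raw trial tibble (e.g. from [read_trials()] or
#'   [simulate_cohort()]).
#' @param models Character vector of model kinds to fit (see
#'   [bias_model()]).
#' @param correction `"gp"`, `"sinusoid"`, `"polynomial"` or `"none"`.
#' @param control An [mcmc_control()].
#' @param min_subjects Cell threshold passed to [joint_bias_map()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return A list with `trials`, `fits`, `summaries`, `comparison`, `map`,
#'   `report`.
#' @export
run_pipeline <- function(trials, models = "stim_resp", correction = "gp",
                         control = mcmc_control(), min_subjects = 2,
                         seed = 1, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  corrected <- stage("correct", {
    if (correction == "none") trials
    else correct_trials(trials, fit_cardinal(trials, correction))
  })
  cleaned <- stage("exclude", exclude_outliers(corrected))
  report <- exclusion_report(cleaned)
  fits <- stage("fit", {
    out <- lapply(models, function(m) {
      fit_bias_model(cleaned, bias_model(m), control = control, seed = seed)
    })
    names(out) <- models
    out
  })
  summaries <- lapply(fits, summarize_posterior)
  comparison <- if (length(fits) >= 2) {
    stage("compare", withr::with_seed(seed + 1L, compare_models(fits)))
  } else {
    NULL
  }
  map <- stage("map", joint_bias_map(cleaned, min_subjects = min_subjects))

  result <- list(trials = cleaned, fits = fits, summaries = summaries,
                 comparison = comparison, map = map, report = report,
                 seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_hash <- substr(rlang::hash(list(models, correction,
                                        unclass(control), seed)), 1, 8)
    tag <- sprintf("%s_seed%d", cfg_hash, seed)
    write_trials(cleaned, file.path(out_dir, sprintf("trials_%s.csv", tag)))
    for (m in names(summaries)) {
      readr::write_csv(summaries[[m]],
                       file.path(out_dir, sprintf("posterior_%s_%s.csv", m, tag)))
    }
    if (!is.null(comparison)) {
      readr::write_csv(comparison,
                       file.path(out_dir, sprintf("aic_%s.csv", tag)))
    }
    readr::write_csv(tibble::as_tibble(map),
                     file.path(out_dir, sprintf("joint_map_%s.csv", tag)))
    summary_json <- list(
      seed = seed, config_hash = cfg_hash, exclusion = as.list(report),
      population = lapply(summaries, function(s) {
        stats::setNames(as.list(s$mode), s$parameter)
      })
    )
    jsonlite::write_json(summary_json,
                         file.path(out_dir, sprintf("summary_%s.json", tag)),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
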