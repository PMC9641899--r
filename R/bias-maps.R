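offset_col <- function(predictor) {
  switch(predictor,
    prev_stimulus = "prev_stim_offset",
    prev_response = "prev_resp_offset",
    stop("unknown predictor: ", predictor, call. = FALSE)
  )
}

# bin index on (-180, 180] with half-open [lo, hi) bins, 180 closed into the
# last bin
bin_index <- function(x, bin) {
  nb <- 360L %/% bin
  pmin(floor((x + 180) / bin), nb - 1L)
}

#' Marginal sliding-window bias curve
#'
#' For each subject, the mean signed error within a sliding circular window
#' of the wrapped offset of the previous stimulus (or response) from the
#' current stimulus; windows with fewer than `min_trials` trials for a
#' subject are dropped for that subject. The group curve is the
#' across-subject mean with a t-based confidence interval.
#'
#' @param trials Trial tibble (corrected/excluded as desired); only eligible
#'   trials enter.
#' @param predictor `"prev_stimulus"` or `"prev_response"`.
#' @param window Window width in degrees (default 10).
#' @param step Step size in degrees (default 1; must divide `window`).
#' @param min_trials Minimum trials per subject per window (default 10).
#' @param conf Confidence level for the across-subject interval.
#' @return A tibble of class `sb_bias_curve` with `center`, `mean_error`,
#'   `ci_low`, `ci_high`, `n_subjects`.
#' @export
bias_curve <- function(trials, predictor = c("prev_stimulus", "prev_response"),
                       window = 10, step = 1, min_trials = 10, conf = 0.95) {
  predictor <- match.arg(predictor)
  stopifnot(window %% step == 0, 360 %% step == 0)
  el <- eligible_trials(trials)
  if (nrow(el) == 0) stop("no eligible trials", call. = FALSE)
  col <- offset_col(predictor)
  nb <- 360L %/% step
  m <- as.integer(window %/% step) # bins per window

  per_subject <- el |>
    dplyr::mutate(.bin = bin_index(.data[[col]], step)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      sums <- counts <- numeric(nb)
      agg_s <- tapply(df$error_deg, df$.bin, sum)
      agg_n <- tapply(df$error_deg, df$.bin, length)
      idx <- as.integer(names(agg_s)) + 1L
      sums[idx] <- agg_s
      counts[idx] <- agg_n
      # circular rolling window of m consecutive bins
      cs <- cumsum(c(0, rep(sums, 2)))
      cn <- cumsum(c(0, rep(counts, 2)))
      k <- seq_len(nb)
      wsum <- cs[k + m] - cs[k]
      wn <- cn[k + m] - cn[k]
      center <- wrap_signed(-180 + (k - 1) * step + (m / 2) * step)
      tibble::tibble(center = center, n = wn,
                     mean = ifelse(wn >= min_trials, wsum / wn, NA_real_))
    }) |>
    dplyr::ungroup()

  grp <- per_subject |>
    dplyr::filter(!is.na(.data$mean)) |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(
      mean_error = mean(.data$mean),
      sem = stats::sd(.data$mean) / sqrt(dplyr::n()),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tcrit = ifelse(.data$n_subjects > 1,
                     stats::qt(1 - (1 - conf) / 2, .data$n_subjects - 1), NA),
      ci_low = .data$mean_error - .data$tcrit * .data$sem,
      ci_high = .data$mean_error + .data$tcrit * .data$sem
    ) |>
    dplyr::select("center", "mean_error", "ci_low", "ci_high", "n_subjects") |>
    dplyr::arrange(.data$center)
  if (nrow(grp) == 0) stop("all windows empty below `min_trials`", call. = FALSE)
  attr(grp, "per_subject") <- per_subject
  attr(grp, "predictor") <- predictor
  class(grp) <- c("sb_bias_curve", class(grp))
  grp
}

#' Joint bias map over previous-stimulus and previous-response offsets
#'
#' Bins each subject's signed errors into a 2-d grid of (previous stimulus -
#' current stimulus) by (previous response - current stimulus) offsets, then
#' averages the per-subject cell means across subjects. Cells to which fewer
#' than `min_subjects` subjects contribute are masked (`NA`).
#'
#' @param trials Trial tibble.
#' @param bin Bin width in degrees (must divide 360).
#' @param min_subjects Minimum subjects per cell for a group mean.
#' @return A tibble of class `sb_joint_map` with `prev_stim_center`,
#'   `prev_resp_center`, `mean_error`, `n_subjects`.
#' @export
joint_bias_map <- function(trials, bin = 10, min_subjects = 14) {
  if (360 %% bin != 0) stop("`bin` must divide 360", call. = FALSE)
  el <- eligible_trials(trials)
  n_subj <- length(unique(el$subject))
  if (n_subj < min_subjects) {
    stop("fewer than `min_subjects` subjects in the data", call. = FALSE)
  }
  by_subject <- el |>
    dplyr::mutate(
      xb = bin_index(.data$prev_stim_offset, bin),
      yb = bin_index(.data$prev_resp_offset, bin)
    ) |>
    dplyr::group_by(.data$subject, .data$xb, .data$yb) |>
    dplyr::summarise(mean = mean(.data$error_deg), n = dplyr::n(),
                     .groups = "drop")
  grp <- by_subject |>
    dplyr::group_by(.data$xb, .data$yb) |>
    dplyr::summarise(
      mean_error = mean(.data$mean), n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_error = ifelse(.data$n_subjects >= min_subjects,
                          .data$mean_error, NA_real_),
      prev_stim_center = -180 + (.data$xb + 0.5) * bin,
      prev_resp_center = -180 + (.data$yb + 0.5) * bin
    ) |>
    dplyr::select("prev_stim_center", "prev_resp_center", "mean_error",
                  "n_subjects")
  attr(grp, "by_subject") <- dplyr::mutate(
    by_subject,
    prev_stim_center = -180 + (.data$xb + 0.5) * bin,
    prev_resp_center = -180 + (.data$yb + 0.5) * bin
  )
  attr(grp, "bin") <- bin
  class(grp) <- c("sb_joint_map", class(grp))
  grp
}

#' Conditional bias curves
#'
#' Splits errors by 10-degree bins of one history offset and plots them
#' against bins of the other: negative slopes against the previous-stimulus
#' offset reveal repulsion; positive slopes against the previous-response
#' offset reveal attraction. Per-subject cell means require `min_trials`
#' trials; group means require `min_subjects` subjects.
#'
#' @param trials Trial tibble.
#' @param condition_on `"prev_response"` or `"prev_stimulus"` (the variable
#'   held fixed within each line).
#' @param bin Bin width in degrees.
#' @param min_trials Minimum trials per subject per cell.
#' @param min_subjects Minimum subjects per group mean.
#' @param conf Confidence level.
#' @return A tibble of class `sb_cond_curves` with `cond_center`,
#'   `x_center`, `mean_error`, `ci_low`, `ci_high`, `n_subjects`.
#' @export
conditional_bias_curves <- function(trials,
                                    condition_on = c("prev_response",
                                                     "prev_stimulus"),
                                    bin = 10, min_trials = 5,
                                    min_subjects = 14, conf = 0.95) {
  condition_on <- match.arg(condition_on)
  el <- eligible_trials(trials)
  cond_col <- offset_col(condition_on)
  x_col <- if (condition_on == "prev_response") {
    "prev_stim_offset"
  } else {
    "prev_resp_offset"
  }
  grp <- el |>
    dplyr::mutate(
      cb = bin_index(.data[[cond_col]], bin),
      xb = bin_index(.data[[x_col]], bin)
    ) |>
    dplyr::group_by(.data$subject, .data$cb, .data$xb) |>
    dplyr::summarise(mean = mean(.data$error_deg), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_trials) |>
    dplyr::group_by(.data$cb, .data$xb) |>
    dplyr::summarise(
      mean_error = mean(.data$mean),
      sem = stats::sd(.data$mean) / sqrt(dplyr::n()),
      n_subjects = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_subjects >= min_subjects) |>
    dplyr::mutate(
      tcrit = stats::qt(1 - (1 - conf) / 2, .data$n_subjects - 1),
      ci_low = .data$mean_error - .data$tcrit * .data$sem,
      ci_high = .data$mean_error + .data$tcrit * .data$sem,
      cond_center = -180 + (.data$cb + 0.5) * bin,
      x_center = -180 + (.data$xb + 0.5) * bin
    ) |>
    dplyr::select("cond_center", "x_center", "mean_error", "ci_low",
                  "ci_high", "n_subjects")
  attr(grp, "condition_on") <- condition_on
  class(grp) <- c("sb_cond_curves", class(grp))
  grp
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.sb_bias_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center, y = .data$mean_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = paste("relative direction of", attr(object, "predictor"), "(deg)"),
      y = "response error (deg)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sb_joint_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$prev_stim_center,
                               y = .data$prev_resp_center,
                               fill = .data$mean_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  na.value = "grey85", name = "error (deg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "previous stimulus - current stimulus (deg)",
                  y = "previous response - current stimulus (deg)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sb_cond_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x_center, y = .data$mean_error,
                               colour = factor(.data$cond_center),
                               group = .data$cond_center)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(colour = paste(attr(object, "condition_on"), "bin (deg)"),
                  x = "offset of the other predictor (deg)",
                  y = "response error (deg)") +
    ggplot2::theme_minimal()
}

#' Gradients of a joint bias map near the origin
#'
#' Linear regression of unmasked cell means on the two bin centres within
#' `extent` degrees of the origin; the previous-stimulus slope is negative
#' and the previous-response slope positive when repulsion from the previous
#' stimulus and attraction toward the previous response coexist.
#'
#' @param map An `sb_joint_map`.
#' @param extent Half-width of the central region in degrees (default 40).
#' @return A one-row tibble with `slope_prev_stim`, `slope_prev_resp`.
#' @export
joint_map_gradients <- function(map, extent = 40) {
  df <- dplyr::filter(
    tibble::as_tibble(map),
    !is.na(.data$mean_error),
    abs(.data$prev_stim_center) <= extent,
    abs(.data$prev_resp_center) <= extent
  )
  fit <- stats::lm(mean_error ~ prev_stim_center + prev_resp_center, data = df)
  tibble::tibble(
    slope_prev_stim = stats::coef(fit)[["prev_stim_center"]],
    slope_prev_resp = stats::coef(fit)[["prev_resp_center"]]
  )
}
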