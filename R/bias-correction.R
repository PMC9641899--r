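#' Fit the sinusoidal cardinal-bias model to one subject
#'
#' Least-squares fit of
#' `y = beta0 + a sgn(x) (sin(4|x| - asin(v)) + v)` with `x` the stimulus
#' direction relative to the vertical axis and `v` constrained to \[-1, 1\].
#'
#' @param stimulus Stimulus directions in degrees.
#' @param error Signed response errors in degrees.
#' @return An object of class `sb_card_sin` with `beta0`, `a`, `v`, `rms`
#'   and a `converged` flag.
#' @export
fit_cardinal_sinusoid <- function(stimulus, error) {
  if (length(stimulus) < 10) stop("need at least 10 trials", call. = FALSE)
  obj <- function(p) {
    pred <- cardinal_bias(stimulus, list(beta0 = p[1], a = p[2],
                                         v = max(-1, min(1, p[3]))))
    sum((error - pred)^2)
  }
  best <- NULL
  for (a0 in c(-2, 0.5, 2)) {
    res <- stats::optim(c(mean(error), a0, 0), obj, method = "L-BFGS-B",
                        lower = c(-45, -45, -1), upper = c(45, 45, 1))
    if (is.null(best) || res$value < best$value) best <- res
  }
  structure(
    list(beta0 = best$par[1], a = best$par[2], v = best$par[3],
         rms = sqrt(best$value / length(error)),
         converged = best$convergence == 0),
    class = c("sb_card_sin", "sb_card_fit")
  )
}

#' @export
predict.sb_card_sin <- function(object, stimulus, ...) {
  cardinal_bias(stimulus, object)
}

#' Fit a polynomial cardinal-bias model to one subject
#'
#' Least-squares polynomial (orthogonal basis) of the stimulus direction;
#' degree 10 by default.
#'
#' @param stimulus Stimulus directions in degrees.
#' @param error Signed response errors in degrees.
#' @param degree Polynomial degree.
#' @return An object of class `sb_card_poly`.
#' @export
fit_cardinal_polynomial <- function(stimulus, error, degree = 10) {
  if (length(stimulus) < degree + 2) stop("too few trials for degree", call. = FALSE)
  fitlm <- stats::lm(error ~ stats::poly(stimulus, degree))
  structure(
    list(lm = fitlm, degree = degree,
         rms = sqrt(mean(stats::residuals(fitlm)^2))),
    class = c("sb_card_poly", "sb_card_fit")
  )
}

#' @export
predict.sb_card_poly <- function(object, stimulus, ...) {
  unname(stats::predict(object$lm, newdata = data.frame(stimulus = stimulus)))
}

# squared-exponential kernel on wrapped (shortest-arc) angular distance
gp_kernel <- function(x1, x2, sigma_f, sigma_l) {
  d <- wrap_signed(outer(x1, x2, "-"))
  sigma_f^2 * exp(-d^2 / (2 * sigma_l^2))
}

chol_jitter <- function(K, sigma_f) {
  for (j in c(0, 1e-8, 1e-7, 1e-6)) {
    ch <- tryCatch(chol(K + diag(j * sigma_f^2, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("kernel matrix not positive definite even with jitter", call. = FALSE)
}

#' Fit a Gaussian-process cardinal-bias model to one subject
#'
#' Nonparametric regression of response error on stimulus direction:
#' `y = beta0 + f(x)` with `f ~ Normal(0, K)` and a squared-exponential
#' kernel evaluated on the wrapped angular distance (so the fitted bias
#' function is continuous across 0/360). An observation-noise SD `sigma_n`
#' is included; the hyperparameters (`sigma_f`, `sigma_l`, `sigma_n`) are
#' set by maximising the marginal likelihood on the log scale and the
#' constant `beta0` is profiled out by generalised least squares.
#'
#' @param stimulus Stimulus directions in degrees (at least 20 trials).
#' @param error Signed response errors in degrees.
#' @return An object of class `sb_card_gp` with hyperparameters, the
#'   training set, and the precomputed weight vector for prediction.
#' @export
fit_cardinal_gp <- function(stimulus, error) {
  n <- length(stimulus)
  if (n < 20) stop("need at least 20 trials", call. = FALSE)
  nll <- function(lp) {
    sigma_f <- exp(lp[1]); sigma_l <- exp(lp[2]); sigma_n <- exp(lp[3])
    K <- gp_kernel(stimulus, stimulus, sigma_f, sigma_l) + diag(sigma_n^2, n)
    ch <- tryCatch(chol_jitter(K, sigma_f), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Kinv_y <- backsolve(ch, forwardsolve(t(ch), error))
    Kinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    beta0 <- sum(Kinv_y) / sum(Kinv_1)
    r <- error - beta0
    Kinv_r <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * sum(r * Kinv_r) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  s0 <- max(stats::sd(error), 0.5)
  opt <- stats::optim(log(c(s0, 30, s0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-7))
  sigma_f <- exp(opt$par[1]); sigma_l <- exp(opt$par[2]); sigma_n <- exp(opt$par[3])
  K <- gp_kernel(stimulus, stimulus, sigma_f, sigma_l) + diag(sigma_n^2, n)
  ch <- chol_jitter(K, sigma_f)
  Kinv_y <- backsolve(ch, forwardsolve(t(ch), error))
  Kinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  beta0 <- sum(Kinv_y) / sum(Kinv_1)
  alpha <- backsolve(ch, forwardsolve(t(ch), error - beta0))
  pred_train <- beta0 + as.vector(gp_kernel(stimulus, stimulus, sigma_f, sigma_l) %*% alpha)
  structure(
    list(beta0 = beta0, sigma_f = sigma_f, sigma_l = sigma_l, sigma_n = sigma_n,
         x = stimulus, alpha = alpha,
         rms = sqrt(mean((error - pred_train)^2)),
         marginal_nll = opt$value),
    class = c("sb_card_gp", "sb_card_fit")
  )
}

#' @export
predict.sb_card_gp <- function(object, stimulus, ...) {
  ks <- gp_kernel(stimulus, object$x, object$sigma_f, object$sigma_l)
  object$beta0 + as.vector(ks %*% object$alpha)
}

#' Fit a cardinal-bias model per subject
#'
#' @param trials Trial tibble with `subject`, `stimulus_deg`, `error_deg`.
#' @param model `"gp"`, `"sinusoid"` or `"polynomial"`.
#' @param z Outliers beyond `z` SD of each subject's mean error are dropped
#'   before fitting (the fit itself should not chase lapses).
#' @return A named list of per-subject fits (class `sb_cardinal_set`).
#' @export
fit_cardinal <- function(trials, model = c("gp", "sinusoid", "polynomial"),
                         z = 2.5) {
  model <- match.arg(model)
  fits <- lapply(split(trials, trials$subject), function(df) {
    keep <- abs(df$error_deg - mean(df$error_deg)) <=
      z * max(stats::sd(df$error_deg), .Machine$double.eps)
    x <- df$stimulus_deg[keep]
    y <- df$error_deg[keep]
    switch(model,
      gp = fit_cardinal_gp(x, y),
      sinusoid = fit_cardinal_sinusoid(x, y),
      polynomial = fit_cardinal_polynomial(x, y)
    )
  })
  structure(fits, class = "sb_cardinal_set", model = model)
}

#' Subtract the fitted cardinal bias from errors and responses
#'
#' @param trials Trial tibble.
#' @param fits A `sb_cardinal_set` from [fit_cardinal()] (one fit per
#'   subject present in `trials`).
#' @return The tibble with `error_deg` and `response_deg` replaced by their
#'   residual (bias-subtracted, re-wrapped) values.
#' @export
correct_trials <- function(trials, fits) {
  missing <- setdiff(as.character(unique(trials$subject)), names(fits))
  if (length(missing) > 0) {
    stop("no cardinal fit for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      bias <- stats::predict(fits[[as.character(key$subject)]], df$stimulus_deg)
      df$error_deg <- wrap_signed(df$error_deg - bias)
      df$response_deg <- wrap_360(df$response_deg - bias)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(names(trials)))
}

#' Compare cardinal-bias correction models by residual RMS
#'
#' @param trials Trial tibble.
#' @param models Which correction models to fit.
#' @return A tibble with `subject`, `model`, `rms`.
#' @export
compare_corrections <- function(trials,
                                models = c("gp", "sinusoid", "polynomial")) {
  purrr::map_dfr(models, function(m) {
    fits <- fit_cardinal(trials, m)
    tibble::tibble(
      subject = names(fits),
      model = m,
      rms = vapply(fits, function(f) f$rms, 0)
    )
  })
}

#' Flag first-of-block trials, outliers, and their successors
#'
#' Marks as excluded (i) the first trial of every block (no predecessor to
#' induce a sequential effect), (ii) trials whose error is more than `z`
#' SD from the subject's mean error, and (iii) the trial immediately
#' following each outlier, whose perception could have been affected by the
#' outlying trial.
#'
#' @param trials Trial tibble with `error_deg`.
#' @param z SD multiplier for the outlier rule (default 2.5).
#' @return The tibble with an `excluded` logical column (overwritten if
#'   present).
#' @export
exclude_outliers <- function(trials, z = 2.5) {
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  trials |>
    dplyr::arrange(.data$subject, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(
      .sd = stats::sd(.data$error_deg),
      .out = .data$.sd > 0 & !is.na(.data$.sd) &
        abs(.data$error_deg - mean(.data$error_deg)) > z * .data$.sd
    ) |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::mutate(
      .first = .data$trial == min(.data$trial),
      .after_out = dplyr::lag(.data$.out, default = FALSE),
      excluded = .data$.first | .data$.out | .data$.after_out
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".sd", -".out", -".first", -".after_out")
}

#' Exclusion report
#'
#' @param trials Trial tibble after [exclude_outliers()].
#' @return One-row tibble: totals and the fraction excluded by the outlier
#'   cascade (first-of-block trials counted separately).
#' @export
exclusion_report <- function(trials) {
  first <- trials |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::summarise(n_first = 1, .groups = "drop")
  n_first <- nrow(first)
  n_total <- nrow(trials)
  n_excl <- sum(trials$excluded)
  tibble::tibble(
    n_trials = n_total,
    n_first = n_first,
    n_outlier_cascade = n_excl - n_first,
    frac_outlier = (n_excl - n_first) / n_total,
    frac_excluded = n_excl / n_total
  )
}

#' Maximum-likelihood DoG fit for one error curve
#'
#' Fits amplitude, peak location and von Mises noise SD of a single DoG bias
#' curve to (offset, error) pairs by direct likelihood maximisation. Used by
#' the shuffle control and for quick marginal-curve quantification.
#'
#' @param offset Wrapped signed offsets in degrees.
#' @param error Signed errors in degrees.
#' @return A tibble with `a`, `l`, `sigma`, `loglik`.
#' @export
fit_dog_curve <- function(offset, error) {
  nll <- function(p) {
    -sum(vonmises_logpdf(error, dog(offset, p[1], p[2]), p[3]))
  }
  s0 <- min(max(stats::sd(error), 2), 60)
  best <- NULL
  for (a0 in c(-3, 0, 3)) {
    res <- stats::optim(c(a0, 25, s0), nll, method = "L-BFGS-B",
                        lower = c(-60, 5, 0.5), upper = c(60, 120, 90))
    if (is.null(best) || res$value < best$value) best <- res
  }
  tibble::tibble(a = best$par[1], l = best$par[2], sigma = best$par[3],
                 loglik = -best$value)
}

#' Shuffle control for the cardinal-bias correction
#'
#' Shuffles the trial order within each block (stimulus-response pairs stay
#' together), which destroys genuine sequential effects, and refits the
#' Response-model DoG amplitude per subject. Any nonzero amplitude that
#' survives shuffling is an artifact of the stimulus-dependent estimation
#' bias; after cardinal correction the artifact should vanish.
#'
#' @param trials Trial tibble (uncorrected).
#' @param with_correction If `TRUE`, apply a per-subject GP cardinal
#'   correction before shuffling.
#' @param n_shuffles Number of independent shuffles (at least 1).
#' @param seed Optional integer seed.
#' @return A tibble with `subject`, `shuffle`, `amplitude` (degrees).
#' @export
shuffle_control <- function(trials, with_correction = FALSE, n_shuffles = 1,
                            seed = NULL) {
  if (n_shuffles < 1) stop("`n_shuffles` must be at least 1", call. = FALSE)
  if (with_correction) {
    trials <- correct_trials(trials, fit_cardinal(trials, "gp"))
  }
  run <- function() {
    purrr::map_dfr(seq_len(n_shuffles), function(k) {
      shuffled <- trials |>
        dplyr::group_by(.data$subject, .data$block) |>
        dplyr::group_modify(function(df, key) {
          df <- df[sample.int(nrow(df)), ]
          df$trial <- seq_len(nrow(df))
          df
        }) |>
        dplyr::ungroup()
      el <- eligible_trials(dplyr::mutate(add_history(shuffled), excluded = FALSE))
      el |>
        dplyr::group_by(.data$subject) |>
        dplyr::group_modify(function(df, key) {
          fit_dog_curve(df$prev_resp_offset, df$error_deg)[, "a"]
        }) |>
        dplyr::ungroup() |>
        dplyr::transmute(subject = .data$subject, shuffle = k,
                         amplitude = .data$a)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
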