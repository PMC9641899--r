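#' First derivative of a Gaussian (DoG) bias curve
#'
#' `y = x a w c exp(-(w x)^2)` with `w = 1/(sqrt(2) l)` and the constant
#' `c = sqrt(2) exp(0.5)` chosen so the curve is odd, peaks exactly at
#' `x = l`, and the peak value equals the amplitude `a`.
#'
#' @param x Offsets in degrees (signed, wrapped).
#' @param a Amplitude in degrees; the signed height of the peak.
#' @param l Peak location in degrees, positive.
#' @return Bias values in degrees.
#' @examples
#' dog(30, a = 1, l = 30) # exactly 1
#' @export
dog <- function(x, a, l) {
  if (any(l <= 0)) stop("`l` must be positive", call. = FALSE)
  w <- 1 / (sqrt(2) * l)
  cc <- sqrt(2) * exp(0.5)
  x * a * w * cc * exp(-(w * x)^2)
}

#' Descriptive bias-model specification
#'
#' Four nested descriptions of the trial-level mean error:
#' * `"stimulus"`: one DoG of the previous-stimulus offset (params a, l, sigma).
#' * `"response"`: one DoG of the previous-response offset (a, l, sigma).
#' * `"stim_resp"`: sum of two independent DoGs, one per offset
#'   (a_stim, l_stim, a_resp, l_resp, sigma).
#' * `"attr_rep"`: sum of an attractive (amplitude > 0) and a repulsive
#'   (amplitude < 0) DoG whose centres are free mixtures
#'   `beta * Response[t-1] + (1 - beta) * Stimulus[t-1]`
#'   (a_att, l_att, beta_att, a_rep, l_rep, beta_rep, sigma).
#'
#' @param kind One of `"stimulus"`, `"response"`, `"stim_resp"`, `"attr_rep"`.
#' @return An object of class `sb_model` holding the parameter layout.
#' @export
bias_model <- function(kind = c("stim_resp", "stimulus", "response", "attr_rep")) {
  kind <- match.arg(kind)
  par <- switch(kind,
    stimulus = tibble::tibble(
      name = c("a", "l", "sigma"), type = c("a", "l", "s"),
      init = c(0, 30, 10), lower = c(-Inf, 0, 0), upper = c(Inf, Inf, Inf)
    ),
    response = tibble::tibble(
      name = c("a", "l", "sigma"), type = c("a", "l", "s"),
      init = c(0, 30, 10), lower = c(-Inf, 0, 0), upper = c(Inf, Inf, Inf)
    ),
    stim_resp = tibble::tibble(
      name = c("a_stim", "l_stim", "a_resp", "l_resp", "sigma"),
      type = c("a", "l", "a", "l", "s"),
      init = c(0, 30, 0, 30, 10),
      lower = c(-Inf, 0, -Inf, 0, 0), upper = c(Inf, Inf, Inf, Inf, Inf)
    ),
    attr_rep = tibble::tibble(
      name = c("a_att", "l_att", "beta_att", "a_rep", "l_rep", "beta_rep", "sigma"),
      type = c("a", "l", "b", "a", "l", "b", "s"),
      init = c(5, 30, 0.5, -5, 30, 0.5, 10),
      lower = c(0, 0, -Inf, -Inf, 0, -Inf, 0),
      upper = c(Inf, Inf, Inf, 0, Inf, Inf, Inf)
    )
  )
  structure(list(kind = kind, params = par, k = nrow(par)), class = "sb_model")
}

#' @export
print.sb_model <- function(x, ...) {
  cat("<sb_model>", x$kind, "-", x$k, "parameters:",
      paste(x$params$name, collapse = ", "), "\n")
  invisible(x)
}

#' Model-predicted mean error for given history
#'
#' Evaluates the trial-level mean of the error distribution under a
#' descriptive model. All offsets are wrapped to (-180, 180].
#'
#' @param prev_stim,prev_resp,cur_stim Directions in degrees (vectors).
#' @param params Named numeric vector matching the model's parameter layout.
#' @param model An [bias_model()] object.
#' @return Predicted signed errors in degrees.
#' @export
model_mean <- function(prev_stim, prev_resp, cur_stim, params, model) {
  if (any(is.na(prev_stim)) || any(is.na(prev_resp))) {
    stop("history predictors contain missing values (first-of-block trials?)",
         call. = FALSE)
  }
  xs <- circ_dist(prev_stim, cur_stim)
  xr <- circ_dist(prev_resp, cur_stim)
  p <- as.list(params)
  switch(model$kind,
    stimulus = dog(xs, p$a, p$l),
    response = dog(xr, p$a, p$l),
    stim_resp = dog(xs, p$a_stim, p$l_stim) + dog(xr, p$a_resp, p$l_resp),
    attr_rep = {
      d <- circ_dist(prev_resp, prev_stim)
      x_att <- wrap_signed(xs + p$beta_att * d)
      x_rep <- wrap_signed(xs + p$beta_rep * d)
      dog(x_att, p$a_att, p$l_att) + dog(x_rep, p$a_rep, p$l_rep)
    }
  )
}

#' Per-subject log-likelihood of a descriptive model
#'
#' Sum over eligible trials (those with a non-excluded immediate predecessor
#' in the same block) of the von Mises log-density of the observed error
#' around the model-predicted mean.
#'
#' @param params Named parameter vector (must include `sigma`).
#' @param trials A trial tibble for one subject, with history columns (added
#'   if absent) and optionally an `excluded` flag.
#' @param model An [bias_model()] object.
#' @return Scalar log-likelihood; `-Inf` when `sigma <= 0`.
#' @export
loglik_subject <- function(params, trials, model) {
  sigma <- params[["sigma"]]
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  el <- eligible_trials(trials)
  mu <- model_mean(el$prev_stim_deg, el$prev_resp_deg, el$stimulus_deg,
                   params, model)
  sum(vonmises_logpdf(el$error_deg, mu, sigma))
}

# trials usable by the sequential likelihood: predecessor present & kept
eligible_trials <- function(trials) {
  if (!"prev_stim_offset" %in% names(trials)) trials <- add_history(trials)
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE
  trials |>
    dplyr::arrange(.data$subject, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::mutate(.prev_kept = dplyr::lag(!.data$excluded, default = FALSE)) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$excluded, .data$.prev_kept,
                  !is.na(.data$prev_stim_offset)) |>
    dplyr::select(-".prev_kept")
}

#' Hierarchical priors for the descriptive models
#'
#' Population means get broad priors: flat for amplitudes (restricted to the
#' positive/negative half-line for the attractive/repulsive amplitudes of the
#' attraction-and-repulsion model), Normal(5, 90^2) for peak locations, flat
#' for the noise SD, and Normal(0.5, 0.5^2) for centre mixtures so that
#' neither previous stimulus nor previous response is favoured. Population
#' SDs get Gamma priors whose mode is half, and SD twice, the assumed
#' between-subject SD (1 degree for amplitudes, 5 for peak locations, 2 for
#' noise SDs, 0.15 for centre mixtures), which makes them vague on the scale
#' of the data. Individual-level amplitudes, peak locations and noise SDs
#' follow von Mises population distributions on the degree scale with
#' concentration `1/sd_rad^2` (numerically wrapped-normal at these scales);
#' centre mixtures follow Gaussians.
#'
#' @param sd_a,sd_l,sd_sigma,sd_beta Assumed between-subject SDs used to set
#'   the Gamma hyper-priors.
#' @return A list of class `sb_priors` with per-type hyper-prior parameters.
#' @export
hier_priors <- function(sd_a = 1, sd_l = 5, sd_sigma = 2, sd_beta = 0.15) {
  gam <- function(sd0) {
    # mode m = sd0/2, sd v = 2*sd0 => v/m = 4; solve mode=(s-1)/r, sd=sqrt(s)/r
    m <- sd0 / 2
    s <- (33 + sqrt(65)) / 32
    r <- (s - 1) / m
    c(shape = s, rate = r)
  }
  structure(
    list(
      assumed_sd = c(a = sd_a, l = sd_l, s = sd_sigma, b = sd_beta),
      gamma = list(a = gam(sd_a), l = gam(sd_l), s = gam(sd_sigma), b = gam(sd_beta)),
      mu_l = c(mean = 5, sd = 90),
      mu_beta = c(mean = 0.5, sd = 0.5)
    ),
    class = "sb_priors"
  )
}
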