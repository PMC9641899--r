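#' Configuration of the encoder-decoder observer
#'
#' The observer encodes each motion direction in a population of `n_neurons`
#' direction-selective neurons with von Mises tuning and independent Poisson
#' spike-count variability, adapts the gains of neurons tuned near the
#' previous trial's adapter, and decodes by recursive Bayesian inference on
#' a uniform direction grid: the previous posterior is convolved with a
#' propagation-noise kernel (von Mises + uniform mixture) to form the prior,
#' which is combined with the new likelihood; the reported estimate is the
#' posterior mean.
#'
#' @param n_neurons Number of sensory neurons (default 20), preferred
#'   directions equally spaced on \[0, 360).
#' @param g0 Baseline response gain (default 4).
#' @param kappa_tuning Tuning concentration (default the value matching a
#'   30-degree Gaussian SD, about 3.65).
#' @param alpha_adapt Maximal fractional gain suppression, in \[0, 1).
#' @param kappa_adapt Concentration of the suppression profile.
#' @param p_same Mixture weight of the von Mises component of the
#'   propagation kernel.
#' @param kappa_prop Concentration of the propagation kernel.
#' @param grid_step Grid resolution in degrees (must divide 360).
#' @param adaptation `"stimulus"` (gain reduction around the previous
#'   stimulus direction) or `"spike_count"` (per-neuron reduction by its own
#'   previous spike count).
#' @return A list of class `sb_observer`.
#' @export
observer_config <- function(n_neurons = 20, g0 = 4,
                            kappa_tuning = kappa_from_sd_deg(30),
                            alpha_adapt = 0.35, kappa_adapt = 8.2,
                            p_same = 0.9, kappa_prop = 14.6,
                            grid_step = 1,
                            adaptation = c("stimulus", "spike_count")) {
  adaptation <- match.arg(adaptation)
  stopifnot(alpha_adapt >= 0, alpha_adapt < 1, p_same >= 0, p_same <= 1,
            360 %% grid_step == 0, n_neurons >= 2, g0 >= 0)
  structure(
    list(
      n_neurons = n_neurons, g0 = g0, kappa_tuning = kappa_tuning,
      alpha_adapt = alpha_adapt, kappa_adapt = kappa_adapt,
      p_same = p_same, kappa_prop = kappa_prop, grid_step = grid_step,
      adaptation = adaptation,
      preferred = seq(0, 360 - 360 / n_neurons, by = 360 / n_neurons)
    ),
    class = "sb_observer"
  )
}

#' Direction grid of an observer configuration
#'
#' @param config An [observer_config()].
#' @return Grid of directions in degrees, \[0, 360) at `grid_step` spacing.
#' @export
observer_grid <- function(config) {
  seq(0, 360 - config$grid_step, by = config$grid_step)
}

#' Expected spike counts of the population
#'
#' Peak-normalised von Mises tuning:
#' `rate_i = gain_i * exp(kappa * (cos(theta - theta_i) - 1))`, so the gain
#' is the expected spike count of a neuron driven at its preferred
#' direction. With the default gain of 4 the decoded estimates carry noise
#' on the order of the human root-mean-squared response error; an
#' unnormalised `exp(kappa cos)` profile would put hundreds of spikes into
#' every trial and make the likelihood so concentrated that the prior (and
#' with it the attractive serial dependence) could not shape the estimate.
#'
#' @param theta Stimulus direction in degrees (scalar).
#' @param gains Per-neuron gains (nonnegative).
#' @param config An [observer_config()].
#' @return Vector of expected counts, one per neuron.
#' @export
tuning_rates <- function(theta, gains, config) {
  if (any(gains < 0)) stop("gains must be nonnegative", call. = FALSE)
  gains *
    exp(config$kappa_tuning * (cos((theta - config$preferred) * pi / 180) - 1))
}

#' Gains after adaptation to a stimulus direction
#'
#' Peak-normalised suppression profile:
#' `g_i = g0 (1 - alpha_adapt exp(kappa_adapt (cos(theta_i - adapter) - 1)))`,
#' so the gain at the adapter is `g0 (1 - alpha_adapt)` and anti-preferred
#' neurons keep their baseline gain.
#'
#' @param adapter Adapter direction in degrees.
#' @param config An [observer_config()].
#' @return Per-neuron gains.
#' @export
adapted_gains_stimulus <- function(adapter, config) {
  supp <- exp(config$kappa_adapt *
                (cos((config$preferred - adapter) * pi / 180) - 1))
  config$g0 * (1 - config$alpha_adapt * supp)
}

#' Gains after adaptation to the previous spike counts
#'
#' `g_i = g0 / (1 + r_i)^alpha_adapt`.
#'
#' @param prev_spikes Spike counts from the previous trial (nonnegative).
#' @param config An [observer_config()].
#' @return Per-neuron gains.
#' @export
adapted_gains_spikes <- function(prev_spikes, config) {
  if (any(prev_spikes < 0)) stop("spike counts must be nonnegative", call. = FALSE)
  config$g0 / (1 + prev_spikes)^config$alpha_adapt
}

#' Sample a population spike-count vector
#'
#' @param theta Stimulus direction in degrees.
#' @param gains Per-neuron gains.
#' @param config An [observer_config()].
#' @param seed Optional integer seed.
#' @return Integer vector of Poisson spike counts.
#' @export
sample_spikes <- function(theta, gains, config, seed = NULL) {
  draw <- function() stats::rpois(config$n_neurons, tuning_rates(theta, gains, config))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# log baseline tuning over the grid: G x N matrix, and summed rates
baseline_tables <- function(config) {
  grid <- observer_grid(config)
  ang <- outer(grid, config$preferred, function(g, p) cos((g - p) * pi / 180))
  logF <- log(config$g0) + config$kappa_tuning * (ang - 1)
  list(grid = grid, logF = logF, Fsum = rowSums(exp(logF)))
}

#' Population likelihood over the direction grid
#'
#' Poisson likelihood of the observed spike vector evaluated with the
#' BASELINE (unadapted) tuning curves: the decoder is unaware of adaptation,
#' which is what shifts the average likelihood away from the adapter.
#' Returned normalised to sum 1 over the grid.
#'
#' @param spikes Spike-count vector (length `n_neurons`).
#' @param config An [observer_config()].
#' @return Probability vector over [observer_grid()].
#' @export
population_likelihood <- function(spikes, config) {
  bt <- baseline_tables(config)
  ll <- as.vector(bt$logF %*% spikes) - bt$Fsum
  p <- exp(ll - max(ll))
  p / sum(p)
}

#' Propagation-noise kernel over the grid
#'
#' Mixture `p_same * vonMises(0, kappa_prop) + (1 - p_same) * uniform`,
#' evaluated at the grid offsets and normalised to sum 1. Element 1
#' corresponds to a zero offset.
#'
#' @param config An [observer_config()].
#' @return Probability vector over grid offsets.
#' @export
propagation_kernel <- function(config) {
  delta <- observer_grid(config) * pi / 180
  dens <- config$p_same * exp(config$kappa_prop * cos(delta) -
                                log(2 * pi) - log_bessel_i0(config$kappa_prop)) +
    (1 - config$p_same) / (2 * pi)
  dens / sum(dens)
}

#' Propagate a posterior through the kernel to form the next prior
#'
#' Circular convolution on the grid (spectral method), renormalised.
#'
#' @param posterior Probability vector over the grid.
#' @param kernel Probability vector from [propagation_kernel()].
#' @return Probability vector (the predictive prior).
#' @export
predict_prior <- function(posterior, kernel) {
  if (length(posterior) != length(kernel)) {
    stop("grid mismatch between posterior and kernel", call. = FALSE)
  }
  out <- Re(stats::fft(stats::fft(posterior) * stats::fft(kernel),
                       inverse = TRUE)) / length(posterior)
  out <- pmax(out, 0)
  out / sum(out)
}

#' Combine prior and likelihood
#'
#' Pointwise product, renormalised; computed in log space to avoid
#' underflow.
#'
#' @param prior,likelihood Probability vectors over the same grid.
#' @return Posterior probability vector.
#' @export
update_posterior <- function(prior, likelihood) {
  if (length(prior) != length(likelihood)) {
    stop("grid mismatch", call. = FALSE)
  }
  lp <- log(prior) + log(likelihood)
  m <- max(lp)
  if (!is.finite(m)) stop("prior and likelihood have no common support", call. = FALSE)
  p <- exp(lp - m)
  p / sum(p)
}

#' Posterior-mean estimate (circular mean of a grid distribution)
#'
#' @param posterior Probability vector over the grid.
#' @param grid Grid directions in degrees; defaults to a uniform grid of the
#'   same length starting at 0.
#' @return Direction in degrees in \[0, 360).
#' @export
posterior_mean_estimate <- function(posterior, grid = NULL) {
  n <- length(posterior)
  if (is.null(grid)) grid <- seq(0, 360 - 360 / n, by = 360 / n)
  r <- grid * pi / 180
  s <- sum(posterior * sin(r)); cc <- sum(posterior * cos(r))
  if (sqrt(s^2 + cc^2) < 1e-12) {
    stop("resultant length is zero; mean undefined", call. = FALSE)
  }
  wrap_360(atan2(s, cc) * 180 / pi)
}

#' Simulate observer responses to a stimulus sequence
#'
#' Runs the full encoder-decoder recursion over each block: the prior and
#' adapter state reset at block boundaries (the first trial is encoded
#' without adaptation under a uniform prior); on later trials gains adapt to
#' the previous trial's stimulus or spike vector, spikes are drawn under the
#' adapted gains, the likelihood is formed with baseline tuning, the
#' previous posterior is propagated through the kernel, and the response is
#' the posterior mean (no motor noise).
#'
#' @param stimuli Trial tibble with `subject`, `block`, `trial`,
#'   `stimulus_deg` (e.g. from [simulate_stimuli()]).
#' @param config An [observer_config()].
#' @param seed Optional integer seed.
#' @return The tibble with `response_deg` and `error_deg` columns.
#' @export
simulate_observer <- function(stimuli, config = observer_config(), seed = NULL) {
  bt <- baseline_tables(config)
  kern_fft <- stats::fft(propagation_kernel(config))
  grid_r <- bt$grid * pi / 180
  sin_g <- sin(grid_r); cos_g <- cos(grid_r)
  G <- length(bt$grid)

  run <- function() {
    df <- dplyr::arrange(stimuli, .data$subject, .data$block, .data$trial)
    key <- paste(df$subject, df$block)
    new_block <- c(TRUE, key[-1] != key[-nrow(df)])
    resp <- numeric(nrow(df))
    posterior <- NULL
    prev_stim <- NA_real_
    prev_spikes <- NULL
    for (i in seq_len(nrow(df))) {
      th <- df$stimulus_deg[i]
      if (new_block[i]) {
        gains <- rep(config$g0, config$n_neurons)
        prior <- rep(1 / G, G)
      } else {
        gains <- if (config$adaptation == "stimulus") {
          adapted_gains_stimulus(prev_stim, config)
        } else {
          adapted_gains_spikes(prev_spikes, config)
        }
        prior <- Re(stats::fft(stats::fft(posterior) * kern_fft,
                               inverse = TRUE)) / G
        prior <- pmax(prior, 0)
        prior <- prior / sum(prior)
      }
      spikes <- stats::rpois(config$n_neurons,
                             tuning_rates(th, gains, config))
      ll <- as.vector(bt$logF %*% spikes) - bt$Fsum
      lp <- ll + log(prior)
      p <- exp(lp - max(lp))
      posterior <- p / sum(p)
      s <- sum(posterior * sin_g); cc <- sum(posterior * cos_g)
      resp[i] <- wrap_360(atan2(s, cc) * 180 / pi)
      prev_stim <- th
      prev_spikes <- spikes
    }
    df$response_deg <- resp
    df$error_deg <- circ_dist(resp, df$stimulus_deg)
    df
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
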