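#' MCMC settings for the hierarchical sampler
#'
#' The `"test"` preset (4 chains, 20,000 burn-in, 20,000 draws, thinning 20,
#' hence 4,000 retained samples) is a scaled-down protocol suitable for desk
#' runs; the `"full"` preset uses 4 chains of one million burn-in and one
#' million draws thinned by 1,000.
#'
#' @param chains Number of independent chains.
#' @param burn Burn-in iterations per chain (step sizes adapt here only).
#' @param draws Post-burn-in iterations per chain.
#' @param thin Keep every `thin`-th draw.
#' @param scale Optional preset, `"test"` or `"full"`; overrides
#'   `burn`/`draws`/`thin`.
#' @return A list of class `sb_mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, burn = 20000, draws = 20000, thin = 20,
                         scale = NULL) {
  if (!is.null(scale)) {
    scale <- match.arg(scale, c("test", "full"))
    if (scale == "full") {
      burn <- 1e6; draws <- 1e6; thin <- 1000
    } else {
      burn <- 20000; draws <- 20000; thin <- 20
    }
  }
  stopifnot(chains >= 1, burn >= 0, draws >= thin, thin >= 1)
  structure(list(chains = chains, burn = as.integer(burn),
                 draws = as.integer(draws), thin = as.integer(thin)),
            class = "sb_mcmc_control")
}

# per-subject data blocks for the C++ sampler
subject_blocks <- function(trials) {
  el <- eligible_trials(trials)
  ids <- sort(unique(trials$subject))
  blocks <- lapply(ids, function(s) {
    di <- el[el$subject == s, ]
    list(
      y = as.numeric(di$error_deg),
      xs = as.numeric(di$prev_stim_offset),
      xr = as.numeric(di$prev_resp_offset),
      d = as.numeric(di$resp_stim_gap)
    )
  })
  names(blocks) <- as.character(ids)
  blocks
}

# sampler metadata (prior hyper-parameters, bounds) for a model spec
sampler_meta <- function(model, priors) {
  type <- model$params$type
  code <- c(a = 0L, l = 1L, s = 2L, b = 3L)[type]
  gsh <- vapply(type, function(t) priors$gamma[[t]][["shape"]], 0)
  gra <- vapply(type, function(t) priors$gamma[[t]][["rate"]], 0)
  mumean <- ifelse(type == "l", priors$mu_l[["mean"]],
                   ifelse(type == "b", priors$mu_beta[["mean"]], 0))
  musd <- ifelse(type == "l", priors$mu_l[["sd"]],
                 ifelse(type == "b", priors$mu_beta[["sd"]], NA_real_))
  mu_lower <- rep(-Inf, model$k)
  mu_upper <- rep(Inf, model$k)
  if (model$kind == "attr_rep") {
    mu_lower[model$params$name == "a_att"] <- 0
    mu_upper[model$params$name == "a_rep"] <- 0
  }
  list(
    ptype = unname(code), gshape = gsh, grate = gra,
    mumean = mumean, musd = musd,
    lower = model$params$lower, upper = model$params$upper,
    mu_lower = mu_lower, mu_upper = mu_upper
  )
}

init_tau_for <- function(model, priors) {
  unname(priors$assumed_sd[model$params$type])
}

#' Fit a descriptive bias model by hierarchical Bayesian MCMC
#'
#' Samples the joint posterior of individual-level parameters (one set per
#' subject) and population-level means and SDs, using a componentwise
#' Metropolis-Hastings random walk. Initial values follow the standard
#' protocol for this model family: amplitude 0 (plus/minus 5 for the signed
#' amplitudes of the attraction-and-repulsion model), peak location 30, noise
#' SD 10, centre mixtures 0.5; population means start equal to the individual
#' values and population SDs at the assumed between-subject SDs.
#'
#' @param trials A trial tibble covering at least two subjects, preprocessed
#'   (history attached and exclusions flagged as needed). Only eligible
#'   trials (a non-excluded immediate predecessor in the same block) enter
#'   the likelihood.
#' @param model A [bias_model()] or its kind string.
#' @param priors A [hier_priors()] object.
#' @param control An [mcmc_control()] object.
#' @param seed Integer seed; each chain runs on an independent stream derived
#'   from it.
#' @return An object of class `sb_fit` with elements `samples` (array of
#'   draws x chains x parameters), `model`, `subjects`, `trials`, `control`,
#'   `acceptance`.
#' @export
fit_bias_model <- function(trials, model = bias_model("stim_resp"),
                           priors = hier_priors(), control = mcmc_control(),
                           seed = 1) {
  if (is.character(model)) model <- bias_model(model)
  stopifnot(inherits(model, "sb_model"), inherits(priors, "sb_priors"))
  blocks <- subject_blocks(trials)
  if (length(blocks) < 2) stop("need at least 2 subjects", call. = FALSE)
  meta <- sampler_meta(model, priors)
  code <- match(model$kind, c("stimulus", "response", "stim_resp", "attr_rep"))
  init <- model$params$init
  tau0 <- init_tau_for(model, priors)

  par_names <- c(
    as.vector(t(outer(names(blocks), model$params$name,
                      function(s, p) paste0(p, "[", s, "]")))),
    paste0("mu_", model$params$name),
    paste0("sd_", model$params$name)
  )
  n_keep <- control$draws %/% control$thin
  samples <- array(
    NA_real_,
    dim = c(n_keep, control$chains, length(par_names)),
    dimnames = list(NULL, paste0("chain", seq_len(control$chains)), par_names)
  )
  acc <- numeric(control$chains)
  for (ch in seq_len(control$chains)) {
    res <- withr::with_seed(as.integer(seed + 7919L * ch), {
      mh_chain_cpp(blocks, code, meta, init, init, tau0,
                   control$burn, control$draws, control$thin)
    })
    samples[, ch, ] <- res$draws
    acc[ch] <- res$acceptance
  }
  structure(
    list(
      samples = samples, model = model, priors = priors, control = control,
      subjects = names(blocks), trials = trials, acceptance = acc,
      seed = seed
    ),
    class = "sb_fit"
  )
}

#' @export
print.sb_fit <- function(x, ...) {
  cat("<sb_fit>", x$model$kind, "model;", length(x$subjects), "subjects;",
      dim(x$samples)[1], "draws x", dim(x$samples)[2], "chains\n")
  cat("  max Gelman-Rubin Rhat:",
      format(max(gelman_rubin(x)$rhat), digits = 4), "\n")
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter from two or more chains:
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B/n` the variance of the chain means.
#'
#' @param x An `sb_fit` or a 3-d array (draws x chains x parameters).
#' @return A tibble with `parameter` and `rhat`.
#' @export
gelman_rubin <- function(x) {
  a <- if (inherits(x, "sb_fit")) x$samples else x
  stopifnot(length(dim(a)) == 3)
  if (dim(a)[2] < 2) stop("need at least 2 chains", call. = FALSE)
  if (dim(a)[1] < 10) stop("need at least 10 draws per chain", call. = FALSE)
  n <- dim(a)[1]
  rhat <- apply(a, 3, function(m) {
    W <- mean(apply(m, 2, stats::var))
    B_over_n <- stats::var(colMeans(m))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  tibble::tibble(parameter = dimnames(a)[[3]], rhat = unname(rhat))
}

posterior_mode <- function(x) {
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Posterior summaries (mode and central credible interval)
#'
#' Pools the thinned draws across chains and reports, per parameter, the
#' kernel-density mode, mean, and central credible interval.
#'
#' @param fit An `sb_fit` object (or 3-d draws array).
#' @param pars Regular expression selecting parameters; defaults to the
#'   population-level ones.
#' @param level Credible level (default 0.95).
#' @return A tibble with `parameter`, `mode`, `mean`, `lower`, `upper`.
#' @export
summarize_posterior <- function(fit, pars = "^(mu|sd)_", level = 0.95) {
  a <- if (inherits(fit, "sb_fit")) fit$samples else fit
  keep <- grepl(pars, dimnames(a)[[3]])
  nm <- dimnames(a)[[3]][keep]
  pooled <- apply(a[, , keep, drop = FALSE], 3, c)
  if (nrow(pooled) < 100) stop("need at least 100 pooled draws", call. = FALSE)
  alpha <- (1 - level) / 2
  tibble::tibble(
    parameter = nm,
    mode = unname(apply(pooled, 2, posterior_mode)),
    mean = unname(colMeans(pooled)),
    lower = unname(apply(pooled, 2, stats::quantile, probs = alpha)),
    upper = unname(apply(pooled, 2, stats::quantile, probs = 1 - alpha))
  )
}

#' Posterior summary of a difference between two parameters
#'
#' @param fit An `sb_fit`.
#' @param par1,par2 Parameter names; the summary is of `par1 - par2` over
#'   pooled draws.
#' @param level Credible level.
#' @return One-row tibble with mode, mean and interval of the difference.
#' @export
posterior_difference <- function(fit, par1, par2, level = 0.95) {
  a <- fit$samples
  d <- c(a[, , par1]) - c(a[, , par2])
  alpha <- (1 - level) / 2
  tibble::tibble(
    parameter = paste(par1, "-", par2),
    mode = posterior_mode(d), mean = mean(d),
    lower = unname(stats::quantile(d, alpha)),
    upper = unname(stats::quantile(d, 1 - alpha))
  )
}

#' Individual-level point estimates (posterior means)
#'
#' @param fit An `sb_fit`.
#' @return A tibble with one row per subject and one column per model
#'   parameter.
#' @export
individual_estimates <- function(fit) {
  nm <- dimnames(fit$samples)[[3]]
  out <- purrr::map_dfr(fit$subjects, function(s) {
    cols <- paste0(fit$model$params$name, "[", s, "]")
    est <- vapply(cols, function(cn) mean(fit$samples[, , cn]), 0)
    names(est) <- fit$model$params$name
    dplyr::bind_cols(tibble::tibble(subject = s), tibble::as_tibble(as.list(est)))
  })
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sb_fit <- function(x, level = 0.95, ...) {
  s <- summarize_posterior(x, level = level)
  tibble::tibble(
    term = s$parameter, estimate = s$mode,
    conf.low = s$lower, conf.high = s$upper
  )
}

#' @export
glance.sb_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$kind,
    n_subjects = length(x$subjects),
    k = x$model$k,
    n_samples = dim(x$samples)[1] * dim(x$samples)[2],
    max_rhat = max(gelman_rubin(x)$rhat),
    acceptance = mean(x$acceptance)
  )
}

#' Per-subject AIC for a fitted model
#'
#' `AIC = 2k - 2 loglik` at the individual-level posterior-mean estimates.
#'
#' @param fit An `sb_fit`.
#' @return A tibble with `subject`, `loglik`, `aic`.
#' @export
aic_by_subject <- function(fit) {
  est <- individual_estimates(fit)
  trials <- fit$trials
  purrr::map_dfr(seq_len(nrow(est)), function(i) {
    s <- est$subject[i]
    params <- unlist(est[i, -1])
    ll <- loglik_subject(params,
                         trials[as.character(trials$subject) == as.character(s), ],
                         fit$model)
    tibble::tibble(subject = s, loglik = ll, aic = 2 * fit$model$k - 2 * ll)
  })
}

#' Compare fitted models by AIC with BCa bootstrap intervals
#'
#' Computes per-subject AIC for each fit, identifies the model with the
#' lowest mean AIC, and reports the across-subject mean AIC difference from
#' that model with a bias-corrected and accelerated (BCa) bootstrap
#' confidence interval.
#'
#' @param ... Named `sb_fit` objects fitted to the same subjects.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level.
#' @return A tibble with one row per model: `model`, `k`, `mean_aic`,
#'   `delta_aic`, `conf.low`, `conf.high`.
#' @export
compare_models <- function(..., n_boot = 10000, conf = 0.95) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "sb_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model$kind, "")
  }
  aics <- lapply(fits, aic_by_subject)
  subj <- aics[[1]]$subject
  for (a in aics) {
    if (!identical(a$subject, subj)) stop("subject sets differ between fits",
                                          call. = FALSE)
  }
  mean_aic <- vapply(aics, function(a) mean(a$aic), 0)
  best <- which.min(mean_aic)
  purrr::map_dfr(seq_along(fits), function(m) {
    diffs <- aics[[m]]$aic - aics[[best]]$aic
    if (m == best || stats::sd(diffs) == 0) {
      ci <- c(mean(diffs), mean(diffs))
    } else {
      bt <- boot::boot(diffs, function(d, idx) mean(d[idx]), R = n_boot)
      bci <- boot::boot.ci(bt, conf = conf, type = "bca")
      ci <- bci$bca[4:5]
    }
    tibble::tibble(
      model = names(fits)[m], k = fits[[m]]$model$k,
      mean_aic = mean_aic[m], delta_aic = mean(diffs),
      conf.low = ci[1], conf.high = ci[2]
    )
  })
}
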