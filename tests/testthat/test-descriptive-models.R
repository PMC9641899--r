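test_that("the DoG curve is odd and peaks at (l, a)", {
  expect_equal(dog(0, 3, 20), 0)
  x <- seq(-180, 180, by = 0.5)
  expect_equal(dog(-x, 2.5, 33), -dog(x, 2.5, 33))
  set.seed(1)
  for (i in 1:100) {
    a <- runif(1, -10, 10)
    l <- runif(1, 5, 80)
    expect_equal(dog(l, a, l), a, tolerance = 1e-10)
    vals <- abs(dog(x, a, l))
    expect_lte(max(vals), abs(a) + 1e-10)
  }
  expect_error(dog(1, 1, 0), "positive")
})

test_that("model means nest and match a hand-computed value", {
  sr <- bias_model("stim_resp")
  ar <- bias_model("attr_rep")
  prev_s <- c(30, 100); prev_r <- c(40, 80); cur <- c(10, 90)
  zero <- c(a_stim = 0, l_stim = 30, a_resp = 0, l_resp = 30, sigma = 8)
  expect_equal(model_mean(prev_s, prev_r, cur, zero, sr), c(0, 0))
  p_sr <- c(a_stim = -4.88, l_stim = 38.45, a_resp = 7.95, l_resp = 28.92,
            sigma = 8)
  p_ar <- c(a_att = 7.95, l_att = 28.92, beta_att = 1, a_rep = -4.88,
            l_rep = 38.45, beta_rep = 0, sigma = 8)
  expect_equal(model_mean(prev_s, prev_r, cur, p_ar, ar),
               model_mean(prev_s, prev_r, cur, p_sr, sr))
  # previous stimulus at +l_stim, previous response on the current stimulus:
  # the response DoG is zero at zero offset, leaving exactly a_stim
  expect_equal(model_mean(38.45, 0, 0, p_sr, sr), -4.88, tolerance = 1e-12)
  expect_error(model_mean(NA, 0, 0, p_sr, sr), "missing")
})

test_that("the subject log-likelihood matches a brute-force product", {
  tr <- tibble::tibble(
    subject = 1, session = 1, block = 1, trial = 1:6, group_range_deg = 80,
    stimulus_deg = c(10, 50, 30, 350, 40, 80),
    response_deg = c(12, 55, 28, 352, 47, 76)
  )
  tr$error_deg <- circ_dist(tr$response_deg, tr$stimulus_deg)
  m <- bias_model("stim_resp")
  p <- c(a_stim = -3, l_stim = 40, a_resp = 6, l_resp = 25, sigma = 7)
  # independent oracle: per-trial density product over trials 2..6
  dens <- numeric(0)
  for (t in 2:6) {
    xs <- circ_dist(tr$stimulus_deg[t - 1], tr$stimulus_deg[t])
    xr <- circ_dist(tr$response_deg[t - 1], tr$stimulus_deg[t])
    mu <- dog(xs, p[["a_stim"]], p[["l_stim"]]) +
      dog(xr, p[["a_resp"]], p[["l_resp"]])
    kap <- 1 / (p[["sigma"]] * pi / 180)^2
    dens <- c(dens, exp(kap * cos((tr$error_deg[t] - mu) * pi / 180)) /
                (2 * pi * besselI(kap, 0)) * pi / 180)
  }
  expect_equal(loglik_subject(p, tr, m), sum(log(dens)), tolerance = 1e-10)
  # additivity: stacking the same subject's data twice doubles the value
  tr2 <- dplyr::bind_rows(tr, dplyr::mutate(tr, block = 2))
  expect_equal(loglik_subject(p, tr2, m), 2 * loglik_subject(p, tr, m))
  expect_equal(loglik_subject(c(p[1:4], sigma = -1), tr, m), -Inf)
})

test_that("gamma hyper-priors have the prescribed mode and spread", {
  pr <- hier_priors()
  for (ty in c("a", "l", "s", "b")) {
    g <- pr$gamma[[ty]]
    sd0 <- pr$assumed_sd[[ty]]
    expect_equal((g[["shape"]] - 1) / g[["rate"]], sd0 / 2, tolerance = 1e-10)
    expect_equal(sqrt(g[["shape"]]) / g[["rate"]], 2 * sd0, tolerance = 1e-10)
  }
})

test_that("acceptance ratios match an independent log-posterior oracle", {
  # R re-implementation of the joint density, written independently of the
  # compiled code path
  r_logpost <- function(blocks, model, meta, ind, mu, tau) {
    lp <- 0
    vm <- function(delta, kap) {
      kap * cos(delta * pi / 180) - log(2 * pi) -
        (kap + log(besselI(kap, 0, expon.scaled = TRUE))) + log(pi / 180)
    }
    for (j in seq_len(model$k)) {
      if (mu[j] < meta$mu_lower[j] || mu[j] > meta$mu_upper[j]) return(-Inf)
      if (tau[j] <= 0) return(-Inf)
      if (is.finite(meta$musd[j])) {
        lp <- lp + dnorm(mu[j], meta$mumean[j], meta$musd[j], log = TRUE)
      }
      lp <- lp + (meta$gshape[j] - 1) * log(tau[j]) - meta$grate[j] * tau[j]
    }
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      th <- ind[i, ]
      for (j in seq_len(model$k)) {
        if (th[j] < meta$lower[j] || th[j] > meta$upper[j]) return(-Inf)
        if (meta$ptype[j] == 3L) {
          lp <- lp + dnorm(th[j], mu[j], tau[j], log = TRUE)
        } else {
          lp <- lp + vm(th[j] - mu[j], 1 / (tau[j] * pi / 180)^2)
        }
      }
      names(th) <- model$params$name
      if (length(b$y) > 0) {
        df <- tibble::tibble(
          subject = i, session = 1, block = 1,
          trial = seq_along(b$y) * 2, # dummy, history supplied directly
          stimulus_deg = 0, response_deg = 0, error_deg = b$y,
          prev_stim_offset = b$xs, prev_resp_offset = b$xr,
          resp_stim_gap = b$d,
          prev_stim_deg = wrap_360(b$xs), prev_resp_deg = wrap_360(b$xr),
          excluded = FALSE
        )
        mu_t <- with(df, switch(model$kind,
          stimulus = dog(prev_stim_offset, th[["a"]], th[["l"]]),
          response = dog(prev_resp_offset, th[["a"]], th[["l"]]),
          stim_resp = dog(prev_stim_offset, th[["a_stim"]], th[["l_stim"]]) +
            dog(prev_resp_offset, th[["a_resp"]], th[["l_resp"]]),
          attr_rep = dog(wrap_signed(prev_stim_offset + th[["beta_att"]] * resp_stim_gap),
                         th[["a_att"]], th[["l_att"]]) +
            dog(wrap_signed(prev_stim_offset + th[["beta_rep"]] * resp_stim_gap),
                th[["a_rep"]], th[["l_rep"]])
        ))
        lp <- lp + sum(vm(df$error_deg - mu_t, 1 / (th[["sigma"]] * pi / 180)^2))
      }
    }
    lp
  }

  set.seed(31)
  for (kind in c("stim_resp", "attr_rep")) {
    model <- bias_model(kind)
    meta <- meta_for(model)
    n <- 40
    blocks <- lapply(1:2, function(i) {
      list(y = runif(n, -20, 20), xs = runif(n, -180, 180),
           xr = runif(n, -180, 180), d = runif(n, -25, 25))
    })
    base_ind <- do.call(rbind, lapply(1:2, function(i) {
      model$params$init + runif(model$k, -0.3, 0.3)
    }))
    base_mu <- model$params$init + runif(model$k, -0.3, 0.3)
    base_tau <- serialbias:::init_tau_for(model, hier_priors())
    lp_cpp0 <- serialbias:::hb_log_posterior_cpp(
      blocks, match(kind, c("stimulus", "response", "stim_resp", "attr_rep")),
      meta, base_ind, base_mu, base_tau
    )
    lp_r0 <- r_logpost(blocks, model, meta, base_ind, base_mu, base_tau)
    for (rep in 1:25) {
      ind <- base_ind + matrix(rnorm(2 * model$k, 0, 0.2), 2)
      ind[, model$params$type == "l"] <- abs(ind[, model$params$type == "l"])
      mu2 <- base_mu + rnorm(model$k, 0, 0.2)
      mu2 <- pmin(pmax(mu2, meta$mu_lower), meta$mu_upper)
      ind <- pmin(pmax(ind, rep(meta$lower, each = 2)),
                  rep(meta$upper, each = 2))
      tau2 <- abs(base_tau + rnorm(model$k, 0, 0.1))
      lp_cpp <- serialbias:::hb_log_posterior_cpp(
        blocks, match(kind, c("stimulus", "response", "stim_resp", "attr_rep")),
        meta, ind, mu2, tau2
      )
      lp_r <- r_logpost(blocks, model, meta, ind, mu2, tau2)
      # the MH acceptance ratio is the difference of log joints
      expect_equal(lp_cpp - lp_cpp0, as.numeric(lp_r - lp_r0),
                   tolerance = 1e-6)
    }
  }
})

test_that("with no data the sampler returns the prior on the centre mixture", {
  # two subjects whose only trials are excluded first-of-block trials
  tr <- tibble::tibble(
    subject = rep(1:2, each = 2), session = 1, block = rep(1:2, 2),
    trial = 1, group_range_deg = 80,
    stimulus_deg = 10, response_deg = 20,
    error_deg = 10, excluded = TRUE
  )
  f <- fit_bias_model(tr, bias_model("attr_rep"),
                      control = mcmc_control(chains = 2, burn = 5000,
                                             draws = 40000, thin = 20),
                      seed = 12)
  for (p in c("mu_beta_att", "mu_beta_rep")) {
    draws <- c(f$samples[, , p])
    # prior moments Normal(0.5, 0.5^2), within random-walk Monte-Carlo error
    expect_lt(abs(mean(draws) - 0.5), 0.1)
    expect_lt(abs(sd(draws) - 0.5), 0.12)
  }
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  set.seed(5)
  same <- array(rnorm(4000), dim = c(1000, 4, 1),
                dimnames = list(NULL, NULL, "p"))
  expect_lt(gelman_rubin(same)$rhat, 1.05)
  apart <- array(c(rnorm(1000, 0), rnorm(1000, 10)), dim = c(1000, 2, 1),
                 dimnames = list(NULL, NULL, "p"))
  # closed form: W ~ 1, B/n = var(c(0,10)) = 50 => Rhat ~ sqrt(51) >> 1.1
  expect_gt(gelman_rubin(apart)$rhat, 3)
  expect_error(gelman_rubin(array(0, c(100, 1, 1))), "2 chains")
})

test_that("posterior summaries report density mode and central interval", {
  set.seed(8)
  a <- array(rnorm(8000, 3, 1), dim = c(2000, 2, 2),
             dimnames = list(NULL, NULL, c("mu_x", "sd_x")))
  s <- summarize_posterior(a, pars = "mu_x")
  expect_equal(s$mode, s$mean, tolerance = 0.15)
  expect_equal(s$lower, unname(quantile(c(a[, , "mu_x"]), 0.025)))
  expect_equal(s$upper, unname(quantile(c(a[, , "mu_x"]), 0.975)))
  expect_error(summarize_posterior(a[1:10, , , drop = FALSE], pars = "mu_x"),
               "100 pooled")
})

test_that("population means are recovered across replicates (coverage)", {
  # 20 small replicates of the single-DoG stimulus model; 95% credible
  # intervals for the population means should cover the truth most of the
  # time even at this reduced scale
  truth <- c(mu_a = -5, mu_l = 38, mu_sigma = 8)
  covered <- 0; total <- 0
  for (rep in 1:20) {
    tr <- mark_first_trials(simulate_cohort(
      n_subjects = 4, n_blocks = 2, ranges = 180,
      params = generative_params(a_rep = -5, l_rep = 38, a_att = 0),
      seed = 500 + rep
    ))
    f <- fit_bias_model(tr, bias_model("stimulus"),
                        control = mcmc_control(chains = 2, burn = 3000,
                                               draws = 3000, thin = 6),
                        seed = rep)
    s <- summarize_posterior(f)
    for (p in names(truth)) {
      row <- s[s$parameter == p, ]
      total <- total + 1
      if (row$lower <= truth[[p]] && truth[[p]] <= row$upper) {
        covered <- covered + 1
      }
    }
  }
  expect_gte(covered / total, 0.8)
})

test_that("AIC comparison penalises the redundant larger model by ~2k", {
  tr <- mark_first_trials(simulate_cohort(
    n_subjects = 6, n_blocks = 4, ranges = 80,
    params = generative_params(a_rep = -5, l_rep = 38, a_att = 0),
    seed = 77
  ))
  ctl <- mcmc_control(chains = 2, burn = 4000, draws = 4000, thin = 8)
  f_stim <- fit_bias_model(tr, bias_model("stimulus"), control = ctl, seed = 3)
  f_sr <- fit_bias_model(tr, bias_model("stim_resp"), control = ctl, seed = 4)
  cmp <- compare_models(stimulus = f_stim, stim_resp = f_sr, n_boot = 2000)
  expect_equal(cmp$delta_aic[cmp$model == "stimulus"], 0)
  d <- cmp$delta_aic[cmp$model == "stim_resp"]
  expect_gt(d, 2 * (5 - 3) - 2)
  expect_lt(d, 2 * (5 - 3) + 2)
  # comparing a model with itself gives a zero difference
  same <- compare_models(a = f_stim, b = f_stim, n_boot = 100)
  expect_equal(same$delta_aic, c(0, 0))
})

test_that("fits are reproducible under a fixed seed", {
  tr <- mark_first_trials(simulate_cohort(n_subjects = 2, n_blocks = 1,
                                          seed = 3))
  ctl <- mcmc_control(chains = 2, burn = 500, draws = 500, thin = 5)
  f1 <- fit_bias_model(tr, "stimulus", control = ctl, seed = 9)
  f2 <- fit_bias_model(tr, "stimulus", control = ctl, seed = 9)
  expect_identical(f1$samples, f2$samples)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(glance(f1)), 1)
})
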