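cfg <- observer_config()

test_that("tuning rates follow the von Mises tuning curve", {
  g <- rep(cfg$g0, cfg$n_neurons)
  r <- tuning_rates(cfg$preferred[3], g, cfg)
  expect_equal(r[3], cfg$g0) # peak-normalised: gain = peak expected count
  expect_lt(max(r[-3] / r[3]), 1)
  expect_equal(tuning_rates(45, g, cfg), tuning_rates(45 + 360, g, cfg))
  expect_equal(tuning_rates(45, 2 * g, cfg), 2 * tuning_rates(45, g, cfg))
  expect_error(tuning_rates(0, -g, cfg), "nonnegative")
})

test_that("stimulus adaptation suppresses gains around the adapter", {
  g <- adapted_gains_stimulus(180, cfg)
  i_ad <- which(cfg$preferred == 180)
  expect_equal(g[i_ad], cfg$g0 * (1 - cfg$alpha_adapt)) # 2.6
  i_anti <- which(cfg$preferred == 0)
  expect_equal(g[i_anti], cfg$g0, tolerance = 1e-5)
  cfg0 <- observer_config(alpha_adapt = 0)
  expect_equal(adapted_gains_stimulus(180, cfg0),
               rep(cfg0$g0, cfg0$n_neurons))
  expect_true(all(g > 0 & g <= cfg$g0))
})

test_that("spike-count adaptation divides gain by (1 + r)^alpha", {
  r <- rep(0, cfg$n_neurons)
  expect_equal(adapted_gains_spikes(r, cfg), rep(cfg$g0, cfg$n_neurons))
  r[1] <- 1
  expect_equal(adapted_gains_spikes(r, cfg)[1], cfg$g0 / 2^0.35)
  cfg0 <- observer_config(alpha_adapt = 0)
  expect_equal(adapted_gains_spikes(r + 5, cfg0), rep(cfg0$g0, cfg0$n_neurons))
  expect_error(adapted_gains_spikes(r - 2, cfg), "nonnegative")
})

test_that("spike sampling is Poisson with the tuned rates", {
  g <- adapted_gains_stimulus(90, cfg)
  rates <- tuning_rates(100, g, cfg)
  draws <- withr::with_seed(2, {
    replicate(3000, sample_spikes(100, g, cfg))
  })
  m <- rowMeans(draws)
  se <- sqrt(rates / 3000)
  expect_true(all(abs(m - rates) < 4 * se + 1e-9))
  expect_equal(sample_spikes(100, 0 * g, cfg), rep(0L, cfg$n_neurons))
  expect_identical(sample_spikes(100, g, cfg, seed = 5),
                   sample_spikes(100, g, cfg, seed = 5))
})

test_that("the baseline likelihood is flat for silence, unbiased on average", {
  lik0 <- population_likelihood(rep(0, cfg$n_neurons), cfg)
  expect_equal(sum(lik0), 1)
  expect_lt(diff(range(lik0)) / mean(lik0), 1e-6)
  # without adaptation the average likelihood peak sits on the stimulus
  peaks <- withr::with_seed(3, {
    replicate(500, {
      sp <- sample_spikes(200, rep(cfg$g0, cfg$n_neurons), cfg)
      grid <- observer_grid(cfg)
      grid[which.max(population_likelihood(sp, cfg))]
    })
  })
  expect_lt(abs(circ_mean(circ_dist(peaks, 200))), 1)
})

test_that("the propagation kernel matches its closed form", {
  k <- propagation_kernel(cfg)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # frozen oracle: 0.9 * exp(kappa)/(2 pi I0(kappa)) + 0.1/(2 pi) at zero
  # offset equals 1.37571 per radian for kappa_prop = 14.6
  expect_equal(k[1] * 360 / (2 * pi), 1.37571, tolerance = 1e-3)
  ku <- propagation_kernel(observer_config(p_same = 0))
  expect_equal(ku, rep(1 / 360, 360))
})

test_that("prior prediction is a circular convolution that diffuses", {
  k <- propagation_kernel(cfg)
  delta <- rep(0, 360); delta[91] <- 1 # mass at 90 degrees
  pr <- predict_prior(delta, k)
  # shifted kernel: mass at 90 + offset
  expect_equal(pr[91], k[1], tolerance = 1e-10)
  expect_equal(pr[101], k[11], tolerance = 1e-10)
  u <- rep(1 / 360, 360)
  expect_equal(predict_prior(u, k), u, tolerance = 1e-12)
  # repeated propagation monotonically increases circular spread
  g <- observer_grid(cfg)
  p <- delta; spreads <- numeric(10)
  for (i in 1:10) {
    p <- predict_prior(p, k)
    r <- sqrt(sum(p * sin(g * pi / 180))^2 + sum(p * cos(g * pi / 180))^2)
    spreads[i] <- sqrt(-2 * log(r)) * 180 / pi
  }
  expect_true(all(diff(spreads) > 0))
  expect_error(predict_prior(delta[1:180], k), "mismatch")
})

test_that("posterior updates multiply densities like von Mises products", {
  g <- observer_grid(cfg)
  vm_grid <- function(mu, kap) {
    d <- exp(kap * cos((g - mu) * pi / 180))
    d / sum(d)
  }
  prior <- vm_grid(100, 3)
  lik <- vm_grid(140, 5)
  post <- update_posterior(prior, lik)
  # closed form: product of von Mises is von Mises with resultant vector
  c1 <- 3 * cos(100 * pi / 180) + 5 * cos(140 * pi / 180)
  s1 <- 3 * sin(100 * pi / 180) + 5 * sin(140 * pi / 180)
  mu12 <- atan2(s1, c1) * 180 / pi
  k12 <- sqrt(c1^2 + s1^2)
  expect_equal(post, vm_grid(mu12, k12), tolerance = 1e-6)
  expect_equal(update_posterior(lik, prior), post)
  u <- rep(1 / 360, 360)
  expect_equal(update_posterior(u, lik), lik, tolerance = 1e-12)
})

test_that("the posterior mean is the resultant direction", {
  g <- observer_grid(cfg)
  delta <- rep(0, 360); delta[11] <- 1
  expect_equal(posterior_mean_estimate(delta), 10)
  sym <- exp(-circ_dist(g, 90)^2 / 800); sym <- sym / sum(sym)
  expect_equal(posterior_mean_estimate(sym), 90, tolerance = 1e-8)
  mix <- rep(0, 360); mix[1] <- 0.7; mix[91] <- 0.3
  expect_equal(posterior_mean_estimate(mix), atan2(0.3, 0.7) * 180 / pi,
               tolerance = 1e-10)
  expect_error(posterior_mean_estimate(rep(1 / 360, 360)), "resultant")
})

test_that("observer simulations are grid-robust and benefit from priors", {
  st <- simulate_stimuli(task_design(20), n_blocks = 1, seed = 17)
  r1 <- simulate_observer(st, observer_config(grid_step = 1), seed = 4)
  r2 <- simulate_observer(st, observer_config(grid_step = 0.5), seed = 4)
  expect_lt(max(abs(circ_dist(r1$response_deg, r2$response_deg))), 0.1)

  # temporal integration helps in a slowly-changing world (adaptation off)
  st3 <- simulate_stimuli(task_design(20), n_blocks = 3, seed = 18)
  mae <- function(p_same) {
    r <- simulate_observer(
      st3, observer_config(alpha_adapt = 0, p_same = p_same), seed = 6
    )
    mean(abs(r$error_deg))
  }
  expect_lt(mae(0.9), mae(0))
})
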