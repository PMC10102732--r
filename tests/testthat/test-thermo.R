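test_that("zero noise reduces the path simulator to deterministic Euler", {
  cfg <- langevin_config(drift = function(mu, t, lambda) -mu,
                         noise_strength = 0)
  pro <- work_protocol(function(mu, l) 0 * mu, function(mu, l) 0 * mu,
                       function(t) 0 * t, 0, 1, 0,
                       eq_sampler = function(n, beta) rep(2, n))
  ens <- simulate_paths(cfg, pro, dt = 0.01, n_paths = 5, seed = 1,
                        keep_paths = TRUE)
  # Euler recursion mu_{k+1} = mu_k (1 - dt) from mu_0 = 2, identical paths
  expect_equal(unname(ens$paths[1, ]), 2 * (1 - 0.01)^(0:100))
  expect_equal(ens$paths[1, ], ens$paths[5, ])
})

test_that("ensembles are bitwise reproducible under a fixed seed", {
  cfg <- langevin_config()
  pro <- protocol_dragged_trap()
  a <- simulate_paths(cfg, pro, dt = 2e-3, n_paths = 200, seed = 33)
  b <- simulate_paths(cfg, pro, dt = 2e-3, n_paths = 200, seed = 33)
  expect_identical(a$works, b$works)
  expect_identical(a$final_states, b$final_states)
  c <- simulate_paths(cfg, pro, dt = 2e-3, n_paths = 200, seed = 34)
  expect_false(identical(a$works, c$works))
})

test_that("stationary variance of a linear-drift ensemble matches I/(2 theta)", {
  theta <- 0.5
  cfg <- langevin_config(drift = function(mu, t, lambda) -theta * mu)  # I = 2
  pro <- work_protocol(function(mu, l) 0 * mu, function(mu, l) 0 * mu,
                       function(t) 0 * t, 0, 5, 0,
                       eq_sampler = function(n, beta) {
                         stats::rnorm(n, 0, sqrt(2 / (2 * theta)))
                       })
  ens <- simulate_paths(cfg, pro, dt = 5e-3, n_paths = 4000, seed = 9)
  expect_equal(stats::var(ens$final_states), 2 / (2 * theta), tolerance = 0.1)
})

test_that("sekimoto work vanishes for static protocols and sums quenches", {
  pro <- protocol_dragged_trap(kappa = 2, v = 0)   # static schedule
  tt <- seq(0, 1, by = 0.1)
  expect_equal(work_along_path(stats::rnorm(11), pro, tt), 0)

  # instantaneous quench: single-step parameter jump at fixed state
  quench <- work_protocol(
    potential = function(mu, l) 0.5 * l * mu^2,
    dV_dmu = function(mu, l) l * mu,
    schedule = function(t) ifelse(t > 0, 4, 1),
    t_start = 0, t_end = 1, delta_F = NA)
  mu0 <- 1.7
  W <- work_along_path(c(mu0, mu0), quench, c(0, 1))
  expect_equal(W, 0.5 * 4 * mu0^2 - 0.5 * 1 * mu0^2)
})

test_that("slower driving dissipates less: <W> approaches delta_F", {
  cfg <- langevin_config()
  # same trap displacement (distance 1) over increasing durations
  W_mean <- vapply(c(1, 4, 16), function(tau) {
    pro <- protocol_dragged_trap(kappa = 1, v = 1 / tau, t_end = tau)
    mean(simulate_paths(cfg, pro, dt = tau * 1e-3, n_paths = 2000,
                        seed = 5)$works)
  }, numeric(1))
  expect_true(all(diff(W_mean) < 0))     # monotone approach
  expect_true(all(W_mean > 0))           # from above: <W> >= delta_F = 0
  expect_lt(W_mean[3], 0.1)
})

test_that("jarzynski and entropy estimators are exact on reversible ensembles", {
  jz <- jarzynski_estimate(works = rep(1.3, 50), beta = 2, delta_F = 1.3)
  expect_identical(jz$mean_exp, 1)
  expect_identical(jz$std_error, 0)
  expect_equal(jz$jensen_gap, 0)
  ef <- entropy_ft_estimate(works = rep(1.3, 50), beta = 2, delta_F = 1.3)
  expect_identical(ef$mean_exp, 1)
  expect_equal(ef$mean_entropy, 0)
})

test_that("dragged trap satisfies both fluctuation theorems within 3 SE", {
  cfg <- langevin_config()   # beta = 1
  ens <- simulate_paths(cfg, protocol_dragged_trap(), dt = 1e-3,
                        n_paths = 5000, seed = 71)
  jz <- jarzynski_estimate(ens$works, beta = 1, delta_F = 0)
  expect_lt(abs(jz$mean_exp - 1), 3 * jz$std_error)
  ef <- entropy_ft_estimate(ens$works, beta = 1, delta_F = 0)
  expect_lt(abs(ef$mean_exp - 1), 3 * ef$std_error)
  # second law on the same ensemble
  expect_gte(jz$jensen_gap, 0)
  expect_gte(ef$mean_entropy, 0)
})

test_that("stiffness switch recovers its analytic free-energy change", {
  beta <- 1
  pro <- protocol_stiffness_switch(kappa_i = 1, kappa_f = 4, t_end = 2)
  dF <- delta_F_stiffness(pro, beta)
  expect_equal(dF, log(4) / 2)
  ens <- simulate_paths(langevin_config(), pro, dt = 1e-3,
                        n_paths = 5000, seed = 72)
  jz <- jarzynski_estimate(ens$works, beta, dF)
  expect_lt(abs(jz$mean_exp - 1), 3 * jz$std_error)
  expect_gte(jz$jensen_gap, 0)
})

test_that("ou noise reproduces the exponential memory kernel", {
  cfg <- langevin_config(ou_tau = 0.02)
  cn <- colored_noise_check(cfg, dt = 1e-3, horizon = 400, seed = 21,
                            n_lags = 40)
  # zero-lag variance 2 k_B T gamma / tau = 100
  expect_equal(cn$empirical[1], cn$var0_theoretical, tolerance = 0.1)
  # lag tau: ratio e^{-1}
  i_tau <- which.min(abs(cn$lag_times - 0.02))
  expect_equal(cn$empirical[i_tau] / cn$empirical[1], exp(-1),
               tolerance = 0.1)

  # tau << dt: increments are white (lag-1 autocorrelation near zero)
  cnw <- colored_noise_check(langevin_config(ou_tau = 1e-4), dt = 1e-3,
                             horizon = 50, seed = 22, n_lags = 2)
  expect_lt(abs(cnw$empirical[2] / cnw$empirical[1]), 0.02)

  expect_warning(colored_noise_check(langevin_config(ou_tau = 5), dt = 1e-2,
                                     horizon = 10, seed = 1), "10 \\* tau")
  expect_error(colored_noise_check(langevin_config(), dt = 1e-3, horizon = 1),
               "ou_tau")
})

test_that("fluctuation-dissipation consistency is enforced", {
  expect_error(langevin_config(noise_strength = 1, temperature = 1),
               "fluctuation-dissipation")
  cfg <- langevin_config(temperature = 2, mass = 2, friction_gamma = 1)
  expect_equal(cfg$noise_strength, 2)
  expect_equal(cfg$beta, 0.5)
})
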