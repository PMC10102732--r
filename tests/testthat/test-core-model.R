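test_that("prediction errors invert the momentum definitions", {
  # perfect prediction: zero momenta and g matching s give all-zero errors
  m <- linear_model(linear_params(theta_g0 = 3, precisions = precisions()))
  e0 <- prediction_errors(state_vector(), 3, m)
  expect_equal(unname(Mod(e0)), c(0, 0, 0))

  # unit mass: eps_w equals p_mu directly
  e1 <- prediction_errors(state_vector(p_mu = 3), 3, m)
  expect_equal(e1[["eps_w"]], 3 + 0i)

  # non-unit masses: exact division by the neural mass
  m2 <- linear_model(canonical_linear_params(precisions(2, 4, 5)))
  psi <- state_vector(1 + 2i, -1i, 8 + 4i, 10 - 5i)
  e2 <- prediction_errors(psi, 0, m2)
  expect_equal(e2[["eps_w"]], (8 + 4i) / 4)
  expect_equal(e2[["eps_eta"]], (10 - 5i) / 5)

  # sensory error by hand substitution into the linear sensory map:
  # g = 0 + 2i*mu + 1i*a at the reference parameters
  psi <- state_vector(-10 - 10i, 10 + 15i, -20 - 10i, 5 - 10i)
  g_hand <- 2i * (-10 - 10i) + 1i * (10 + 15i)
  e3 <- prediction_errors(psi, 0, ref_model)
  expect_equal(e3[["eps_z"]], -g_hand)

  expect_error(prediction_errors(psi, NaN, ref_model), "finite")
})

test_that("free energy is the holomorphic quadratic form of the errors", {
  m <- linear_model(linear_params(theta_g0 = 5))
  # perfect prediction
  expect_equal(free_energy(state_vector(), 5, m), 0 + 0i)
  # single quadratic term p_mu^2 / (2 m_w)
  expect_equal(free_energy(state_vector(p_mu = 1), 5, m), 0.5 + 0i)

  # hand substitution at the reference parameters (holomorphic squares)
  psi <- state_vector(-10 - 10i, 10 + 15i, -20 - 10i, 5 - 10i)
  s <- 7 + 0i
  eps_z <- s - (2i * psi[["mu"]] + 1i * psi[["a"]])
  F_hand <- psi[["p_mu"]]^2 / 2 + psi[["p_a"]]^2 / 2 + eps_z^2 / 2
  expect_equal(free_energy(psi, s, ref_model), F_hand)

  expect_error(precisions(0, 1, 1), "positive")
})

test_that("hamiltonian satisfies the Legendre identity against the flow", {
  m <- linear_model(linear_params())
  expect_equal(hamiltonian(state_vector(), 0, m), 0 + 0i)
  # single kinetic term with f = 0
  expect_equal(hamiltonian(state_vector(p_mu = 1), 0, m), 0.5 + 0i)

  # H + F = p_mu mu_dot + p_a a_dot at randomly drawn states and stimuli
  set.seed(11)
  for (k in 1:20) {
    psi <- random_state()
    s <- random_complex(1, 10)
    v <- bm_vector_field(psi, s, ref_model)
    lhs <- hamiltonian(psi, s, ref_model) + free_energy(psi, s, ref_model)
    rhs <- psi[["p_mu"]] * v[["mu"]] + psi[["p_a"]] * v[["a"]]
    expect_lt(Mod(lhs - rhs), 1e-9 * (1 + Mod(rhs)))
  }
})

test_that("vector field equals the driven linear system and -J grad H", {
  R <- relaxation_matrix(ref_params)
  set.seed(7)
  for (k in 1:10) {
    psi <- random_state()
    s <- random_complex(1, 20)
    v <- bm_vector_field(psi, s, ref_model)
    # linear closure: psi_dot = -R psi + I(s)
    rhs <- -as.vector(R %*% unclass(psi)) + source_vector(ref_params, s)
    expect_lt(max(Mod(v - rhs)), 1e-10 * (1 + max(Mod(rhs))))
  }

  # symplectic check: -J dH/dPsi by central holomorphic differences
  J <- rbind(cbind(matrix(0, 2, 2), -diag(2)), cbind(diag(2), matrix(0, 2, 2)))
  h <- 1e-5
  psi <- state_vector(1 + 2i, -3 + 1i, 0.5 - 1i, 2 + 0.5i)
  s <- 4 - 2i
  gradH <- vapply(1:4, function(i) {
    e <- rep(0 + 0i, 4); e[i] <- h
    (hamiltonian(as_state_vector(unclass(psi) + e), s, ref_model) -
       hamiltonian(as_state_vector(unclass(psi) - e), s, ref_model)) / (2 * h)
  }, complex(1))
  v <- bm_vector_field(psi, s, ref_model)
  expect_lt(max(Mod(v - as.vector(-J %*% gradH))), 1e-6)
})

test_that("momentum definition round-trips through the flow equations", {
  # mu_dot from the flow, fed back through p_mu = m_w (mu_dot - f)
  m2 <- linear_model(canonical_linear_params(precisions(3, 2.5, 4)))
  psi <- state_vector(2 - 1i, 1 + 1i, -3 + 2i, 4 - 4i)
  v <- bm_vector_field(psi, 9, m2)
  mu_dot <- v[["mu"]]
  expect_equal(2.5 * (mu_dot - m2$f(psi[["mu"]])), psi[["p_mu"]])
  a_dot <- v[["a"]]
  expect_equal(4 * (a_dot - m2$pi(psi[["a"]])), psi[["p_a"]])
})

test_that("action accumulates free energy at quadrature order two", {
  # constant integrand: exactly c * tau
  n <- 100
  tr_df <- data.frame(time = seq(0, 1, length.out = n + 1),
                      F = rep(3 + 1i, n + 1))
  expect_equal(bm_action(tr_df), 3 + 1i)
  # zero-horizon integral
  expect_equal(bm_action(data.frame(time = 0, F = 5 + 0i)), 0 + 0i)

  # halving dt shrinks the quadrature error by about 4 (trapezoid = O(dt^2))
  psi0 <- attractor_centre(ref_params, 0)
  a1 <- bm_action(propagate(ref_params, psi0, stimulus_constant(50), 0, 0.2, 50))
  a2 <- bm_action(propagate(ref_params, psi0, stimulus_constant(50), 0, 0.1, 100))
  a3 <- bm_action(propagate(ref_params, psi0, stimulus_constant(50), 0, 0.05, 200))
  # Richardson: (a1 - a2)/(a2 - a3) -> 4
  expect_equal(Mod(a1 - a2) / Mod(a2 - a3), 4, tolerance = 0.1)

  expect_error(bm_action(data.frame(time = c(0, 1, 3), F = complex(3))),
               "uniform")
})

test_that("finite-difference fallback matches analytic derivatives", {
  p <- ref_params
  suppressMessages(
    m_fd <- generative_model(
      g = function(mu, a) p$theta_g0 + p$theta_g1 * mu + p$theta_g2 * a,
      f = function(mu) p$theta_f0 + p$theta_f1 * mu,
      pi_fun = function(a) p$theta_pi0 + p$theta_pi2 * a,
      precisions = p$precisions))
  expect_setequal(m_fd$fd_fallback, c("df_dmu", "dpi_da", "dg_dmu", "dg_da"))
  psi <- state_vector(1 - 2i, 3 + 1i, -1 + 1i, 2i)
  v_an <- bm_vector_field(psi, 5, ref_model)
  v_fd <- bm_vector_field(psi, 5, m_fd)
  expect_lt(max(Mod(v_an - v_fd)), 1e-6)
})
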