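#' Prediction errors of a phase-space state
#'
#' In phase space the state and motor prediction errors are recovered
#' exactly from the conjugate momenta, \eqn{\varepsilon_w = p_\mu / m_w}
#' and \eqn{\varepsilon_\eta = p_a / m_\eta}, while the sensory error is
#' \eqn{\varepsilon_z = s - g(\mu, a)}.
#'
#' @param psi a [state_vector].
#' @param s complex scalar, instantaneous sensory input.
#' @param model a [generative_model].
#' @return Named complex vector `(eps_w, eps_eta, eps_z)`.
#' @export
prediction_errors <- function(psi, s, model) {
  psi <- as_state_vector(psi)
  s <- as.complex(s)
  if (!is_finite_complex(s)) stop("stimulus must be a finite scalar", call. = FALSE)
  m <- model$precisions
  c(eps_w = unname(psi[["p_mu"]] / m[["m_w"]]),
    eps_eta = unname(psi[["p_a"]] / m[["m_eta"]]),
    eps_z = unname(s - model$g(psi[["mu"]], psi[["a"]])))
}

#' Laplace-encoded variational free energy (phase-space form)
#'
#' The instantaneous free energy of the column,
#' \deqn{F = \frac{p_\mu^2}{2 m_w} + \frac{p_a^2}{2 m_\eta}
#'       + \frac{m_z}{2}\,(s - g(\mu, a))^2,}
#' is the configuration-space quadratic form evaluated at
#' \eqn{\dot\mu = f + p_\mu/m_w}, \eqn{\dot a = \pi + p_a/m_\eta}. All
#' squares are holomorphic (no complex conjugation), so `F` is itself
#' complex when states or parameters are; the additive constant
#' \eqn{\tfrac12\ln(\sigma_z\sigma_w\sigma_\eta)} is omitted. Interpretation
#' of the real/imaginary parts is left to the caller.
#'
#' @inheritParams prediction_errors
#' @return Complex scalar `F`.
#' @export
free_energy <- function(psi, s, model) {
  psi <- as_state_vector(psi)
  m <- model$precisions
  eps_z <- as.complex(s) - model$g(psi[["mu"]], psi[["a"]])
  unname(psi[["p_mu"]]^2 / (2 * m[["m_w"]]) +
           psi[["p_a"]]^2 / (2 * m[["m_eta"]]) +
           m[["m_z"]] / 2 * eps_z^2)
}

#' Hamiltonian of the Bayesian mechanics
#'
#' Legendre transform of the free-energy Lagrangian,
#' \deqn{H = \frac{p_\mu^2}{2 m_w} + \frac{p_a^2}{2 m_\eta}
#'       + p_\mu f(\mu) + p_a \pi(a) - \frac{m_z}{2}\,\varepsilon_z^2,}
#' the generator of time evolution in the cognitive phase space. For a
#' constant stimulus `H` is conserved along exact trajectories, which the
#' integrator tests exploit as an accuracy diagnostic. The identity
#' \eqn{H + F = p_\mu\dot\mu + p_a\dot a} holds exactly at every state.
#'
#' @inheritParams prediction_errors
#' @return Complex scalar `H`.
#' @export
hamiltonian <- function(psi, s, model) {
  psi <- as_state_vector(psi)
  m <- model$precisions
  mu <- psi[["mu"]]; a <- psi[["a"]]
  eps_z <- as.complex(s) - model$g(mu, a)
  unname(psi[["p_mu"]]^2 / (2 * m[["m_w"]]) +
           psi[["p_a"]]^2 / (2 * m[["m_eta"]]) +
           psi[["p_mu"]] * model$f(mu) + psi[["p_a"]] * model$pi(a) -
           m[["m_z"]] / 2 * eps_z^2)
}

#' Bayesian-mechanics vector field
#'
#' Hamilton's equations of the column, \eqn{\dot\Psi_i = -J_{ij}
#' \partial H/\partial\Psi_j} with the fixed symplectic block matrix `J`,
#' unpacked component-wise as
#' \deqn{\dot\mu = p_\mu/m_w + f(\mu), \quad
#'       \dot a = p_a/m_\eta + \pi(a),}
#' \deqn{\dot p_\mu = -p_\mu\,\partial_\mu f - m_z (s - g)\,\partial_\mu g,
#'       \quad
#'       \dot p_a = -p_a\,\partial_a \pi - m_z (s - g)\,\partial_a g.}
#' Perception (updating \eqn{\mu}) and motor inference (updating \eqn{a})
#' descend the same free-energy landscape jointly.
#'
#' @inheritParams prediction_errors
#' @return Named complex vector of rates, ordered like the state.
#' @export
bm_vector_field <- function(psi, s, model) {
  psi <- as_state_vector(psi)
  s <- as.complex(s)
  m <- model$precisions
  mu <- psi[["mu"]]; a <- psi[["a"]]
  p_mu <- psi[["p_mu"]]; p_a <- psi[["p_a"]]
  eps_z <- s - model$g(mu, a)
  out <- c(p_mu / m[["m_w"]] + model$f(mu),
           p_a / m[["m_eta"]] + model$pi(a),
           -p_mu * model$df_dmu(mu) - m[["m_z"]] * eps_z * model$dg_dmu(mu, a),
           -p_a * model$dpi_da(a) - m[["m_z"]] * eps_z * model$dg_da(mu, a))
  names(out) <- c("mu", "a", "p_mu", "p_a")
  out
}

# vectorised F(t), H(t) along a sampled trajectory; assumes the model maps
# are vectorised over complex vectors (true for all built-ins)
traj_energies <- function(states, s_vals, model) {
  m <- model$precisions
  mu <- states[, 1]; a <- states[, 2]
  p_mu <- states[, 3]; p_a <- states[, 4]
  eps_z <- s_vals - model$g(mu, a)
  kin <- p_mu^2 / (2 * m[["m_w"]]) + p_a^2 / (2 * m[["m_eta"]])
  list(F = kin + m[["m_z"]] / 2 * eps_z^2,
       H = kin + p_mu * model$f(mu) + p_a * model$pi(a) -
         m[["m_z"]] / 2 * eps_z^2)
}

#' Action accumulated along a trajectory
#'
#' Time integral of the free energy, \eqn{S = \int_{t_0}^{t} F\,dt'},
#' evaluated by the trapezoid rule on the trajectory's uniform grid. The
#' temporal horizon is \eqn{\tau = t - t_0}; minimising this accumulator is
#' the variational statement the equations of motion realise.
#'
#' @param trajectory a [bm_trajectory] carrying `free_energy` samples, or a
#'   data frame with columns `time` and `F` (complex).
#' @return Complex scalar, the accumulated action.
#' @export
bm_action <- function(trajectory) {
  if (inherits(trajectory, "bm_trajectory")) {
    tt <- trajectory$times
    Fv <- trajectory$free_energy
  } else {
    tt <- trajectory$time
    Fv <- trajectory$F
  }
  n <- length(tt)
  if (n < 2L) return(0 + 0i)
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt))) {
    stop("trajectory grid must be uniform", call. = FALSE)
  }
  sum((Fv[-n] + Fv[-1]) / 2 * dt)
}
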