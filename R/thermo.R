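#' Over-damped Langevin configuration
#'
#' Mesoscopic neural activity is modelled by the over-damped Langevin
#' equation \eqn{d\mu/dt = f(\mu; t) + w(t)} with delta-correlated Gaussian
#' noise, \eqn{\langle w(t) w(t')\rangle = I\,\delta(t - t')}. In one
#' dimension the drift and noise strength are tied to physical parameters
#' by \eqn{f = A/(m\gamma)} and \eqn{I = 2 k_B T/(m\gamma)}: `A` is the
#' conservative force, `m` the unit's mass, `gamma` the friction whose
#' inverse is the momentum relaxation time, and `T` the (housekeeping, body)
#' temperature. When `temperature`, `mass` and `friction_gamma` are all
#' given, `noise_strength` is checked against (or derived from) the
#' fluctuation-dissipation relation.
#'
#' @param drift function `(mu, t, lambda)` returning the drift `f`.
#' @param noise_strength non-negative real `I`; derived from
#'   `2 k_B T/(m gamma)` when omitted.
#' @param temperature,k_B,mass,friction_gamma physical parameters
#'   (defaults: unit scales, `k_B = 1`).
#' @param ou_tau optional positive real: autocorrelation time of the
#'   Ornstein-Uhlenbeck coloured-noise kernel (see [colored_noise_check()]).
#' @return An object of class `"langevin_config"`.
#' @export
langevin_config <- function(drift = NULL, noise_strength = NULL,
                            temperature = NULL, k_B = 1, mass = 1,
                            friction_gamma = 1, ou_tau = NULL) {
  stopifnot(k_B > 0, mass > 0, friction_gamma > 0)
  if (is.null(temperature) && is.null(noise_strength)) temperature <- 1
  if (is.null(noise_strength)) {
    stopifnot(temperature >= 0)
    noise_strength <- 2 * k_B * temperature / (mass * friction_gamma)
  } else if (is.null(temperature)) {
    stopifnot(noise_strength >= 0)
    temperature <- noise_strength * mass * friction_gamma / (2 * k_B)
  } else {
    fdr <- 2 * k_B * temperature / (mass * friction_gamma)
    if (abs(noise_strength - fdr) > 1e-8 * max(1, fdr)) {
      stop("noise_strength ", noise_strength,
           " violates the fluctuation-dissipation relation 2 k_B T/(m gamma) = ",
           fdr, call. = FALSE)
    }
  }
  if (!is.null(ou_tau)) stopifnot(ou_tau > 0)
  structure(
    list(drift = drift, noise_strength = noise_strength,
         temperature = temperature, k_B = k_B, mass = mass,
         friction_gamma = friction_gamma, ou_tau = ou_tau,
         beta = if (temperature > 0) 1 / (k_B * temperature) else Inf),
    class = "langevin_config")
}

#' Work protocols for fluctuation-theorem experiments
#'
#' A protocol is a potential \eqn{V(\mu, \lambda)} plus a schedule
#' \eqn{\lambda(t)} on `[t_start, t_end]` and the analytic Helmholtz
#' free-energy change `delta_F` between the endpoint equilibria. Two
#' built-ins cover the standard test cases:
#' `protocol_dragged_trap()` drags a harmonic trap
#' \eqn{V = \tfrac12\kappa(\mu - vt)^2} at speed `v` (`delta_F = 0`:
#' translating a trap leaves the partition function unchanged), and
#' `protocol_stiffness_switch()` ramps the stiffness from `kappa_i` to
#' `kappa_f` (`delta_F = ln(kappa_f/kappa_i) / (2 beta)`).
#'
#' @param potential function `(mu, lambda)` returning the energy.
#' @param dV_dmu function `(mu, lambda)`: spatial derivative (for the
#'   drift `-dV/dmu / (m gamma)`).
#' @param schedule function `t -> lambda`.
#' @param t_start,t_end protocol window.
#' @param delta_F analytic free-energy change between endpoint equilibria
#'   (a function of `beta` for the built-ins; a number here).
#' @param eq_sampler optional function `(n, beta)` drawing initial states
#'   from the `lambda(t_start)` equilibrium.
#' @param kappa,kappa_i,kappa_f trap stiffnesses.
#' @param v drag speed.
#' @return An object of class `"work_protocol"`.
#' @name work_protocols
#' @export
work_protocol <- function(potential, dV_dmu, schedule, t_start = 0,
                          t_end = 1, delta_F = NA_real_, eq_sampler = NULL) {
  stopifnot(is.function(potential), is.function(dV_dmu),
            is.function(schedule), t_end > t_start)
  structure(
    list(potential = potential, dV_dmu = dV_dmu, schedule = schedule,
         t_start = t_start, t_end = t_end, delta_F = delta_F,
         eq_sampler = eq_sampler),
    class = "work_protocol")
}

#' @rdname work_protocols
#' @export
protocol_dragged_trap <- function(kappa = 1, v = 1, t_start = 0, t_end = 1) {
  work_protocol(
    potential = function(mu, lambda) 0.5 * kappa * (mu - lambda)^2,
    dV_dmu = function(mu, lambda) kappa * (mu - lambda),
    schedule = function(t) v * t,
    t_start = t_start, t_end = t_end,
    delta_F = 0,
    eq_sampler = function(n, beta) {
      stats::rnorm(n, mean = v * t_start, sd = sqrt(1 / (beta * kappa)))
    })
}

#' @rdname work_protocols
#' @export
protocol_stiffness_switch <- function(kappa_i = 1, kappa_f = 4,
                                      t_start = 0, t_end = 1) {
  stopifnot(kappa_i > 0, kappa_f > 0)
  ramp <- function(t) {
    u <- pmin(1, pmax(0, (t - t_start) / (t_end - t_start)))
    kappa_i + (kappa_f - kappa_i) * u
  }
  p <- work_protocol(
    potential = function(mu, lambda) 0.5 * lambda * mu^2,
    dV_dmu = function(mu, lambda) lambda * mu,
    schedule = ramp,
    t_start = t_start, t_end = t_end,
    delta_F = NA_real_,   # depends on beta; filled by delta_F_stiffness()
    eq_sampler = function(n, beta) {
      stats::rnorm(n, 0, sd = sqrt(1 / (beta * kappa_i)))
    })
  p$kappa_i <- kappa_i
  p$kappa_f <- kappa_f
  p
}

#' Free-energy change of a stiffness switch
#'
#' \eqn{\Delta F = \ln(\kappa_f/\kappa_i)/(2\beta)}, from the Gaussian
#' partition functions of the endpoint traps.
#'
#' @param protocol a stiffness-switch protocol.
#' @param beta inverse temperature.
#' @return Real scalar.
#' @export
delta_F_stiffness <- function(protocol, beta) {
  log(protocol$kappa_f / protocol$kappa_i) / (2 * beta)
}

#' Simulate an ensemble of driven Langevin paths
#'
#' Euler-Maruyama discretisation of the over-damped dynamics under a work
#' protocol: per step the parameter is updated first (the work stroke,
#' Sekimoto convention) and the state then relaxes with increment
#' \eqn{f\,dt + \sqrt{I\,dt}\,\xi}, \eqn{\xi \sim N(0,1)}. The drift is
#' taken from `config$drift` if supplied, otherwise derived from the
#' protocol potential as \eqn{-\partial_\mu V/(m\gamma)}. Initial states
#' are drawn from the protocol's start-point equilibrium (required for the
#' Jarzynski estimator to apply). Ensembles are reproducible under a fixed
#' seed. Paths that leave the representable range are flagged and excluded,
#' with the count reported.
#'
#' @param config a [langevin_config].
#' @param protocol a [work_protocol].
#' @param dt step size; a warning is issued when `dt * max |dV'/dmu|`
#'   sampled along the ensemble exceeds 0.1.
#' @param n_paths number of paths.
#' @param seed integer RNG seed.
#' @param mu0_sampler optional function `(n, beta)` overriding the
#'   protocol's equilibrium sampler.
#' @param keep_paths logical; store the full path matrix (memory grows as
#'   `n_paths * n_steps`).
#' @return An object of class `"langevin_ensemble"`: per-path Sekimoto work
#'   `works`, final states, the time and schedule grids, the exclusion
#'   count, and (optionally) the path matrix.
#' @export
simulate_paths <- function(config, protocol, dt = 1e-3, n_paths = 1e4,
                           seed = 1L, mu0_sampler = NULL, keep_paths = FALSE) {
  stopifnot(inherits(config, "langevin_config"),
            inherits(protocol, "work_protocol"), dt > 0, n_paths >= 2)
  set.seed(as.integer(seed))
  beta <- config$beta
  mg <- config$mass * config$friction_gamma
  sampler <- mu0_sampler %||% protocol$eq_sampler
  if (is.null(sampler)) stop("no initial-state sampler available", call. = FALSE)
  n_steps <- as.integer(round((protocol$t_end - protocol$t_start) / dt))
  times <- protocol$t_start + dt * (0:n_steps)
  lam <- protocol$schedule(times)
  drift <- config$drift %||%
    function(mu, t, lambda) -protocol$dV_dmu(mu, lambda) / mg
  sig <- sqrt(config$noise_strength * dt)

  mu <- sampler(n_paths, beta)
  W <- numeric(n_paths)
  paths <- if (keep_paths) matrix(NA_real_, n_paths, n_steps + 1L) else NULL
  if (keep_paths) paths[, 1L] <- mu
  max_slope <- 0
  for (k in seq_len(n_steps)) {
    # work stroke: parameter update at fixed state
    W <- W + protocol$potential(mu, lam[k + 1L]) - protocol$potential(mu, lam[k])
    # heat stroke: state relaxation under the updated parameter
    f <- drift(mu, times[k], lam[k + 1L])
    max_slope <- max(max_slope, max(abs(f)) * dt)
    mu <- mu + f * dt + sig * stats::rnorm(n_paths)
    if (keep_paths) paths[, k + 1L] <- mu
  }
  if (max_slope > 0.1) {
    warning("dt * max|f| = ", format(max_slope, digits = 3),
            " exceeds 0.1; consider a smaller step")
  }
  bad <- !is.finite(mu) | !is.finite(W)
  if (any(bad)) {
    warning(sum(bad), " divergent path(s) excluded")
  }
  structure(
    list(works = W[!bad], final_states = mu[!bad], times = times,
         lambda = lam, n_excluded = sum(bad), seed = as.integer(seed),
         beta = beta, paths = if (keep_paths) paths[!bad, , drop = FALSE]),
    class = "langevin_ensemble")
}

#' @export
print.langevin_ensemble <- function(x, ...) {
  cat("<langevin_ensemble>", length(x$works), "paths,",
      length(x$times) - 1L, "steps, seed", x$seed, "\n")
  cat("  <W> =", format(mean(x$works), digits = 6),
      " sd(W) =", format(stats::sd(x$works), digits = 6), "\n")
  if (x$n_excluded > 0) cat("  excluded:", x$n_excluded, "\n")
  invisible(x)
}

#' Sekimoto work along a single path
#'
#' Accumulates \eqn{W = \sum_k [V(\mu_k, \lambda_{k+1}) -
#' V(\mu_k, \lambda_k)]}: the energy change under each parameter update at
#' fixed state. A static schedule therefore does exactly zero work, and an
#' instantaneous quench contributes \eqn{V(\mu_0, \lambda_f) -
#' V(\mu_0, \lambda_i)} in one stroke.
#'
#' @param path numeric vector of states \eqn{\mu_k} on the time grid.
#' @param protocol a [work_protocol].
#' @param times time grid aligned with `path`.
#' @return Real scalar, the accumulated work.
#' @export
work_along_path <- function(path, protocol, times) {
  stopifnot(length(path) == length(times))
  lam <- protocol$schedule(times)
  n <- length(times)
  if (n < 2L) return(0)
  sum(protocol$potential(path[-n], lam[-1L]) -
        protocol$potential(path[-n], lam[-n]))
}

#' Jarzynski-equality estimator
#'
#' Estimates \eqn{\langle e^{-\beta(W - \Delta F)}\rangle} over a work
#' ensemble, which the nonequilibrium work relation pins to 1 for any
#' driving speed, together with its Monte-Carlo standard error and the
#' Jensen (second-law) gap \eqn{\langle W\rangle - \Delta F \ge 0}.
#' Exponentials are accumulated with a max-shift so strongly dissipative
#' ensembles cannot overflow.
#'
#' @param works numeric vector of per-path work values.
#' @param beta inverse temperature.
#' @param delta_F free-energy change between endpoint equilibria.
#' @return An object of class `"ft_estimate"`.
#' @export
jarzynski_estimate <- function(works, beta, delta_F = 0) {
  stopifnot(length(works) >= 2L, is.finite(beta), beta > 0)
  a <- -beta * (works - delta_F)
  m <- max(a)
  x <- exp(a - m)                     # in (0, 1]
  mean_exp <- exp(m) * mean(x)
  std_error <- exp(m) * stats::sd(x) / sqrt(length(works))
  structure(
    list(estimator = "jarzynski",
         mean_exp = mean_exp, std_error = std_error,
         n_paths = length(works),
         mean_work = mean(works), delta_F = delta_F, beta = beta,
         jensen_gap = mean(works) - delta_F,
         entropy_changes = NULL),
    class = "ft_estimate")
}

#' Integral entropy fluctuation-theorem estimator
#'
#' Under isothermal driving the per-path total entropy production is
#' \eqn{\Delta S_{tot}/k_B = \beta(W - \Delta F)}; the integral fluctuation
#' theorem states \eqn{\langle e^{-\Delta S_{tot}/k_B}\rangle = 1}, and on
#' average \eqn{\langle\Delta S_{tot}\rangle \ge 0} (the stochastic second
#' law). Reversible ensembles (all \eqn{\Delta S_{tot} = 0}) give exactly 1.
#'
#' @inheritParams jarzynski_estimate
#' @param k_B Boltzmann constant (default 1, arbitrary units).
#' @return An object of class `"ft_estimate"` carrying the per-path
#'   `entropy_changes` (\eqn{\Delta S_{tot}}, in units of `k_B`).
#' @export
entropy_ft_estimate <- function(works, beta, delta_F = 0, k_B = 1) {
  stopifnot(length(works) >= 2L, is.finite(beta), beta > 0)
  ds <- beta * (works - delta_F)      # Delta S_tot / k_B
  m <- max(-ds)
  x <- exp(-ds - m)
  mean_exp <- exp(m) * mean(x)
  std_error <- exp(m) * stats::sd(x) / sqrt(length(works))
  structure(
    list(estimator = "entropy_ft",
         mean_exp = mean_exp, std_error = std_error,
         n_paths = length(works),
         mean_work = mean(works), delta_F = delta_F, beta = beta,
         mean_entropy = mean(ds) * k_B,
         entropy_changes = ds * k_B),
    class = "ft_estimate")
}

#' @export
print.ft_estimate <- function(x, ...) {
  cat("<ft_estimate>", x$estimator, "\n")
  cat("  mean_exp =", format(x$mean_exp, digits = 6),
      "+/-", format(x$std_error, digits = 3),
      " (n =", x$n_paths, ")\n")
  cat("  <W> =", format(x$mean_work, digits = 6),
      " delta_F =", format(x$delta_F, digits = 6), "\n")
  if (!is.null(x$mean_entropy)) {
    cat("  <Delta S_tot> =", format(x$mean_entropy, digits = 6), "\n")
  }
  invisible(x)
}

#' Coloured-noise autocorrelation check
#'
#' Generates an Ornstein-Uhlenbeck noise process \eqn{\zeta(t)} whose
#' stationary kernel is the exponential memory
#' \eqn{\langle\zeta(t)\zeta(t')\rangle = 2 k_B T\,\gamma\tau^{-1}
#' e^{-|t - t'|/\tau}} and compares its empirical autocorrelation against
#' that kernel. At zero lag the variance is \eqn{2 k_B T \gamma/\tau}; at
#' lag \eqn{\tau} the ratio to the zero-lag value is \eqn{e^{-1}}; as
#' \eqn{\tau \to 0} with matched strength the increments recover
#' delta-correlated white noise.
#'
#' @param config a [langevin_config] with `ou_tau` set.
#' @param dt sampling step.
#' @param horizon total simulated time; a warning is issued below
#'   `10 * tau` (too little data for a stable estimate).
#' @param seed integer RNG seed.
#' @param n_lags number of lags (in steps) to report.
#' @return A list with the lag grid, empirical and theoretical
#'   autocovariances, and their maximum absolute deviation relative to the
#'   zero-lag value.
#' @export
colored_noise_check <- function(config, dt = 1e-3, horizon = 100,
                                seed = 1L, n_lags = 50L) {
  stopifnot(inherits(config, "langevin_config"))
  tau <- config$ou_tau
  if (is.null(tau)) stop("config$ou_tau is not set", call. = FALSE)
  if (horizon < 10 * tau) {
    warning("horizon ", horizon, " < 10 * tau; autocorrelation estimate ",
            "will be noisy")
  }
  set.seed(as.integer(seed))
  var0 <- 2 * config$k_B * config$temperature * config$friction_gamma / tau
  n <- as.integer(round(horizon / dt))
  rho <- exp(-dt / tau)
  innov_sd <- sqrt(var0 * (1 - rho^2))
  z1 <- stats::rnorm(1, 0, sqrt(var0))
  eps <- stats::rnorm(n - 1L, 0, innov_sd)
  z <- c(z1, as.numeric(stats::filter(eps, rho, method = "recursive",
                                      init = z1)))
  lags <- 0:n_lags
  emp <- vapply(lags, function(L) {
    mean(z[1:(n - L)] * z[(1 + L):n])
  }, numeric(1))
  theo <- var0 * exp(-lags * dt / tau)
  list(lag_times = lags * dt, empirical = emp, theoretical = theo,
       var0_theoretical = var0,
       max_rel_dev = max(abs(emp - theo)) / var0,
       tau = tau, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
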