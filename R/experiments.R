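#' Spontaneous (resting-state) dynamics
#'
#' Runs the stimulus-free column from \eqn{\Psi(0) = 0} using the exact
#' spontaneous solution \eqn{\Psi_{sp}(t) = \Psi_c - R^{-1} e^{-Rt} I_{sp}}.
#' With the reference parameters the orbit circulates about the spontaneous
#' centre, whose real projection onto \eqn{(\mu, a, p_\mu)} is
#' \eqn{(-10, 10, -20)}; the pure-imaginary spectrum keeps the orbit
#' bounded without decay.
#'
#' @param params a [linear_params] object.
#' @param t_max horizon.
#' @param dt step.
#' @return A list: `trajectory` ([bm_trajectory]), `centre`
#'   ([state_vector]), `centre_projection` (real 3-vector), `spectrum`
#'   ([eigen_spectrum] result) and `intensity`.
#' @export
run_spontaneous <- function(params = canonical_linear_params(),
                            t_max = 500, dt = 0.01) {
  n <- as.integer(round(t_max / dt))
  tr <- propagate(params, state_vector(), stimulus_null(), 0, dt, n)
  centre <- attractor_centre(params, 0)
  list(trajectory = tr,
       centre = centre,
       centre_projection = Re(unclass(centre)[c("mu", "a", "p_mu")]),
       spectrum = eigen_spectrum(params),
       intensity = cognitive_intensity(centre))
}

#' Locate a spontaneous-orbit state near a real projection
#'
#' The spontaneous orbit lives in the 8-real-dimensional phase space, but
#' published initial conditions are often quoted only as the real
#' \eqn{(\mu, a, p_\mu)} projection. This helper completes such a triple to
#' a full complex state by scanning the spontaneous orbit for the sample
#' whose projection is closest (Euclidean distance) to the target, and
#' reports the achieved distance so a poor match is visible rather than
#' silent.
#'
#' @param target real 3-vector `(Re mu, Re a, Re p_mu)`.
#' @param params a [linear_params] object.
#' @param t_max,dt scan grid of the spontaneous orbit.
#' @return A list: `state` (full complex [state_vector]), `time` (orbit
#'   time of the match) and `distance`.
#' @export
spontaneous_state_near <- function(target, params = canonical_linear_params(),
                                   t_max = 500, dt = 0.01) {
  stopifnot(length(target) == 3L, is.numeric(target))
  sp <- run_spontaneous(params, t_max, dt)
  st <- sp$trajectory$states
  d2 <- (Re(st[, 1]) - target[1])^2 + (Re(st[, 2]) - target[2])^2 +
    (Re(st[, 3]) - target[3])^2
  k <- which.min(d2)
  list(state = as_state_vector(st[k, ]),
       time = sp$trajectory$times[k],
       distance = sqrt(d2[k]))
}

# default initial state of the stimulated runs: the spontaneous-orbit
# sample matching the reference resting-state projection
default_resting_state <- function(params) {
  spontaneous_state_near(c(-16.9, 21.1, -13.3), params)$state
}

#' Passive recognition under a static stimulus
#'
#' Exposes the resting column to a constant sensory input `s` and
#' propagates exactly: \eqn{\Psi(t) = e^{-Rt}\Psi(0) + \Psi_c -
#' R^{-1}e^{-Rt}I}. The attractor keeps its shape but its centre shifts to
#' \eqn{\Psi_c(s) = R^{-1} I(s)}.
#'
#' @param params a [linear_params] object.
#' @param s constant stimulus value.
#' @param psi0 initial state; defaults to a state on the spontaneous orbit.
#' @param t_max,dt time grid.
#' @return A list: `trajectory`, `centre` (\eqn{\Psi_c(s)}), `intensity`.
#' @export
run_static <- function(params = canonical_linear_params(), s = 100,
                       psi0 = NULL, t_max = 500, dt = 0.01) {
  psi0 <- if (is.null(psi0)) default_resting_state(params) else as_state_vector(psi0)
  n <- as.integer(round(t_max / dt))
  tr <- propagate(params, psi0, stimulus_constant(s), 0, dt, n)
  centre <- attractor_centre(params, s)
  list(trajectory = tr, centre = centre,
       intensity = cognitive_intensity(centre))
}

#' Cognitive-intensity sweep over stimulus strength
#'
#' Tabulates \eqn{|\Psi_c(s)|^2} over a range of static stimuli for one or
#' more neural-mass settings. Heavier masses encode more precise internal
#' models, and the intensity a given stimulus evokes is weaker for the more
#' precise model — precision substitutes for neural excursion.
#'
#' @param s_values numeric/complex vector of stimulus values.
#' @param masses_list list of [precisions] objects (or length-3 vectors
#'   `(m_z, m_w, m_eta)`).
#' @param params base [linear_params]; its theta values are kept and its
#'   masses replaced per sweep entry.
#' @return A data frame with columns `s`, `m_z`, `m_w`, `m_eta`,
#'   `intensity`.
#' @export
intensity_sweep <- function(s_values = seq(0, 100, by = 10),
                            masses_list = list(c(1, 1, 1), c(10, 1, 10)),
                            params = canonical_linear_params()) {
  rows <- list()
  for (m in masses_list) {
    pr <- if (inherits(m, "precisions")) m else precisions(m[1], m[2], m[3])
    p <- linear_params(params$theta_g0, params$theta_g1, params$theta_g2,
                       params$theta_f0, params$theta_f1,
                       params$theta_pi0, params$theta_pi2, pr)
    for (s in s_values) {
      rows[[length(rows) + 1L]] <- data.frame(
        s = Re(s), m_z = pr[["m_z"]], m_w = pr[["m_w"]], m_eta = pr[["m_eta"]],
        intensity = cognitive_intensity(attractor_centre(p, s)))
    }
  }
  do.call(rbind, rows)
}

#' Active recognition under a sigmoid stimulus
#'
#' Integrates the full Bayesian mechanics (generic Runge-Kutta, so the run
#' doubles as an integration test against the exact propagator) under the
#' saturating sigmoid stimulus. The imaginary part of the motor momentum,
#' `Im p_a(t)`, is returned as the motor-inference readout: it tracks the
#' sigmoid transition as the column actively infers the rising input.
#'
#' @param params a [linear_params] object.
#' @param s_inf,k,t_m sigmoid parameters (defaults: saturation 100,
#'   stiffness 0.2, midpoint 250).
#' @param psi0 initial state; defaults to a state on the spontaneous orbit.
#' @param t_max,dt time grid.
#' @return A list: `trajectory`, `motor_trace` (data frame `t`,
#'   `im_p_a`), `stimulus`.
#' @export
run_sigmoid <- function(params = canonical_linear_params(),
                        s_inf = 100, k = 0.2, t_m = 250,
                        psi0 = NULL, t_max = 500, dt = 0.01) {
  psi0 <- if (is.null(psi0)) default_resting_state(params) else as_state_vector(psi0)
  stim <- stimulus_sigmoid(s_inf, k, t_m)
  n <- as.integer(round(t_max / dt))
  tr <- integrate_bm(linear_model(params), psi0, stim, 0, dt, n)
  list(trajectory = tr,
       motor_trace = data.frame(t = tr$times, im_p_a = Im(tr$states[, 4])),
       stimulus = stim)
}

#' Stimulus-driven bifurcation between attractors
#'
#' Follows the dynamic transition from the spontaneous attractor to the
#' stimulus-locked ("cognitive") attractor as a sigmoid input rises.
#' The trajectory is cut into windows ending at the snapshot times; each
#' window's bounding box and mean (in the real projection) localise the
#' orbit, and the per-window mean migrates from the spontaneous centre
#' \eqn{\Psi_c(0)} to the saturated centre \eqn{\bar\Psi_c(s_\infty)}. The
#' empirical relaxation time is the first time the running mean enters and
#' stays within a ball around \eqn{\bar\Psi_c} (radius a fraction of the
#' centre shift).
#'
#' @param params a [linear_params] object.
#' @param s_inf,k,t_m sigmoid parameters.
#' @param psi0 initial state; defaults to the spontaneous-orbit state
#'   completing the real triple `(-16.9, 21.1, -13.3)`.
#' @param snapshot_times window endpoints (defaults `5, 100, 260, 500`).
#' @param dt step.
#' @param ball_fraction radius of the arrival ball as a fraction of the
#'   centre shift.
#' @param mean_window width (time units) of the trailing average used for
#'   the arrival criterion; about one slow oscillation period.
#' @return A list: `trajectory`, `snapshots` (per-window data frame with
#'   means and bounding boxes), `centre_spontaneous`, `centre_saturated`,
#'   `centre_shift`, `relaxation_time`, `initial_state`,
#'   `initial_state_distance`.
#' @export
run_bifurcation <- function(params = canonical_linear_params(),
                            s_inf = 100, k = 0.2, t_m = 250,
                            psi0 = NULL,
                            snapshot_times = c(5, 100, 260, 500),
                            dt = 0.01, ball_fraction = 0.05,
                            mean_window = 10) {
  init_info <- NULL
  if (is.null(psi0)) {
    init_info <- spontaneous_state_near(c(-16.9, 21.1, -13.3), params)
    psi0 <- init_info$state
  } else {
    psi0 <- as_state_vector(psi0)
  }
  t_max <- max(snapshot_times)
  stim <- stimulus_sigmoid(s_inf, k, t_m)
  n <- as.integer(round(t_max / dt))
  tr <- integrate_bm(linear_model(params), psi0, stim, 0, dt, n)

  c0 <- attractor_centre(params, 0)
  c_inf <- attractor_centre(params, s_inf)
  shift <- sqrt(sum(Mod(unclass(c_inf) - unclass(c0))^2))

  edges <- c(0, snapshot_times)
  snaps <- lapply(seq_along(snapshot_times), function(i) {
    sel <- tr$times > edges[i] & tr$times <= edges[i + 1L]
    st <- tr$states[sel, , drop = FALSE]
    data.frame(
      t_end = snapshot_times[i],
      mean_mu_re = mean(Re(st[, 1])), mean_a_re = mean(Re(st[, 2])),
      mean_pmu_re = mean(Re(st[, 3])), mean_pa_re = mean(Re(st[, 4])),
      box_mu_lo = min(Re(st[, 1])), box_mu_hi = max(Re(st[, 1])),
      box_a_lo = min(Re(st[, 2])), box_a_hi = max(Re(st[, 2])),
      box_pmu_lo = min(Re(st[, 3])), box_pmu_hi = max(Re(st[, 3])),
      dist_to_c0 = dist_window_mean(st, c0),
      dist_to_cinf = dist_window_mean(st, c_inf))
  })
  snaps <- do.call(rbind, snaps)

  # relaxation time: the orbit circles its centre without decaying (the
  # spectrum sits on the imaginary axis), so the arrival criterion is on the
  # trailing time-average of the state, which washes the oscillation out;
  # relaxation = first entry into the ball around the saturated centre that
  # is never left again
  win <- max(2L, as.integer(round(mean_window / dt)) + 1L)
  wts <- rep(1 / win, win)
  run_mean <- apply(tr$states, 2, function(col) {
    complex(real = as.numeric(stats::filter(Re(col), wts, sides = 1)),
            imaginary = as.numeric(stats::filter(Im(col), wts, sides = 1)))
  })
  devs <- sqrt(rowSums(Mod(sweep(run_mean, 2, unclass(c_inf)))^2))
  inside <- !is.na(devs) & devs <= ball_fraction * shift
  stays <- rev(cumprod(rev(inside))) > 0
  relax <- if (any(stays)) tr$times[which(stays)[1]] else NA_real_

  list(trajectory = tr, snapshots = snaps,
       centre_spontaneous = c0, centre_saturated = c_inf,
       centre_shift = shift, relaxation_time = relax,
       initial_state = psi0,
       initial_state_distance = if (is.null(init_info)) NA_real_ else init_info$distance)
}

# distance of a window's complex mean state from a centre
dist_window_mean <- function(states, centre) {
  m <- colMeans(states)
  sqrt(sum(Mod(m - unclass(centre))^2))
}
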