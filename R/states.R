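#' Phase-space state vector of a single cortical column
#'
#' The column's cognitive state lives in a complex 4-dimensional phase space
#' with the fixed component ordering \eqn{\Psi = (\mu, a, p_\mu, p_a)}:
#' the perceptual (internal) state \eqn{\mu}, the motor state \eqn{a}, and
#' their conjugate momenta. The momenta are the mass-weighted prediction
#' errors: \eqn{p_\mu = m_w(\dot\mu - f)} and \eqn{p_a = m_\eta(\dot a - \pi)}.
#' Every component may be complex; the real phase space is 8-dimensional.
#'
#' @param mu complex scalar, perceptual state (arbitrary units).
#' @param a complex scalar, motor state.
#' @param p_mu complex scalar, momentum conjugate to `mu`.
#' @param p_a complex scalar, momentum conjugate to `a`.
#'
#' @return A named complex vector of length 4 with class `"state_vector"`.
#' @examples
#' state_vector(-10 - 10i, 10 + 15i, -20 - 10i, 5 - 10i)
#' @export
state_vector <- function(mu = 0 + 0i, a = 0 + 0i, p_mu = 0 + 0i, p_a = 0 + 0i) {
  psi <- as.complex(c(mu = mu, a = a, p_mu = p_mu, p_a = p_a))
  names(psi) <- c("mu", "a", "p_mu", "p_a")
  if (length(psi) != 4L) {
    stop("state_vector components must be scalars", call. = FALSE)
  }
  if (!all(is.finite(Re(psi)) & is.finite(Im(psi)))) {
    stop("state_vector components must be finite", call. = FALSE)
  }
  structure(psi, class = "state_vector")
}

#' Coerce a length-4 complex vector to a state vector
#'
#' @param x numeric or complex vector of length 4, ordered
#'   \eqn{(\mu, a, p_\mu, p_a)}.
#' @return A `state_vector`.
#' @export
as_state_vector <- function(x) {
  if (inherits(x, "state_vector")) return(x)
  x <- as.complex(x)
  if (length(x) != 4L) stop("expected a length-4 state", call. = FALSE)
  state_vector(x[1L], x[2L], x[3L], x[4L])
}

#' @export
print.state_vector <- function(x, ...) {
  cat("<state_vector>  (mu, a, p_mu, p_a)\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Neural masses (prediction-channel precisions)
#'
#' The three inverse variances of the generative densities act as inertial
#' masses of the Bayesian mechanics: \eqn{m_z = 1/\sigma_z} (sensory),
#' \eqn{m_w = 1/\sigma_w} (state) and \eqn{m_\eta = 1/\sigma_\eta} (motor).
#' Heavier masses encode more precise predictions.
#'
#' @param m_z,m_w,m_eta strictly positive reals.
#' @return A named numeric vector with class `"precisions"`.
#' @examples
#' precisions(1, 1, 1)
#' precisions(10, 1, 10)  # high sensory/motor precision
#' @export
precisions <- function(m_z = 1, m_w = 1, m_eta = 1) {
  m <- c(m_z = as.numeric(m_z), m_w = as.numeric(m_w), m_eta = as.numeric(m_eta))
  if (!all(is.finite(m)) || any(m <= 0)) {
    stop("neural masses must be strictly positive and finite", call. = FALSE)
  }
  structure(m, class = "precisions")
}

#' Channel variances corresponding to a set of neural masses
#'
#' Inverts the mass/variance relation \eqn{m_i \sigma_i = 1}.
#'
#' @param m a [precisions] object.
#' @return Named numeric vector `(sigma_z, sigma_w, sigma_eta)`.
#' @export
variances <- function(m) {
  stopifnot(inherits(m, "precisions"))
  c(sigma_z = 1 / m[["m_z"]], sigma_w = 1 / m[["m_w"]],
    sigma_eta = 1 / m[["m_eta"]])
}

#' @export
print.precisions <- function(x, ...) {
  cat("<precisions>  m_z =", x[["m_z"]], " m_w =", x[["m_w"]],
      " m_eta =", x[["m_eta"]], "\n")
  invisible(x)
}

# internal: finite complex scalar check
is_finite_complex <- function(z) {
  length(z) == 1L && is.finite(Re(z)) && is.finite(Im(z))
}
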