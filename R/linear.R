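#' Relaxation matrix of the linear Bayesian mechanics
#'
#' Substituting the linear generative maps into Hamilton's equations closes
#' the dynamics into the driven linear system \eqn{\dot\Psi + R\Psi = I(t)}.
#' The 4x4 complex relaxation matrix, in the fixed component order
#' \eqn{(\mu, a, p_\mu, p_a)}, is
#' \deqn{R = \begin{pmatrix}
#'  -\theta_f^{(1)} & 0 & -1/m_w & 0 \\
#'  0 & -\theta_\pi^{(2)} & 0 & -1/m_\eta \\
#'  -m_z\theta_g^{(1)}\theta_g^{(1)} & -m_z\theta_g^{(1)}\theta_g^{(2)} &
#'    \theta_f^{(1)} & 0 \\
#'  -m_z\theta_g^{(1)}\theta_g^{(2)} & -m_z\theta_g^{(2)}\theta_g^{(2)} &
#'    0 & \theta_\pi^{(2)}
#' \end{pmatrix}.}
#' All products are holomorphic (no conjugation). The trace vanishes
#' identically — a symplectic signature every parameter draw must satisfy.
#'
#' @param params a [linear_params] object.
#' @return 4x4 complex matrix.
#' @examples
#' R <- relaxation_matrix(canonical_linear_params())
#' sum(diag(R))  # 0 by construction
#' @export
relaxation_matrix <- function(params) {
  stopifnot(inherits(params, "linear_params"))
  p <- params
  m <- p$precisions
  mz <- m[["m_z"]]
  matrix(c(
    -p$theta_f1,                    0 + 0i,                        -1 / m[["m_w"]], 0 + 0i,
    0 + 0i,                         -p$theta_pi2,                  0 + 0i,          -1 / m[["m_eta"]],
    -mz * p$theta_g1 * p$theta_g1,  -mz * p$theta_g1 * p$theta_g2, p$theta_f1,      0 + 0i,
    -mz * p$theta_g1 * p$theta_g2,  -mz * p$theta_g2 * p$theta_g2, 0 + 0i,          p$theta_pi2),
    nrow = 4, ncol = 4, byrow = TRUE,
    dimnames = list(c("mu", "a", "p_mu", "p_a"), c("mu", "a", "p_mu", "p_a")))
}

#' Source vector of the linear Bayesian mechanics
#'
#' The inhomogeneous drive of \eqn{\dot\Psi + R\Psi = I(t)}: the prior
#' intercepts feed the state rows and the sensory input enters the momentum
#' rows,
#' \deqn{I(t) = \left(\theta_f^{(0)},\; \theta_\pi^{(0)},\;
#'   -m_z\theta_g^{(1)} s(t) + m_z\theta_g^{(0)}\theta_g^{(1)},\;
#'   -m_z\theta_g^{(2)} s(t) + m_z\theta_g^{(0)}\theta_g^{(2)}\right)^T.}
#'
#' @param params a [linear_params] object.
#' @param s complex scalar stimulus value.
#' @return Named complex vector of length 4.
#' @export
source_vector <- function(params, s = 0 + 0i) {
  stopifnot(inherits(params, "linear_params"))
  p <- params
  mz <- p$precisions[["m_z"]]
  s <- as.complex(s)
  out <- c(p$theta_f0,
           p$theta_pi0,
           -mz * p$theta_g1 * s + mz * p$theta_g0 * p$theta_g1,
           -mz * p$theta_g2 * s + mz * p$theta_g0 * p$theta_g2)
  names(out) <- c("mu", "a", "p_mu", "p_a")
  out
}

#' Closed-form determinant of the relaxation matrix
#'
#' \deqn{\det R = \theta_f^{(1)2}\theta_\pi^{(2)2}
#'   + \frac{m_z}{m_w}\,\theta_g^{(1)2}\theta_\pi^{(2)2}
#'   + \frac{m_z}{m_\eta}\,\theta_f^{(1)2}\theta_g^{(2)2},}
#' with holomorphic squares. Together with the vanishing trace this pins the
#' product and sum of the four eigenvalues for any parameter draw.
#'
#' @param params a [linear_params] object.
#' @return Complex scalar.
#' @export
det_closed_form <- function(params) {
  stopifnot(inherits(params, "linear_params"))
  p <- params
  m <- p$precisions
  p$theta_f1^2 * p$theta_pi2^2 +
    m[["m_z"]] / m[["m_w"]] * p$theta_g1^2 * p$theta_pi2^2 +
    m[["m_z"]] / m[["m_eta"]] * p$theta_f1^2 * p$theta_g2^2
}

#' Attractor centre of the linear dynamics
#'
#' The fixed point of \eqn{\dot\Psi + R\Psi = I(s)} under a (constant)
#' stimulus `s`: the unique solution of \eqn{R\,\Psi_c = I(s)}. With zero
#' stimulus this is the spontaneous (resting-state) centre; its location is
#' set entirely by the generative parameters and the neural masses.
#'
#' @param params a [linear_params] object.
#' @param s complex scalar stimulus (default 0, the spontaneous case).
#' @param tol singularity guard on `|det R|`.
#' @return A [state_vector], \eqn{\Psi_c(s)}.
#' @examples
#' psi_c <- attractor_centre(canonical_linear_params())
#' Re(psi_c[c("mu", "a", "p_mu")])  # (-10, 10, -20)
#' @export
attractor_centre <- function(params, s = 0 + 0i, tol = 1e-12) {
  R <- relaxation_matrix(params)
  d <- complex_det(R)
  if (Mod(d) <= tol * max(1, max(Mod(R)))^4) {
    stop("degenerate attractor: relaxation matrix is singular (det = ",
         format(d), ")", call. = FALSE)
  }
  as_state_vector(solve(R, source_vector(params, s)))
}

#' Cognitive intensity of a centre
#'
#' The conjugate-squared norm \eqn{|\Psi_c|^2 = \sum_i \Psi_{c,i}
#' \Psi_{c,i}^*}, a non-negative real scalar proposed as a quantitative
#' measure of the neural resources a percept engages. This is the one place
#' complex conjugation enters the linear theory.
#'
#' @param centre a [state_vector] (or any length-4 complex vector).
#' @return Non-negative real scalar.
#' @examples
#' cognitive_intensity(attractor_centre(canonical_linear_params()))  # 1150
#' @export
cognitive_intensity <- function(centre) {
  psi <- as_state_vector(centre)
  sum(Re(psi * Conj(psi)))
}

#' Eigen-analysis of the relaxation matrix
#'
#' Solves \eqn{R\phi_\alpha = \lambda_\alpha\phi_\alpha} and checks the two
#' spectral invariants: \eqn{\sum_\alpha \lambda_\alpha = \mathrm{tr}\,R = 0}
#' and \eqn{\prod_\alpha \lambda_\alpha = \det R} against the closed form.
#' Writing \eqn{\lambda = i\omega}, eigenvalues with negligible real part
#' mark centre-like (stationary, oscillatory) modes; `max |Re lambda|` is
#' reported as the stationarity diagnostic rather than asserted, since
#' whether a given draw is exactly centre-like is a property of the
#' parameters, not of the method.
#'
#' @param params a [linear_params] object.
#' @param centre_tol relative `|Re lambda|` threshold for the centre-like
#'   label.
#' @return An object of class `"bm_spectrum"`: eigenvalues, eigenvectors,
#'   trace/determinant checks and the stationarity diagnostic.
#' @export
eigen_spectrum <- function(params, centre_tol = 1e-6) {
  R <- relaxation_matrix(params)
  e <- eigen(R)
  nrmR <- max(Mod(R))
  resid <- vapply(seq_len(4), function(k) {
    max(Mod(R %*% e$vectors[, k] - e$values[k] * e$vectors[, k]))
  }, numeric(1))
  structure(
    list(values = e$values,
         vectors = e$vectors,
         omega = e$values / 1i,    # lambda = i*omega
         trace = sum(diag(R)),
         det_numeric = complex_det(R),
         det_closed_form = det_closed_form(params),
         residual = max(resid),
         max_re = max(abs(Re(e$values))),
         centre_like = max(abs(Re(e$values))) < centre_tol * max(nrmR, 1)),
    class = "bm_spectrum")
}

#' @export
print.bm_spectrum <- function(x, ...) {
  cat("<bm_spectrum>\n  eigenvalues:\n")
  for (v in x$values) cat("   ", format(v, digits = 6), "\n")
  cat("  sum =", format(sum(x$values), digits = 3),
      " (trace =", format(x$trace, digits = 3), ")\n")
  cat("  product =", format(prod(x$values), digits = 6),
      " (closed form =", format(x$det_closed_form, digits = 6), ")\n")
  cat("  max |Re lambda| =", format(x$max_re, digits = 3),
      if (x$centre_like) " [centre-like]" else "", "\n")
  invisible(x)
}

#' Modal expansion about the stimulus-saturated centre
#'
#' Under a constant (or saturated) stimulus the trajectory decomposes over
#' the eigenmodes of `R`,
#' \deqn{\Psi(t) = \bar\Psi_c + \sum_\alpha c_\alpha e^{-\lambda_\alpha t}
#'   \phi_\alpha,}
#' with \eqn{\bar\Psi_c = R^{-1} I(s_\infty)} and the coefficients solving
#' \eqn{\Phi c = \Psi(0) - \bar\Psi_c}. (Writing \eqn{\lambda = i\omega}
#' the factors are the oscillatory \eqn{e^{-i\omega t}}.)
#'
#' @param params a [linear_params] object.
#' @param psi0 initial [state_vector].
#' @param s_inf constant/saturated stimulus value.
#' @param cond_max maximum acceptable condition number of the eigenbasis.
#' @return An object of class `"bm_modal"`: centre, eigenvalues/vectors,
#'   coefficients, and a `reconstruct(t)` closure evaluating the expansion.
#' @export
modal_expansion <- function(params, psi0, s_inf, cond_max = 1e8) {
  psi0 <- as_state_vector(psi0)
  spec <- eigen_spectrum(params)
  Phi <- spec$vectors
  sv <- svd(Phi)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > cond_max) {
    stop("eigenbasis ill-conditioned (condition number ",
         format(sv[1] / max(sv[length(sv)], .Machine$double.xmin), digits = 3),
         "); use propagate()", call. = FALSE)
  }
  centre <- attractor_centre(params, s_inf)
  coef <- solve(Phi, unclass(psi0) - unclass(centre))
  reconstruct <- function(t) {
    # rows: time samples; cols: state components
    ph <- exp(outer(t, -spec$values))          # n x 4, e^{-lambda_alpha t}
    out <- (ph * matrix(coef, length(t), 4, byrow = TRUE)) %*% t(Phi)
    sweep(out, 2, unclass(centre), "+")
  }
  structure(
    list(centre = centre, values = spec$values, vectors = Phi,
         coefficients = coef, reconstruct = reconstruct),
    class = "bm_modal")
}

#' @export
print.bm_modal <- function(x, ...) {
  cat("<bm_modal> centre:\n")
  print(x$centre)
  cat("coefficients:\n")
  print(format(x$coefficients, digits = 6), quote = FALSE)
  invisible(x)
}
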