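#' Generative model of the sensorimotor loop
#'
#' Bundles the three generative maps of the column — the sensory prediction
#' \eqn{g(\mu, a)}, the state-dynamics prior \eqn{f(\mu)} and the motor
#' policy prior \eqn{\pi(a)} — together with their first derivatives and the
#' neural masses. The maps may be nonlinear and complex-valued; derivatives
#' that are not supplied are replaced by a central finite-difference fallback
#' (holomorphic step `fd_step`), and that substitution is recorded in the
#' model so callers can detect it.
#'
#' @param g function `(mu, a)` returning the sensory prediction.
#' @param f function `(mu)` returning the prior state drift.
#' @param pi_fun function `(a)` returning the prior motor drift.
#' @param dg_dmu,dg_da functions `(mu, a)`: partial derivatives of `g`.
#' @param df_dmu function `(mu)`: derivative of `f`.
#' @param dpi_da function `(a)`: derivative of `pi_fun`.
#' @param precisions a [precisions] object.
#' @param params optional named list of raw parameters (kept for provenance).
#' @param fd_step complex step for the finite-difference fallback.
#'
#' @return An object of class `"generative_model"`.
#' @seealso [linear_model()] for the built-in linear form.
#' @export
generative_model <- function(g, f, pi_fun,
                             dg_dmu = NULL, dg_da = NULL,
                             df_dmu = NULL, dpi_da = NULL,
                             precisions = bayesmech::precisions(),
                             params = list(),
                             fd_step = 1e-6) {
  stopifnot(is.function(g), is.function(f), is.function(pi_fun),
            inherits(precisions, "precisions"))
  fd_used <- character(0)
  cdiff1 <- function(fun) function(x) (fun(x + fd_step) - fun(x - fd_step)) / (2 * fd_step)
  if (is.null(df_dmu)) { df_dmu <- cdiff1(f); fd_used <- c(fd_used, "df_dmu") }
  if (is.null(dpi_da)) { dpi_da <- cdiff1(pi_fun); fd_used <- c(fd_used, "dpi_da") }
  if (is.null(dg_dmu)) {
    dg_dmu <- function(mu, a) (g(mu + fd_step, a) - g(mu - fd_step, a)) / (2 * fd_step)
    fd_used <- c(fd_used, "dg_dmu")
  }
  if (is.null(dg_da)) {
    dg_da <- function(mu, a) (g(mu, a + fd_step) - g(mu, a - fd_step)) / (2 * fd_step)
    fd_used <- c(fd_used, "dg_da")
  }
  if (length(fd_used)) {
    message("finite-difference fallback in use for: ", paste(fd_used, collapse = ", "))
  }
  structure(
    list(g = g, f = f, pi = pi_fun,
         dg_dmu = dg_dmu, dg_da = dg_da, df_dmu = df_dmu, dpi_da = dpi_da,
         precisions = precisions, params = params,
         fd_fallback = fd_used, fd_step = fd_step),
    class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat("<generative_model>",
      if (!is.null(x$params$linear)) "(linear)" else "(user-defined)", "\n")
  print(x$precisions)
  if (length(x$fd_fallback)) {
    cat("finite-difference derivatives:", paste(x$fd_fallback, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parameters of the linear generative model
#'
#' The linear form of the generative maps,
#' \deqn{g(\mu, a) = \theta_g^{(0)} + \theta_g^{(1)}\mu + \theta_g^{(2)}a,}
#' \deqn{f(\mu) = \theta_f^{(0)} + \theta_f^{(1)}\mu, \qquad
#'       \pi(a) = \theta_\pi^{(0)} + \theta_\pi^{(2)}a,}
#' carries seven (possibly complex) parameters plus the three neural masses.
#' The linear coefficient of the policy is indexed `theta_pi2` to keep the
#' conventional superscript of the field's notation.
#'
#' @param theta_g0,theta_g1,theta_g2 sensory intercept, perceptual gain,
#'   motor gain.
#' @param theta_f0,theta_f1 state-prior intercept and rate.
#' @param theta_pi0,theta_pi2 policy intercept and rate.
#' @param precisions a [precisions] object.
#' @return An object of class `"linear_params"`.
#' @examples
#' # the worked-example parameter set with a pure-imaginary-spectrum matrix
#' canonical_linear_params()
#' @export
linear_params <- function(theta_g0 = 0, theta_g1 = 0, theta_g2 = 0,
                          theta_f0 = 0, theta_f1 = 0,
                          theta_pi0 = 0, theta_pi2 = 0,
                          precisions = bayesmech::precisions()) {
  th <- as.complex(c(theta_g0, theta_g1, theta_g2, theta_f0, theta_f1,
                     theta_pi0, theta_pi2))
  if (!all(is.finite(Re(th)) & is.finite(Im(th)))) {
    stop("linear parameters must be finite", call. = FALSE)
  }
  stopifnot(inherits(precisions, "precisions"))
  structure(
    list(theta_g0 = th[1], theta_g1 = th[2], theta_g2 = th[3],
         theta_f0 = th[4], theta_f1 = th[5],
         theta_pi0 = th[6], theta_pi2 = th[7],
         precisions = precisions),
    class = "linear_params")
}

#' @export
print.linear_params <- function(x, ...) {
  cat("<linear_params>\n")
  cat("  g: theta_g0 =", format(x$theta_g0), " theta_g1 =", format(x$theta_g1),
      " theta_g2 =", format(x$theta_g2), "\n")
  cat("  f: theta_f0 =", format(x$theta_f0), " theta_f1 =", format(x$theta_f1), "\n")
  cat("  pi: theta_pi0 =", format(x$theta_pi0), " theta_pi2 =", format(x$theta_pi2), "\n")
  print(x$precisions)
  invisible(x)
}

#' Reference parameter set of the worked examples
#'
#' The parameter set used throughout the package's worked examples:
#' intercepts \eqn{(\theta_g^{(0)}, \theta_f^{(0)}, \theta_\pi^{(0)}) =
#' (0, 10, 10)}, gains \eqn{\theta_g^{(1)} = 2e^{i\pi/2}},
#' \eqn{\theta_f^{(1)} = -1}, \eqn{\theta_g^{(2)} = \theta_\pi^{(2)} =
#' e^{i\pi/2}}. With unit masses the relaxation matrix has a pure-imaginary
#' eigenvalue spectrum, so the free dynamics orbit a centre rather than decay:
#' the spontaneous attractor sits at \eqn{\Psi_c} with real projection
#' \eqn{(\mathrm{Re}\,\mu, \mathrm{Re}\,a, \mathrm{Re}\,p_\mu) =
#' (-10, 10, -20)}.
#'
#' @param masses a [precisions] object (default unit masses).
#' @return A [linear_params] object.
#' @export
canonical_linear_params <- function(masses = precisions(1, 1, 1)) {
  linear_params(
    theta_g0 = 0, theta_g1 = 2 * exp(1i * pi / 2), theta_g2 = exp(1i * pi / 2),
    theta_f0 = 10, theta_f1 = -1,
    theta_pi0 = 10, theta_pi2 = exp(1i * pi / 2),
    precisions = masses)
}

#' Build the generative model for a linear parameter set
#'
#' Instantiates the linear maps and their exact derivatives as a
#' [generative_model], so the same phase-space machinery (free energy,
#' Hamiltonian, vector field, integrator) drives linear and nonlinear models
#' alike.
#'
#' @param params a [linear_params] object.
#' @return A `"generative_model"` with analytic derivatives.
#' @export
linear_model <- function(params) {
  stopifnot(inherits(params, "linear_params"))
  p <- params
  generative_model(
    g = function(mu, a) p$theta_g0 + p$theta_g1 * mu + p$theta_g2 * a,
    f = function(mu) p$theta_f0 + p$theta_f1 * mu,
    pi_fun = function(a) p$theta_pi0 + p$theta_pi2 * a,
    dg_dmu = function(mu, a) p$theta_g1,
    dg_da = function(mu, a) p$theta_g2,
    df_dmu = function(mu) p$theta_f1,
    dpi_da = function(a) p$theta_pi2,
    precisions = p$precisions,
    params = list(linear = p))
}
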