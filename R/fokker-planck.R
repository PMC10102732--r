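#' Gridded probability density with drift and diffusion
#'
#' Container for steady-state Fokker-Planck diagnostics: a regular 1D or
#' 2D lattice with a normalised density `p`, a scalar diffusion constant
#' `D` (= noise strength / 2) and a drift field `f`. Normalisation
#' (sum of `p` times the cell volume = 1) is enforced at construction.
#'
#' @param grid for 1D, a numeric vector of equally spaced points; for 2D, a
#'   list with components `x` and `y`, each equally spaced.
#' @param values non-negative density values: a vector (1D) or matrix with
#'   `length(x)` rows and `length(y)` columns (2D).
#' @param diffusion positive real diffusion constant `D`.
#' @param drift_field drift `f`: in 1D a function `mu -> f`; in 2D a
#'   function `(x, y) -> cbind(fx, fy)` accepting equal-length vectors.
#' @param normalize logical; rescale `values` to unit mass.
#' @return An object of class `"grid_density"`.
#' @export
grid_density <- function(grid, values, diffusion, drift_field,
                         normalize = FALSE) {
  dims <- if (is.list(grid)) 2L else 1L
  if (dims == 1L) {
    x <- as.numeric(grid)
    if (length(x) < 5L) stop("grid too coarse: need >= 5 points", call. = FALSE)
    h <- diff(x)
    if (max(abs(h - h[1])) > 1e-9 * h[1]) stop("grid must be regular", call. = FALSE)
    cell <- h[1]
    values <- as.numeric(values)
    stopifnot(length(values) == length(x))
  } else {
    x <- as.numeric(grid$x); y <- as.numeric(grid$y)
    if (length(x) < 5L || length(y) < 5L) {
      stop("grid too coarse: need >= 5 points per dimension", call. = FALSE)
    }
    hx <- diff(x); hy <- diff(y)
    if (max(abs(hx - hx[1])) > 1e-9 * hx[1] ||
        max(abs(hy - hy[1])) > 1e-9 * hy[1]) {
      stop("grid must be regular", call. = FALSE)
    }
    cell <- hx[1] * hy[1]
    values <- as.matrix(values)
    stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("density values must be finite and non-negative", call. = FALSE)
  }
  mass <- sum(values) * cell
  if (normalize) {
    if (mass <= 0 || !is.finite(mass)) {
      stop("density not normalizable on this grid (mass = ", mass, ")",
           call. = FALSE)
    }
    values <- values / mass
    mass <- 1
  } else if (abs(mass - 1) > 1e-6) {
    stop("density mass ", format(mass), " differs from 1", call. = FALSE)
  }
  structure(
    list(dims = dims, grid = if (dims == 1L) x else list(x = x, y = y),
         values = values, diffusion = diffusion, drift_field = drift_field,
         cell = cell),
    class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  cat("<grid_density>", x$dims, "D,",
      if (x$dims == 1L) length(x$grid) else
        paste(length(x$grid$x), "x", length(x$grid$y)),
      "points, D =", x$diffusion, "\n")
  invisible(x)
}

#' Equilibrium (Boltzmann) density on a grid
#'
#' The zero-flux steady state of the Smoluchowski-Fokker-Planck equation
#' under a gradient drift is the Boltzmann density
#' \eqn{p_{eq}(\mu) \propto e^{-\beta V(\mu)}}, here normalised on the
#' grid. The potential must be confining on the grid (negligible mass at
#' the boundary) for the discrete normalisation to be meaningful.
#'
#' @param potential function of one (1D) or two (2D) vector arguments
#'   returning `V`.
#' @param beta inverse temperature.
#' @param grid as in [grid_density].
#' @param diffusion diffusion constant `D` attached to the result.
#' @param drift_field drift attached to the result; defaults to the
#'   detailed-balance gradient drift \eqn{f = -D\beta\,\nabla V} computed
#'   by central differences of the potential.
#' @return A normalised [grid_density].
#' @export
fp_equilibrium_density <- function(potential, beta, grid, diffusion = 1,
                                   drift_field = NULL) {
  dims <- if (is.list(grid)) 2L else 1L
  if (dims == 1L) {
    x <- as.numeric(grid)
    V <- potential(x)
    p <- exp(-beta * V)
  } else {
    x <- as.numeric(grid$x); y <- as.numeric(grid$y)
    V <- outer(x, y, potential)
    p <- exp(-beta * V)
  }
  if (all(p == 0) || any(!is.finite(p))) {
    stop("potential not normalizable on this grid", call. = FALSE)
  }
  if (is.null(drift_field)) {
    h <- 1e-6
    if (dims == 1L) {
      drift_field <- function(mu) {
        -diffusion * beta * (potential(mu + h) - potential(mu - h)) / (2 * h)
      }
    } else {
      drift_field <- function(px, py) {
        cbind(-diffusion * beta *
                (potential(px + h, py) - potential(px - h, py)) / (2 * h),
              -diffusion * beta *
                (potential(px, py + h) - potential(px, py - h)) / (2 * h))
      }
    }
  }
  grid_density(grid, p, diffusion, drift_field, normalize = TRUE)
}

#' Probability flux field and its divergence
#'
#' Computes the steady-state probability flux
#' \eqn{j = p f - D \nabla p} on the grid (central differences in the
#' interior, one-sided at the edges) together with the scalar divergence
#' field \eqn{\nabla\cdot j}. At equilibrium (Boltzmann `p` with the
#' matching gradient drift) `j` vanishes identically — detailed balance;
#' a nonequilibrium steady state instead carries a nonzero but
#' divergence-free (solenoidal) flux, the signature of broken detailed
#' balance in living systems. Summary metrics `max_flux` and
#' `max_divergence` quantify both properties; the discretisation error in
#' each is second order in the grid spacing.
#'
#' @param density a [grid_density].
#' @return A list with the flux components, the divergence field and the
#'   summary metrics `max_flux` (max Euclidean norm of `j`) and
#'   `max_divergence` (max `|div j|`, interior points).
#' @export
flux_field <- function(density) {
  stopifnot(inherits(density, "grid_density"))
  D <- density$diffusion
  if (density$dims == 1L) {
    x <- density$grid
    p <- density$values
    f <- density$drift_field(x)
    dp <- grad_central(p, x[2] - x[1])
    j <- p * f - D * dp
    div <- grad_central(j, x[2] - x[1])
    interior <- 2:(length(x) - 1L)
    list(j = j, divergence = div,
         max_flux = max(abs(j)),
         max_divergence = max(abs(div[interior])))
  } else {
    x <- density$grid$x; y <- density$grid$y
    hx <- x[2] - x[1]; hy <- y[2] - y[1]
    p <- density$values
    pts <- expand.grid(x = x, y = y)      # column-major: x varies fastest
    fv <- density$drift_field(pts$x, pts$y)
    fx <- matrix(fv[, 1], length(x), length(y))
    fy <- matrix(fv[, 2], length(x), length(y))
    dpx <- apply(p, 2, grad_central, h = hx)
    dpy <- t(apply(p, 1, grad_central, h = hy))
    jx <- p * fx - D * dpx
    jy <- p * fy - D * dpy
    djx <- apply(jx, 2, grad_central, h = hx)
    djy <- t(apply(jy, 1, grad_central, h = hy))
    div <- djx + djy
    ix <- 2:(length(x) - 1L); iy <- 2:(length(y) - 1L)
    list(jx = jx, jy = jy, divergence = div,
         max_flux = max(sqrt(jx^2 + jy^2)),
         max_divergence = max(abs(div[ix, iy])))
  }
}

# central differences inside, one-sided at the ends
grad_central <- function(v, h) {
  n <- length(v)
  g <- numeric(n)
  g[1] <- (v[2] - v[1]) / h
  g[n] <- (v[n] - v[n - 1L]) / h
  if (n > 2L) g[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * h)
  g
}
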