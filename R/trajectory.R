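#' Trajectory container
#'
#' A sampled solution of the Bayesian mechanics on a uniform time grid:
#' states \eqn{\Psi(t)}, stimulus samples \eqn{s(t)}, and the free energy
#' and Hamiltonian evaluated at each sample.
#'
#' @param times numeric vector, strictly increasing uniform grid.
#' @param states complex matrix, one row per sample, columns
#'   `(mu, a, p_mu, p_a)`.
#' @param stimulus_values complex vector of `s(t)` samples.
#' @param free_energy,hamiltonian complex vectors of `F(t)`, `H(t)`.
#' @param method character tag recording how the trajectory was computed.
#' @return An object of class `"bm_trajectory"`.
#' @export
bm_trajectory <- function(times, states, stimulus_values,
                          free_energy, hamiltonian, method = "unknown") {
  n <- length(times)
  states <- as.matrix(states)
  stopifnot(nrow(states) == n, ncol(states) == 4L,
            length(stimulus_values) == n,
            length(free_energy) == n, length(hamiltonian) == n)
  if (n >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * max(dt)) {
      stop("trajectory times must be a strictly increasing uniform grid",
           call. = FALSE)
    }
  }
  colnames(states) <- c("mu", "a", "p_mu", "p_a")
  structure(
    list(times = times, states = states, stimulus_values = stimulus_values,
         free_energy = free_energy, hamiltonian = hamiltonian,
         method = method),
    class = "bm_trajectory")
}

#' @export
print.bm_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<bm_trajectory>", n, "samples, t in [",
      format(x$times[1]), ",", format(x$times[n]), "], method:", x$method, "\n")
  cat("  final state:\n")
  print(as_state_vector(x$states[n, ]))
  invisible(x)
}

#' @export
as.data.frame.bm_trajectory <- function(x, ...) {
  data.frame(
    t = x$times,
    s_re = Re(x$stimulus_values), s_im = Im(x$stimulus_values),
    mu_re = Re(x$states[, 1]), mu_im = Im(x$states[, 1]),
    a_re = Re(x$states[, 2]), a_im = Im(x$states[, 2]),
    pmu_re = Re(x$states[, 3]), pmu_im = Im(x$states[, 3]),
    pa_re = Re(x$states[, 4]), pa_im = Im(x$states[, 4]),
    F_re = Re(x$free_energy), F_im = Im(x$free_energy),
    H_re = Re(x$hamiltonian), H_im = Im(x$hamiltonian))
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds the real/imaginary columns of `t, s, mu, a, p_mu, p_a, F,
#' H`; the sidecar (same path with extension `.json`) records the method
#' tag and any extra provenance (parameters, seed) passed in `meta`.
#' Complex numbers in `meta` are serialised as `[re, im]` pairs.
#'
#' @param trajectory a [bm_trajectory].
#' @param path output CSV path.
#' @param meta named list of provenance entries for the sidecar.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(trajectory, path, meta = list()) {
  stopifnot(inherits(trajectory, "bm_trajectory"))
  df <- as.data.frame(trajectory)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".json")
  payload <- c(list(method = trajectory$method,
                    n_samples = length(trajectory$times),
                    t_start = trajectory$times[1],
                    t_end = trajectory$times[length(trajectory$times)]),
               encode_complex_meta(meta))
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# complex values -> [re, im] pairs, recursively, for JSON provenance
encode_complex_meta <- function(x) {
  if (is.complex(x)) {
    if (length(x) == 1L) return(c(Re(x), Im(x)))
    return(lapply(seq_along(x), function(i) c(Re(x[i]), Im(x[i]))))
  }
  if (is.list(x)) return(lapply(x, encode_complex_meta))
  x
}
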