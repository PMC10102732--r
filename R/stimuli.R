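#' Stimulus schedules
#'
#' Sensory input streams \eqn{s(t)} driving the column. Four kinds are
#' provided: the null stream, a constant, the saturating sigmoid
#' \deqn{s(t) = \frac{s_\infty}{1 + e^{-k(t - t_m)}},}
#' and an arbitrary sampled time series with linear interpolation. `t_m` is
#' the time at which the sigmoid reaches its midpoint \eqn{s_\infty/2} and
#' `k` sets the stiffness of the transition. Stimuli may be complex-valued,
#' though the worked examples all use real inputs.
#'
#' @param value complex scalar (constant stimulus).
#' @param s_inf complex scalar, sigmoid saturation value.
#' @param k positive real, sigmoid stiffness.
#' @param t_m real, sigmoid midpoint time.
#' @param time,values sampled schedule for the series kind; `time` must be
#'   strictly increasing.
#' @param extrapolate logical: if `FALSE`, evaluating a series stimulus
#'   outside its support is an error; if `TRUE`, endpoint values are held
#'   constant.
#'
#' @return An object of class `"bm_stimulus"`.
#' @examples
#' s <- stimulus_sigmoid(s_inf = 100, k = 0.2, t_m = 250)
#' eval_stimulus(s, 250)  # 50, the midpoint
#' @name stimuli
NULL

new_stimulus <- function(.kind, ...) {
  structure(c(list(kind = .kind), list(...)), class = "bm_stimulus")
}

#' @rdname stimuli
#' @export
stimulus_null <- function() new_stimulus("null")

#' @rdname stimuli
#' @export
stimulus_constant <- function(value) {
  value <- as.complex(value)
  if (!is_finite_complex(value)) stop("constant stimulus must be finite", call. = FALSE)
  new_stimulus("constant", value = value)
}

#' @rdname stimuli
#' @export
stimulus_sigmoid <- function(s_inf, k, t_m) {
  if (!(is.numeric(k) && length(k) == 1L && is.finite(k) && k > 0)) {
    stop("sigmoid stiffness k must be a positive real", call. = FALSE)
  }
  s_inf <- as.complex(s_inf)
  if (!is_finite_complex(s_inf)) stop("s_inf must be finite", call. = FALSE)
  new_stimulus("sigmoid", s_inf = s_inf, k = k, t_m = as.numeric(t_m))
}

#' @rdname stimuli
#' @export
stimulus_series <- function(time, values, extrapolate = TRUE) {
  time <- as.numeric(time)
  values <- as.complex(values)
  if (length(time) != length(values) || length(time) < 2L) {
    stop("series stimulus needs matching time/value samples (>= 2)", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("series times must be strictly increasing", call. = FALSE)
  new_stimulus("series", time = time, values = values, extrapolate = extrapolate)
}

#' Evaluate a stimulus schedule
#'
#' Vectorised over `t`. The sigmoid is overflow-guarded: for
#' \eqn{k(t - t_m) < -700} it returns exactly 0 (the representable-range
#' convention), and its large-`t` limit is exactly `s_inf`.
#'
#' @param stimulus a `"bm_stimulus"`.
#' @param t real time(s).
#' @return Complex vector of stimulus values, same length as `t`.
#' @export
eval_stimulus <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "bm_stimulus"))
  t <- as.numeric(t)
  switch(stimulus$kind,
    null = rep(0 + 0i, length(t)),
    constant = rep(stimulus$value, length(t)),
    sigmoid = {
      x <- stimulus$k * (t - stimulus$t_m)
      num <- ifelse(x < -700, 0, 1 / (1 + exp(-x)))
      stimulus$s_inf * num
    },
    series = {
      tt <- stimulus$time
      if (!stimulus$extrapolate &&
          (min(t) < tt[1L] || max(t) > tt[length(tt)])) {
        stop("time outside series support (extrapolate = FALSE)", call. = FALSE)
      }
      re <- stats::approx(tt, Re(stimulus$values), xout = t, rule = 2)$y
      im <- stats::approx(tt, Im(stimulus$values), xout = t, rule = 2)$y
      complex(real = re, imaginary = im)
    },
    stop("unknown stimulus kind: ", stimulus$kind, call. = FALSE))
}

#' @export
print.bm_stimulus <- function(x, ...) {
  cat("<bm_stimulus>", x$kind, "\n")
  if (x$kind == "constant") cat("  value =", format(x$value), "\n")
  if (x$kind == "sigmoid") {
    cat("  s_inf =", format(x$s_inf), " k =", x$k, " t_m =", x$t_m, "\n")
  }
  if (x$kind == "series") cat("  n =", length(x$time), "samples\n")
  invisible(x)
}
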