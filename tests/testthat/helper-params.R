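# shared fixtures: the reference parameter set and random complex draws

ref_params <- canonical_linear_params()
ref_model <- linear_model(ref_params)

# full complex spontaneous centre, solved independently in test-linear.R
ref_centre <- c(-10 - 10i, 10 + 15i, -20 - 10i, 5 - 10i)

random_complex <- function(n, scale = 2) {
  complex(real = stats::runif(n, -scale, scale),
          imaginary = stats::runif(n, -scale, scale))
}

random_linear_params <- function() {
  th <- random_complex(7)
  m <- stats::runif(3, 0.2, 5)
  linear_params(th[1], th[2], th[3], th[4], th[5], th[6], th[7],
                precisions(m[1], m[2], m[3]))
}

random_state <- function(scale = 10) {
  as_state_vector(random_complex(4, scale))
}

state_dist <- function(a, b) {
  sqrt(sum(Mod(as.complex(unclass(a)) - as.complex(unclass(b)))^2))
}
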