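# Independent closed-form eigenvalue oracle: quadratic formula on the trace
# and determinant of the linearized dynamics matrix, written from scratch so
# it shares no code with the package's diagonalization route.
sigma_quadratic_oracle <- function(q, state, sys, vf) {
  a11 <- -sys$Dc * q^2 - 1i * vf * q - state$fc
  a12 <- -state$fm
  a21 <- state$fc
  a22 <- -sys$Dm * q^2 + state$fm
  tr <- a11 + a22
  det <- a11 * a22 - a12 * a21
  disc <- sqrt(as.complex(tr^2 - 4 * det))
  s <- c((tr + disc) / 2, (tr - disc) / 2)
  s[order(-Re(s), -Im(s))]
}

# random strictly positive kinetics + transport draws for property sweeps
rand_setup <- function() {
  p <- reaction_params(kon = runif(1, 0.2, 3), kfb = runif(1, 0.2, 3),
                       koff = runif(1, 0.5, 4), KD = runif(1, 0.3, 3))
  n_bar <- runif(1, 0.5, 8)
  st <- homogeneous_state(n_bar, p)
  sys <- system_params(Dm = runif(1, 0.005, 0.5), Dc = runif(1, 1, 50),
                       n_bar = n_bar, reaction = p)
  list(p = p, st = st, sys = sys)
}

# cache for expensive shared fixtures (persists across test files in one run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# stationary single-peak state at the default operating point, N = 256
default_peak_init <- function() {
  cached("peak_default_256", {
    make_initial(system_params(N = 256), "single-peak")
  })
}

fig5_sys <- function() system_params(Dm = 0.1, Dc = 10, L = 20, n_bar = 7, N = 256)

fig5_peak_init <- function() {
  cached("peak_fig5_256", {
    suppressWarnings(make_initial(fig5_sys(), "single-peak", relax_max = 2000))
  })
}
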