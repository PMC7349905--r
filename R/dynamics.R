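#' Concentration field on the finite-volume grid
#'
#' A snapshot of the membrane and cytosol concentration profiles at one time,
#' on cell centers `x_i = (i + 1/2) dx`, `dx = L/N`.
#'
#' @param x cell-center coordinates (um).
#' @param m membrane concentrations (1/um).
#' @param c cytosolic concentrations (1/um).
#' @param t time stamp (s).
#' @return An object of class `polarity_field`.
#' @export
polarity_field <- function(x, m, c, t = 0) {
  stopifnot(length(x) == length(m), length(m) == length(c))
  if (any(m < -1e-12) || any(c < -1e-12)) {
    abort("concentrations must be non-negative")
  }
  structure(list(x = x, m = pmax(m, 0), c = pmax(c, 0), t = t),
            class = "polarity_field")
}

#' @export
print.polarity_field <- function(x, ...) {
  cat(sprintf(
    "<polarity_field> t=%g s, %d cells | m in [%.4g, %.4g], c in [%.4g, %.4g]\n",
    x$t, length(x$x), min(x$m), max(x$m), min(x$c), max(x$c)))
  invisible(x)
}

#' @export
tidy.polarity_field <- function(x, ...) {
  tibble::tibble(t = x$t, x = x$x, m = x$m, c = x$c, n = x$m + x$c)
}

grid_centers <- function(sys) {
  dx <- sys$L / sys$N
  (seq_len(sys$N) - 0.5) * dx
}

grid_faces <- function(sys) {
  dx <- sys$L / sys$N
  (0:sys$N) * dx
}

#' Right-hand side of the semi-discretized dynamics
#'
#' Conservative finite-volume discretization of
#' \deqn{\partial_t m = D_m \partial_x^2 m + f(m, c)}
#' \deqn{\partial_t c + \partial_x(v_f c) = D_c \partial_x^2 c - f(m, c)}
#' Diffusion uses central face gradients; advection uses the conservative
#' face flux `v(x_face) * c_face` with first-order upwinding selected by the
#' sign of the face velocity (`scheme = "upwind"`, the default) or an
#' arithmetic-mean face value (`scheme = "central"`, for convergence
#' studies). Reactions act pointwise. Because every transport term is a
#' telescoping difference of face fluxes, the discrete total mass
#' `sum(m + c) dx` has exactly zero time derivative for periodic boundaries
#' and for no-flux boundaries (zero diffusive and advective flux at the
#' walls).
#'
#' @param field a [polarity_field()] consistent with `sys`'s grid.
#' @param sys a [system_params()].
#' @param t time (s), used to gate flows with an onset `t0`.
#' @param scheme `"upwind"` or `"central"` advective face value.
#' @return A list with numeric vectors `dm`, `dc` (1/(um s)).
#' @export
polarity_rhs <- function(field, sys, t = Inf, scheme = c("upwind", "central")) {
  scheme <- match.arg(scheme)
  stopifnot(length(field$m) == sys$N)
  vface <- flow_velocity(sys$flow, grid_faces(sys), sys$L, t)
  d <- rhs_core(field$m, field$c, sys, vface, scheme)
  list(dm = d[seq_len(sys$N)], dc = d[sys$N + seq_len(sys$N)])
}

# core used both by polarity_rhs and the deSolve wrapper; vface has N+1 entries
rhs_core <- function(m, c, sys, vface, scheme) {
  N <- sys$N
  dx <- sys$L / N
  if (sys$boundary == "periodic") {
    ml <- c(m[N], m[-N]); mr <- c(m[-1], m[1])
    cl <- c(c[N], c[-N]); cr <- c(c[-1], c[1])
    dif_m <- sys$Dm * (ml - 2 * m + mr) / dx^2
    dif_c <- sys$Dc * (cl - 2 * c + cr) / dx^2
    # faces 1..N+1; left neighbour of face j is cell j-1 (face 1: cell N)
    cL <- c(c[N], c)          # cell left of each face
    cR <- c(c, c[1])          # cell right of each face
  } else {
    # no-flux: reflective ghost cells give zero diffusive flux at the walls
    dif_m <- sys$Dm * (c(m[-1], m[N]) - 2 * m + c(m[1], m[-N])) / dx^2
    dif_c <- sys$Dc * (c(c[-1], c[N]) - 2 * c + c(c[1], c[-N])) / dx^2
    cL <- c(c[1], c)          # wall faces get zero velocity anyway
    cR <- c(c, c[N])
  }
  cface <- if (scheme == "upwind") ifelse(vface >= 0, cL, cR) else (cL + cR) / 2
  flux <- vface * cface
  if (sys$boundary == "noflux") {
    flux[1] <- 0
    flux[N + 1] <- 0
  }
  adv_c <- -(flux[-1] - flux[-(N + 1)]) / dx
  f <- attach_rate(m, sys$reaction) * c - detach_rate(m, sys$reaction) * m
  c(dif_m + f, dif_c + adv_c - f)
}

#' Initial conditions
#'
#' Two fixtures: `"homogeneous-noise"` perturbs the homogeneous steady state
#' with zero-mean seeded noise applied antisymmetrically (`m = m* + xi`,
#' `c = c* - xi`), so the local and mean total density are exactly preserved;
#' `"single-peak"` adds a zero-spatial-mean Gaussian bump to the membrane
#' profile (total mass exactly preserved) and relaxes it without flow until
#' the profile is stationary (relative sup-norm change per 10 s below
#' `1e-8`), yielding the stationary one-peak pattern used as the starting
#' point of flow protocols.
#'
#' @param sys a [system_params()].
#' @param kind `"homogeneous-noise"` or `"single-peak"`.
#' @param amplitude noise standard deviation, or bump height (1/um). Default
#'   `1e-3 * n_bar` for noise and `n_bar / 5` for the bump.
#' @param seed RNG seed (noise only); same seed gives bit-identical fields.
#' @param width bump width parameter (um), single-peak only.
#' @param center bump center (um), single-peak only; default `L/2`.
#' @param relax_max maximum relaxation time (s) before giving up with a
#'   warning, single-peak only.
#' @return A [polarity_field()] at `t = 0`.
#' @export
make_initial <- function(sys, kind = c("homogeneous-noise", "single-peak"),
                         amplitude = NULL, seed = NULL,
                         width = sys$L / 20, center = sys$L / 2,
                         relax_max = 2000) {
  kind <- match.arg(kind)
  st <- homogeneous_state(sys$n_bar, sys$reaction)
  x <- grid_centers(sys)
  if (kind == "homogeneous-noise") {
    amplitude <- amplitude %||% (1e-3 * sys$n_bar)
    stopifnot(amplitude >= 0)
    xi <- numeric(sys$N)
    if (amplitude > 0) {
      if (!is.null(seed)) {
        old <- get0(".Random.seed", envir = globalenv())
        on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
      }
      xi <- rnorm(sys$N, 0, amplitude)
      xi <- xi - mean(xi)
    }
    m <- st$m_star + xi
    c <- st$c_star - xi
    if (any(m < 0) || any(c < 0)) {
      abort("noise amplitude drives concentrations negative; reduce it")
    }
    return(polarity_field(x, m, c, t = 0))
  }
  # single-peak: mass-neutral bump on m, relaxed to stationarity without flow
  amplitude <- amplitude %||% (sys$n_bar / 5)
  stopifnot(amplitude >= 0)
  bump <- amplitude * exp(-((x - center) / width)^2)
  bump <- bump - mean(bump)
  m <- st$m_star + bump
  c <- rep(st$c_star, sys$N)
  if (any(m < 0)) abort("bump amplitude drives m negative; reduce it")
  sys0 <- sys
  sys0$flow <- flow_profile("uniform", vf = 0)
  fld <- polarity_field(x, m, c, t = 0)
  elapsed <- 0
  repeat {
    sim <- simulate_polarity(fld, sys0, t_end = 10, save_every = 10)
    new <- final_field(sim)
    delta <- max(abs(new$m - fld$m)) / max(abs(fld$m))
    fld <- polarity_field(new$x, new$m, new$c, t = 0)
    elapsed <- elapsed + 10
    if (delta < 1e-8) break
    if (elapsed >= relax_max) {
      warn(sprintf("single-peak relaxation not stationary after %g s (last change %.3g)",
                   elapsed, delta))
      break
    }
  }
  fld
}

#' Integrate the polarity model
#'
#' Method-of-lines integration of [polarity_rhs()] with the stiff sparse
#' solver `deSolve::lsodes` (relative tolerance `1e-8`, absolute `1e-10` by
#' default). A flow onset `t0` inside `(0, t_end)` is handled by splitting
#' the integration at `t0`, so the discontinuity never sits inside a solver
#' step. Saved fields are clamped at zero; undershoot beyond `-1e-12` is
#' reported as a warning. The mean total density at every saved time is
#' recorded as the mass ledger.
#'
#' @param init a [polarity_field()] (see [make_initial()]); its `t` is taken
#'   as the start time.
#' @param sys a [system_params()].
#' @param t_end integration end time (s), relative to `init$t`.
#' @param save_every spacing of saved snapshots (s).
#' @param scheme advective face scheme, see [polarity_rhs()].
#' @param rtol,atol solver tolerances.
#' @param seed echoed into the result for provenance (the integration itself
#'   is deterministic).
#' @return An object of class `polar_sim`: saved `times`, matrices `m`, `c`
#'   (time by cell), `x`, the mass ledger `n_bar_series`, `sys`, and solver
#'   diagnostics.
#' @examples
#' sys <- system_params(N = 64)
#' sim <- simulate_polarity(make_initial(sys, "homogeneous-noise", seed = 1),
#'                          sys, t_end = 1, save_every = 1)
#' @export
simulate_polarity <- function(init, sys, t_end, save_every = t_end / 100,
                              scheme = c("upwind", "central"),
                              rtol = 1e-8, atol = 1e-10, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(t_end > 0, length(init$m) == sys$N)
  t_start <- init$t
  times <- unique(c(seq(t_start, t_start + t_end, by = save_every),
                    t_start + t_end))
  t0 <- sys$flow$t0
  vface_on <- flow_velocity(sys$flow, grid_faces(sys), sys$L, t = Inf)
  deriv <- function(t, y, parms) {
    N <- sys$N
    list(rhs_core(y[seq_len(N)], y[N + seq_len(N)], sys, parms$vface, scheme))
  }
  y0 <- c(init$m, init$c)
  run_segment <- function(y, ts, vface) {
    if (length(ts) < 2) return(matrix(c(ts, y), nrow = 1))
    out <- deSolve::ode(y, ts, deriv, parms = list(vface = vface),
                        method = "lsodes", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      abort(sprintf("stiff integration failed near t = %g (istate = %d)",
                    out[nrow(out), 1], attr(out, "istate")[1]))
    }
    out
  }
  if (t0 > t_start && t0 < t_start + t_end) {
    ts1 <- unique(c(times[times <= t0], t0))
    ts2 <- unique(c(t0, times[times > t0]))
    out1 <- run_segment(y0, ts1, 0 * vface_on)
    out2 <- run_segment(out1[nrow(out1), -1], ts2, vface_on)
    keep1 <- ts1 %in% times
    out <- rbind(out1[keep1, , drop = FALSE],
                 out2[ts2 > t0, , drop = FALSE])
  } else {
    vface <- if (t0 <= t_start) vface_on else 0 * vface_on
    out <- run_segment(y0, times, vface)
  }
  N <- sys$N
  tt <- out[, 1]
  m <- out[, 1 + seq_len(N), drop = FALSE]
  c <- out[, 1 + N + seq_len(N), drop = FALSE]
  undershoot <- min(m, c)
  if (undershoot < -1e-12) {
    warn(sprintf("negative concentrations clamped (worst undershoot %.3g)", undershoot))
  }
  m[m < 0] <- 0
  c[c < 0] <- 0
  structure(
    list(times = tt, x = grid_centers(sys), m = m, c = c,
         n_bar_series = rowMeans(m + c), sys = sys, scheme = scheme,
         seed = seed),
    class = "polar_sim"
  )
}

#' @export
print.polar_sim <- function(x, ...) {
  drift <- max(abs(x$n_bar_series - x$n_bar_series[1])) / x$n_bar_series[1]
  cat(sprintf(
    "<polar_sim> t in [%g, %g] s (%d saves), N=%d cells | mass drift %.2e\n",
    min(x$times), max(x$times), length(x$times), length(x$x), drift))
  invisible(x)
}

#' @export
tidy.polar_sim <- function(x, ...) {
  tt <- rep(x$times, each = length(x$x))
  xx <- rep(x$x, times = length(x$times))
  mm <- as.vector(t(x$m))
  cc <- as.vector(t(x$c))
  tibble::tibble(t = tt, x = xx, m = mm, c = cc)
}

#' @export
glance.polar_sim <- function(x, ...) {
  tibble::tibble(
    t_start = min(x$times), t_end = max(x$times), n_saves = length(x$times),
    N = length(x$x), L = x$sys$L, boundary = x$sys$boundary,
    mass_drift = max(abs(x$n_bar_series - x$n_bar_series[1])) / x$n_bar_series[1]
  )
}

#' Extract one saved snapshot of a simulation
#'
#' @param sim a `polar_sim`.
#' @param t requested time (s); the nearest saved time is used.
#' @return A [polarity_field()].
#' @export
field_at <- function(sim, t) {
  i <- which.min(abs(sim$times - t))
  polarity_field(sim$x, sim$m[i, ], sim$c[i, ], t = sim$times[i])
}

#' @rdname field_at
#' @export
final_field <- function(sim) field_at(sim, max(sim$times))

#' Relative mass drift of a simulation
#'
#' Largest relative deviation of the mean total density from its initial
#' value across all saved times; the dynamics conserve it exactly, so this
#' measures integrator error only.
#'
#' @param sim a `polar_sim`.
#' @return A single non-negative number.
#' @export
mass_drift <- function(sim) {
  max(abs(sim$n_bar_series - sim$n_bar_series[1])) / sim$n_bar_series[1]
}
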