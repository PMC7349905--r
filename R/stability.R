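#' Growth rates of spatial modes under uniform flow
#'
#' Linearizing the dynamics about a homogeneous steady state and expanding
#' perturbations in Fourier modes `exp(sigma t + i q x)` yields, for each
#' wavenumber `q`, the eigenvalue problem of the 2x2 complex matrix
#' \deqn{J(q) = \begin{pmatrix} -D_c q^2 - i v_f q - f_c & -f_m \\
#'   f_c & -D_m q^2 + f_m \end{pmatrix}}
#' acting on the perturbation vector `(c, m)`. `dispersion()` returns both
#' eigenvalues at each `q`; the branch with larger real part (the one that
#' decides stability) is `sigma`, the other `sigma_minor`. Ties in the real
#' part are broken toward the larger imaginary part.
#'
#' At `q = 0` the branches are exactly `{0, fm - fc}`: the zero eigenvalue
#' reflects mass conservation (perturbations that change the mean density
#' shift the steady state along the nullcline), while `sigma1 = fm - fc`
#' governs homogeneous stability. Without flow and for homogeneously stable
#' states the spectrum is purely real; uniform flow makes it complex, and the
#' sign of `Im sigma` equals the sign of `vf` on the unstable band, so all
#' growing modes drift upstream with phase velocity `-Im sigma / q`.
#'
#' The linear analysis is defined for spatially uniform flow only; a
#' non-uniform [flow_profile()] in `sys` is rejected unless `vf` is given
#' explicitly.
#'
#' @param q wavenumber(s) (1/um), non-negative; vectorized.
#' @param state a [homogeneous_state()] (or [local_state()]).
#' @param sys a [system_params()].
#' @param vf uniform flow speed (um/s). Defaults to the uniform speed in
#'   `sys$flow`.
#' @return A tibble with complex columns `sigma` (dominant branch) and
#'   `sigma_minor`, plus `q` and the phase velocity `v_phase = -Im(sigma)/q`
#'   (`NA` at `q = 0`).
#' @examples
#' st <- homogeneous_state(5)
#' dispersion(c(0, 1), st, system_params())
#' @export
dispersion <- function(q, state, sys, vf = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  if (any(q < 0)) abort("wavenumbers must be non-negative")
  ev <- vapply(q, function(qi) {
    J <- jacobian_q(qi, state, sys, vf)
    e <- eigen(J, only.values = TRUE)$values
    # dominant first: larger real part, ties toward larger imaginary part
    o <- order(-Re(e), -Im(e))
    e[o]
  }, complex(2))
  tibble::tibble(
    q = q,
    sigma = ev[1, ],
    sigma_minor = ev[2, ],
    v_phase = ifelse(q > 0, -Im(ev[1, ]) / q, NA_real_)
  )
}

# vectorized closed-form eigenvalues (trace/determinant quadratic); used by
# internal band scans where per-q LAPACK calls would dominate the runtime.
# dispersion() itself diagonalizes the Jacobian; the two routes agree to
# rounding and a regression test asserts it.
dispersion_fast <- function(q, state, sys, vf) {
  a11 <- -sys$Dc * q^2 - 1i * vf * q - state$fc
  a22 <- -sys$Dm * q^2 + state$fm
  tr <- a11 + a22
  dt <- a11 * a22 + state$fm * state$fc
  rt <- sqrt(tr^2 / 4 - dt)
  s1 <- tr / 2 + rt
  s2 <- tr / 2 - rt
  swap <- Re(s2) > Re(s1) | (Re(s2) == Re(s1) & Im(s2) > Im(s1))
  dom <- ifelse(swap, s2, s1)
  min_ <- ifelse(swap, s1, s2)
  list(sigma = dom, sigma_minor = min_)
}

jacobian_q <- function(q, state, sys, vf) {
  matrix(c(-sys$Dc * q^2 - 1i * vf * q - state$fc, state$fc,
           -state$fm, -sys$Dm * q^2 + state$fm),
         nrow = 2, ncol = 2)
}

resolve_uniform_vf <- function(sys, vf) {
  if (!is.null(vf)) return(vf)
  if (!is_uniform_flow(sys$flow)) {
    abort(paste0(
      "linear stability analysis is only defined for uniform flow; ",
      "pass an explicit `vf` or use a uniform flow_profile"))
  }
  sys$flow$vf
}

#' Dispersion relation on a wavenumber grid
#'
#' Evaluates [dispersion()] on a composite grid (logarithmic near `q = 0` to
#' resolve the long-wavelength behaviour, linear across the band) and
#' attaches the band diagnostics from [unstable_band()].
#'
#' @inheritParams dispersion
#' @param q optional explicit wavenumber grid; default is 512 points on
#'   `[0, 4 * q_hi]` where `q_hi` estimates the right band edge.
#' @return An object of class `dispersion_result`: the mode table plus fields
#'   `q_max`, `q_star`, `lambda_star` and the parameters used.
#' @export
dispersion_relation <- function(state, sys, vf = NULL, q = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  if (is.null(q)) {
    q_hi <- band_edge_guess(state, sys)
    q <- q_composite_grid(4 * q_hi)
  }
  tab <- dispersion(q, state, sys, vf)
  band <- unstable_band(state, sys, vf)
  structure(
    list(modes = tab, q_max = band$q_max, q_star = band$q_star,
         lambda_star = band$lambda_star, empty = band$empty,
         state = state, sys = sys, vf = vf),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> vf=%g um/s, %d modes\n", x$vf, nrow(x$modes)))
  if (x$empty) {
    cat("  laterally stable: no unstable band\n")
  } else {
    cat(sprintf("  unstable band (0, %.6g] 1/um; q*=%.6g (lambda*=%.6g um)\n",
                x$q_max, x$q_star, x$lambda_star))
  }
  invisible(x)
}

#' @export
tidy.dispersion_result <- function(x, ...) {
  dplyr::mutate(x$modes,
                re_sigma = Re(.data$sigma), im_sigma = Im(.data$sigma),
                sigma = NULL, sigma_minor = NULL)
}

#' @export
glance.dispersion_result <- function(x, ...) {
  tibble::tibble(vf = x$vf, empty_band = x$empty, q_max = x$q_max,
                 q_star = x$q_star, lambda_star = x$lambda_star,
                 s_nc = x$state$s_nc, sigma1 = x$state$sigma1)
}

# rough estimate of the right band edge: in the fast-flow / fast-diffusion
# limit Re sigma ~ fm - Dm q^2, giving q ~ sqrt(fm/Dm); floor at domain scale
band_edge_guess <- function(state, sys) {
  g <- if (state$fm > 0 && sys$Dm > 0) sqrt(state$fm / sys$Dm) else 0
  max(g, 2 * pi / sys$L)
}

q_composite_grid <- function(q_hi, n = 512) {
  n_log <- n %/% 4
  qs <- c(0,
          exp(seq(log(q_hi * 1e-5), log(q_hi * 1e-2), length.out = n_log)),
          seq(q_hi * 1e-2, q_hi, length.out = n - n_log - 1))
  sort(unique(qs))
}

#' Band of laterally unstable modes
#'
#' Locates the unstable band `(0, q_max]` where `Re sigma(q) > 0`, the
#' fastest-growing mode `q_star`, and its wavelength `lambda_star = 2 pi /
#' q_star`. `q_max` is found by a bracketed root-solve of `Re sigma(q) = 0`
#' (tolerance 1e-10), `q_star` by bounded maximization. When the state is
#' laterally stable the band is empty (`empty = TRUE`, `NA` diagnostics) --
#' this is a result, not an error.
#'
#' @inheritParams dispersion
#' @return A list with `empty`, `q_max`, `q_star`, `lambda_star`,
#'   `sigma_star` (the complex growth rate at `q_star`).
#' @export
unstable_band <- function(state, sys, vf = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  re_sig <- function(q) Re(dispersion_fast(q, state, sys, vf)$sigma)
  q_hi <- band_edge_guess(state, sys)
  # dense scan; extend upward if still positive at the top
  for (i in 1:6) {
    qs <- seq(q_hi / 2048, q_hi, length.out = 2048)
    re <- re_sig(qs)
    if (re[length(re)] < 0 || all(re <= 0)) break
    q_hi <- 2 * q_hi
  }
  pos <- which(re > 0)
  if (length(pos) == 0) {
    return(list(empty = TRUE, q_max = NA_real_, q_star = NA_real_,
                lambda_star = NA_real_, sigma_star = NA_complex_))
  }
  i_last <- max(pos)
  if (i_last == length(qs)) {
    warn("Re sigma still positive at the top of the scanned q range; q_max unresolved")
    return(list(empty = FALSE, q_max = NA_real_, q_star = NA_real_,
                lambda_star = NA_real_, sigma_star = NA_complex_))
  }
  q_max <- uniroot(re_sig, c(qs[i_last], qs[i_last + 1]), tol = 1e-10)$root
  opt <- optimize(re_sig, c(qs[1] / 2, q_max), maximum = TRUE, tol = 1e-10)
  q_star <- opt$maximum
  list(empty = FALSE, q_max = q_max, q_star = q_star,
       lambda_star = 2 * pi / q_star,
       sigma_star = dispersion_fast(q_star, state, sys, vf)$sigma)
}

#' Mass-redistribution instability criterion under uniform flow
#'
#' The long-wavelength expansion of the dispersion relation shows that a band
#' of unstable modes opens exactly when the nullcline slope is steeper than a
#' flow-modified threshold:
#' \deqn{s_{nc} < -\frac{D_m}{D_c}\left[1 +
#'   \frac{v_f^2 (1+s_{nc})^2}{D_c f_c}\right]^{-1}.}
#' Without flow this reduces to the diffusion-driven slope criterion
#' `s_nc < -Dm/Dc`; as `|vf|` grows the threshold rises monotonically toward
#' `0^-`, so flow always widens the unstable range, and for sufficiently fast
#' flow the criterion becomes simply `s_nc < 0`, independent of diffusion.
#' The threshold is evaluated in the algebraically equivalent form
#' `-Dm / (Dc + vf^2 (1+s_nc)^2 / fc)`, which remains well-defined for
#' `Dc = 0` with `vf != 0` (flow alone can drive the instability).
#'
#' @inheritParams dispersion
#' @return A list with `unstable` (logical), `threshold` (the critical slope),
#'   `s_nc`, and `vf`.
#' @export
instability_criterion <- function(state, sys, vf = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  if (state$sigma1 >= 0) {
    abort("instability criterion applies to homogeneously stable states (sigma1 < 0)")
  }
  if (sys$Dc == 0 && vf == 0) {
    abort("criterion undefined for Dc = 0 without flow (no cytosolic transport)")
  }
  s <- state$s_nc
  threshold <- -sys$Dm / (sys$Dc + vf^2 * (1 + s)^2 / state$fc)
  list(unstable = s < threshold, threshold = threshold, s_nc = s, vf = vf)
}

#' Long-wavelength expansion of the dispersion relation
#'
#' Second-order expansion about `q = 0` for homogeneously stable states
#' (`s_nc > -1`):
#' \deqn{\sigma(q) \approx -\frac{1}{1+s_{nc}}\left[i s_{nc} v_f q +
#'   (D_m + s_{nc} D_c) q^2 +
#'   \frac{s_{nc} v_f^2}{f_c (1+s_{nc})^2} q^2\right].}
#' The imaginary part is linear in `q`, giving the wavelength-independent
#' long-wavelength phase velocity `vf * s_nc / (1 + s_nc)` (see
#' [long_wavelength_phase_velocity()]); the real part is quadratic, and its
#' sign at small `q` is the band-opening condition of
#' [instability_criterion()].
#'
#' @inheritParams dispersion
#' @return Complex growth rate(s), vectorized over `q`.
#' @export
long_wavelength_sigma <- function(q, state, sys, vf = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  s <- state$s_nc
  if (s <= -1) abort("expansion requires s_nc > -1 (homogeneous stability)")
  -1 / (1 + s) * (1i * s * vf * q + (sys$Dm + s * sys$Dc) * q^2 +
                    s * vf^2 / (state$fc * (1 + s)^2) * q^2)
}

#' Long-wavelength phase velocity
#'
#' `v_phase = vf * s_nc / (1 + s_nc)`, the `q`-independent drift speed of
#' long-wavelength modes. For laterally unstable states (`s_nc < 0 > -1`) it
#' has the opposite sign of `vf`: modes propagate upstream.
#'
#' @inheritParams dispersion
#' @return Phase velocity (um/s).
#' @export
long_wavelength_phase_velocity <- function(state, sys, vf = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  vf * state$s_nc / (1 + state$s_nc)
}

#' Slow-flow propagation coefficient A(q)
#'
#' To lowest order in the flow speed the dispersion relation acquires an
#' imaginary part `Im sigma(q) = vf q^2 A(q)` on top of the flow-free (real)
#' relation. `A(q)` is computed numerically as the central-difference limit
#' `[Im sigma(q; +vf_eps) - Im sigma(q; -vf_eps)] / (2 vf_eps q^2)`; it is
#' positive for every laterally unstable mode, which is the linear-order
#' statement that growing perturbations always propagate against the flow.
#'
#' @param q wavenumber(s) (1/um), strictly positive.
#' @param state a [homogeneous_state()].
#' @param sys a [system_params()].
#' @param vf_eps flow step used for the central difference (um/s).
#' @return `A(q)` (s/um, such that `vf * q^2 * A` is a rate), vectorized.
#' @export
slow_flow_coefficient <- function(q, state, sys, vf_eps = 1e-3) {
  if (any(q <= 0)) abort("q must be strictly positive")
  im_p <- Im(dispersion(q, state, sys, vf = vf_eps)$sigma)
  im_m <- Im(dispersion(q, state, sys, vf = -vf_eps)$sigma)
  (im_p - im_m) / (2 * vf_eps * q^2)
}

#' Fast-flow limit of the dispersion relation
#'
#' For flow fast compared to reactions and cytosolic transport,
#' `sigma(q) ~ fm - Dm q^2 + i fc fm / (vf q)` at nonzero `q`. The real part
#' is independent of both `Dc` and `vf` -- advection makes cytosolic
#' transport effectively instantaneous, as fast diffusion would -- and the
#' phase velocity `-fc fm / (vf q^2)` decays as `1/vf`, so ever-faster flow
#' moves the pattern ever more slowly (opposite to the slow-flow limit, which
#' is why the propagation speed peaks at intermediate flow).
#'
#' @param q wavenumber(s) (1/um), strictly positive.
#' @param state a [homogeneous_state()].
#' @param sys a [system_params()].
#' @param vf flow speed (um/s), nonzero.
#' @return Complex growth rate(s), vectorized over `q`.
#' @export
fast_flow_sigma <- function(q, state, sys, vf) {
  if (any(q <= 0)) abort("q must be strictly positive")
  if (vf == 0) abort("fast-flow limit needs vf != 0")
  state$fm - sys$Dm * q^2 + 1i * state$fc * state$fm / (vf * q)
}

#' Fast-flow phase velocity
#'
#' `-fc fm / (vf q^2)`, the drift speed of modes in the fast-flow limit.
#'
#' @inheritParams fast_flow_sigma
#' @return Phase velocity (um/s), vectorized over `q`.
#' @export
fast_flow_phase_velocity <- function(q, state, sys, vf) {
  -Im(fast_flow_sigma(q, state, sys, vf)) / q
}

#' Membrane--cytosol phase shift of the dominant mode
#'
#' Diagnostic for the spatial offset between the membrane and cytosol
#' components of the dominant eigenmode: the argument of `c_hat / m_hat` for
#' the eigenvector `(c_hat, m_hat)` of the dominant branch. Without flow the
#' eigenvector is real and the shift is 0 (or pi); uniform flow shifts the
#' cytosol profile downstream relative to the membrane profile, and the
#' magnitude of the shift grows with `|vf|` toward a saturation value that
#' this function lets you measure empirically.
#'
#' @inheritParams dispersion
#' @return Phase shift in radians, in `(-pi, pi]`, vectorized over `q`.
#' @export
eigenvector_phase_shift <- function(q, state, sys, vf = NULL) {
  vf <- resolve_uniform_vf(sys, vf)
  vapply(q, function(qi) {
    J <- jacobian_q(qi, state, sys, vf)
    e <- eigen(J)
    k <- order(-Re(e$values), -Im(e$values))[1]
    v <- e$vectors[, k] # (c_hat, m_hat)
    Arg(v[1] / v[2])
  }, numeric(1))
}
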