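#' Reaction rate f(m, c)
#'
#' Net attachment flux `f(m, c) = a(m) c - d(m) m` (1/(um s)). Positive values
#' mean net transfer from the cytosol to the membrane. Vectorized over `m`
#' and `c`.
#'
#' @param m membrane concentration (1/um), non-negative.
#' @param c cytosolic concentration (1/um), non-negative.
#' @param p a [reaction_params()].
#' @return Numeric vector of reaction rates.
#' @examples
#' reaction_rate(0, 1, reaction_params()) # pure attachment: kon
#' @export
reaction_rate <- function(m, c, p = reaction_params()) {
  if (any(m < 0) || any(c < 0)) {
    abort("concentrations must be non-negative")
  }
  attach_rate(m, p) * c - detach_rate(m, p) * m
}

#' Partial derivatives of the reaction rate
#'
#' Closed-form partials `fm = df/dm` and `fc = df/dc` at given concentrations:
#' `fm = a'(m) c - d'(m) m - d(m)`, `fc = a(m)`. For attachment--detachment
#' kinetics `fc > 0` everywhere.
#'
#' @inheritParams reaction_rate
#' @return A tibble with columns `fm`, `fc` (1/s).
#' @export
reaction_partials <- function(m, c, p = reaction_params()) {
  if (any(m < 0) || any(c < 0)) {
    abort("concentrations must be non-negative")
  }
  tibble::tibble(
    fm = attach_rate_deriv(m, p) * c - detach_rate_deriv(m, p) * m -
      detach_rate(m, p),
    fc = attach_rate(m, p)
  )
}

#' Reactive nullcline
#'
#' Solves `f(m, c) = 0` for the cytosolic concentration:
#' `c_nc(m) = d(m) m / a(m)`. Local reactive equilibria lie on this curve;
#' its slope relative to the flux-balance-subspace slope `-Dm/Dc` decides
#' lateral (mass-redistribution) instability.
#'
#' @param m membrane concentration (1/um), non-negative; vectorized.
#' @param p a [reaction_params()].
#' @return Cytosolic concentration on the nullcline (1/um).
#' @examples
#' nullcline_c(1, reaction_params()) # (koff * 1 / (KD + 1)) / (kon + kfb) = 0.5
#' @export
nullcline_c <- function(m, p = reaction_params()) {
  if (any(m < 0)) abort("m must be non-negative")
  detach_rate(m, p) * m / attach_rate(m, p)
}

#' Analytic slope of the reactive nullcline
#'
#' `dc/dm` along `c_nc(m)`. By the implicit-function theorem this equals
#' `-fm/fc` evaluated on the nullcline, the quantity denoted `s_nc` whose
#' comparison to `-Dm/Dc` (and its flow-modified generalization) controls
#' lateral instability.
#'
#' @inheritParams nullcline_c
#' @return Dimensionless slope, vectorized over `m`.
#' @export
nullcline_slope <- function(m, p = reaction_params()) {
  c_nc <- nullcline_c(m, p)
  pd <- reaction_partials(m, c_nc, p)
  -pd$fm / pd$fc
}

#' Homogeneous steady state
#'
#' Solves `f(m*, c*) = 0` with `m* + c* = n_bar` by bracketed root-finding of
#' `g(m) = a(m) (n_bar - m) - d(m) m` on `[0, n_bar]`, and attaches the
#' linearization at the state: partials `fm`, `fc`, nullcline slope
#' `s_nc = -fm/fc`, and the homogeneous eigenvalue `sigma1 = fm - fc` (the
#' other homogeneous eigenvalue is exactly 0, reflecting mass conservation).
#' The state is homogeneously stable when `sigma1 < 0`, equivalently
#' `s_nc > -1`.
#'
#' If several roots exist (possible for general kinetics), the smallest-`m`
#' root -- the branch continuously connected to `(0, 0)` as `n_bar` grows --
#' is returned and a warning lists all roots.
#'
#' @param n_bar mean total density (1/um), non-negative.
#' @param p a [reaction_params()].
#' @return An object of class `homogeneous_state`: a list with fields
#'   `n_bar`, `m_star`, `c_star`, `fm`, `fc`, `s_nc`, `sigma1`.
#' @examples
#' st <- homogeneous_state(5)
#' st$s_nc # about -0.0398: steeper than -Dm/Dc = -0.001, laterally unstable
#' @export
homogeneous_state <- function(n_bar, p = reaction_params()) {
  stopifnot(is.numeric(n_bar), length(n_bar) == 1, n_bar >= 0)
  if (n_bar == 0) {
    m_star <- 0
  } else {
    g <- function(m) attach_rate(m, p) * (n_bar - m) - detach_rate(m, p) * m
    roots <- find_roots(g, 0, n_bar)
    if (length(roots) == 0) {
      abort(sprintf(
        "no homogeneous steady state bracketed in [0, %g]: g(0)=%g, g(n_bar)=%g",
        n_bar, g(0), g(n_bar)))
    }
    if (length(roots) > 1) {
      warn(sprintf("multiple homogeneous steady states at n_bar=%g (m* = %s); using the smallest",
                   n_bar, paste(signif(roots, 6), collapse = ", ")))
    }
    m_star <- min(roots)
  }
  c_star <- n_bar - m_star
  pd <- reaction_partials(m_star, c_star, p)
  new_homogeneous_state(n_bar, m_star, c_star, pd$fm, pd$fc)
}

new_homogeneous_state <- function(n_bar, m_star, c_star, fm, fc) {
  structure(
    list(n_bar = n_bar, m_star = m_star, c_star = c_star,
         fm = fm, fc = fc, s_nc = -fm / fc, sigma1 = fm - fc),
    class = "homogeneous_state"
  )
}

#' Linearization at an arbitrary on-nullcline composition
#'
#' Builds a `homogeneous_state`-like object from a local composition
#' `(m, c)`. Used to evaluate the dispersion relation at the local reactive
#' equilibrium of a spatial point (e.g. a pattern's inflection point), where
#' the local total density `m + c` differs from the system mean.
#'
#' @param m,c local concentrations (1/um).
#' @param p a [reaction_params()].
#' @return An object of class `homogeneous_state` with `n_bar = m + c`.
#' @export
local_state <- function(m, c, p = reaction_params()) {
  pd <- reaction_partials(m, c, p)
  new_homogeneous_state(m + c, m, c, pd$fm, pd$fc)
}

#' @export
print.homogeneous_state <- function(x, ...) {
  cat(sprintf(
    "<homogeneous_state> n_bar=%g: m*=%.6g, c*=%.6g | fm=%.6g, fc=%.6g, s_nc=%.6g, sigma1=%.6g\n",
    x$n_bar, x$m_star, x$c_star, x$fm, x$fc, x$s_nc, x$sigma1))
  invisible(x)
}

#' @export
tidy.homogeneous_state <- function(x, ...) {
  tibble::tibble(n_bar = x$n_bar, m_star = x$m_star, c_star = x$c_star,
                 fm = x$fm, fc = x$fc, s_nc = x$s_nc, sigma1 = x$sigma1)
}

#' Local reactive equilibria along a total-density profile
#'
#' Vectorized [homogeneous_state()]: for each local total density `n(x)` the
#' local equilibrium concentrations `m*(n)`, `c*(n)` and the nullcline slope
#' `s_nc(n)` there. Continuation is monotone in `n` (the smallest-root branch
#' is followed throughout; no branch jumping).
#'
#' @param n vector of total densities (1/um), non-negative.
#' @param p a [reaction_params()].
#' @return A tibble with columns `n`, `m_star`, `c_star`, `fm`, `fc`, `s_nc`.
#' @export
local_equilibria <- function(n, p = reaction_params()) {
  if (any(n < 0)) abort("total densities must be non-negative")
  states <- purrr::map(n, function(ni) tidy(homogeneous_state(ni, p)))
  out <- dplyr::bind_rows(states)
  dplyr::rename(out, n = "n_bar")
}

# all sign-change roots of g on [lo, hi], polished by uniroot
find_roots <- function(g, lo, hi, n_scan = 400, tol = 1e-14) {
  xs <- seq(lo, hi, length.out = n_scan)
  gs <- vapply(xs, g, numeric(1))
  roots <- xs[gs == 0]
  idx <- which(gs[-1] * gs[-n_scan] < 0)
  for (i in idx) {
    r <- uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root
    roots <- c(roots, r)
  }
  sort(unique(roots))
}
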