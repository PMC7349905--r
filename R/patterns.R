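#' Track the pattern peak through a simulation
#'
#' Sub-grid peak positions by parabolic interpolation through the maximum of
#' `m` and its two neighbours at every saved time, unwrapped across the
#' periodic boundary, and the propagation speed `v_p` as the slope of a
#' least-squares line over the window. Steady propagation is declared when
#' the relative spread of instantaneous speeds is below 2%. Frames with more
#' than one prominent peak are flagged and `v_p` is withheld.
#'
#' @param sim a `polar_sim`.
#' @param window numeric length-2 time range (s); default the full run.
#' @return An object of class `peak_track` with a position table and the
#'   fitted speed; see [glance.peak_track()].
#' @export
track_peak <- function(sim, window = range(sim$times)) {
  keep <- sim$times >= window[1] & sim$times <= window[2]
  if (sum(keep) < 3) abort("window contains fewer than 3 saved frames")
  tt <- sim$times[keep]
  M <- sim$m[keep, , drop = FALSE]
  N <- ncol(M)
  dx <- sim$sys$L / N
  periodic <- sim$sys$boundary == "periodic"
  pos <- numeric(length(tt))
  npeaks <- integer(length(tt))
  for (k in seq_along(tt)) {
    m <- M[k, ]
    i <- which.max(m)
    il <- if (i == 1) N else i - 1
    ir <- if (i == N) 1 else i + 1
    if (!periodic && (i == 1 || i == N)) {
      pos[k] <- sim$x[i]
    } else {
      denom <- m[il] - 2 * m[i] + m[ir]
      delta <- if (denom < 0) 0.5 * (m[il] - m[ir]) / denom else 0
      pos[k] <- sim$x[i] + delta * dx
    }
    # prominent local maxima above the half-amplitude level
    lev <- min(m) + 0.5 * (max(m) - min(m))
    ml <- if (periodic) c(m[N], m[-N]) else c(-Inf, m[-N])
    mr <- if (periodic) c(m[-1], m[1]) else c(m[-1], -Inf)
    npeaks[k] <- sum(m > ml & m >= mr & m > lev)
  }
  if (periodic) {
    d <- diff(pos)
    L <- sim$sys$L
    d <- ((d + L / 2) %% L) - L / 2
    pos <- pos[1] + c(0, cumsum(d))
  }
  multi <- any(npeaks > 1)
  fit <- lm(pos ~ tt)
  v_p <- unname(coef(fit)[2])
  # a stationary peak gives an (expected) essentially perfect constant fit
  v_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  vinst <- diff(pos) / diff(tt)
  spread <- if (abs(mean(vinst)) > 0) {
    (max(vinst) - min(vinst)) / abs(mean(vinst))
  } else {
    Inf
  }
  structure(
    list(positions = tibble::tibble(t = tt, position = pos, n_peaks = npeaks),
         v_p = if (multi) NA_real_ else v_p,
         v_p_stderr = v_se, steady = is.finite(spread) && spread < 0.02,
         spread = spread, multi_peak = multi, window = window),
    class = "peak_track"
  )
}

#' @export
print.peak_track <- function(x, ...) {
  cat(sprintf("<peak_track> %d frames in [%g, %g] s\n",
              nrow(x$positions), x$window[1], x$window[2]))
  if (x$multi_peak) {
    cat("  multiple peaks detected; v_p withheld\n")
  } else {
    cat(sprintf("  v_p = %.6g um/s (se %.2g), steady: %s\n",
                x$v_p, x$v_p_stderr, x$steady))
  }
  invisible(x)
}

#' @export
tidy.peak_track <- function(x, ...) x$positions

#' @describeIn track_peak one-row summary: `v_p`, its standard error, the
#'   steadiness flag and the multi-peak flag.
#' @param x a `peak_track`.
#' @param ... unused.
#' @export
glance.peak_track <- function(x, ...) {
  tibble::tibble(v_p = x$v_p, v_p_stderr = x$v_p_stderr, steady = x$steady,
                 spread = x$spread, multi_peak = x$multi_peak)
}

circ_delta <- function(x, ref, L) ((x - ref + L / 2) %% L) - L / 2

#' Phase-plane trajectory of a pattern
#'
#' Maps a concentration profile to the ordered `(m, c)` point sequence in the
#' phase plane and extracts the loop diagnostics: the signed shoelace area
#' enclosed by the trajectory, the cytosolic concentrations `cL` / `cR` where
#' the trajectory crosses the reactive nullcline on the upstream /
#' downstream flank of the peak, and the deviation from the flux-balance
#' subspace (FBS) -- the line of slope `-Dm/Dc` that contains every
#' stationary no-flow pattern. With flow the cytosol profile is shifted
#' downstream relative to the membrane profile, the trajectory opens into a
#' loop, and `cL - cR > 0` for `vf > 0`; this attachment asymmetry is what
#' propels the peak upstream.
#'
#' Nullcline crossings are located by sign change of
#' `c(x) - c_nc(m(x))` with linear interpolation; on each flank the crossing
#' nearest the peak is used. For `vf = 0` the "upstream" flank is taken to be
#' the left one.
#'
#' @param field a [polarity_field()] holding a single-peak pattern.
#' @param sys a [system_params()].
#' @param vf flow speed used to orient the flanks; default taken from
#'   `sys$flow` (uniform) or its sign at the peak (parabolic).
#' @return An object of class `phase_trajectory` with fields `points`
#'   (tibble `x`, `m`, `c`), `loop_area`, `cL`, `cR`, `fbs_slope`,
#'   `fbs_max_dev` (max point distance from the best-fit FBS line, relative
#'   to the trajectory extent).
#' @export
phase_trajectory <- function(field, sys, vf = NULL) {
  m <- field$m; c <- field$c; x <- field$x
  N <- length(m)
  if (is.null(vf)) {
    vf <- if (is_uniform_flow(sys$flow)) sys$flow$vf else {
      flow_velocity(sys$flow, x[which.max(m)], sys$L, t = Inf)
    }
  }
  g <- c - nullcline_c(m, sys$reaction)
  periodic <- sys$boundary == "periodic"
  i2 <- if (periodic) c(2:N, 1) else 2:N
  i1 <- if (periodic) 1:N else 1:(N - 1)
  cross <- which(g[i1] * g[i2] < 0)
  if (length(cross) < 2) {
    abort("fewer than two nullcline crossings: pattern too weak for loop analysis")
  }
  s <- g[i1][cross] / (g[i1][cross] - g[i2][cross])
  xm <- x[i1][cross]; xp <- x[i2][cross]
  if (periodic) xp[xp < xm] <- xp[xp < xm] + sys$L
  x_cross <- (xm + s * (xp - xm)) %% sys$L
  m_cross <- m[i1][cross] + s * (m[i2][cross] - m[i1][cross])
  c_cross <- c[i1][cross] + s * (c[i2][cross] - c[i1][cross])
  x_peak <- x[which.max(m)]
  d <- if (periodic) circ_delta(x_cross, x_peak, sys$L) else x_cross - x_peak
  upstream_sign <- if (vf >= 0) -1 else 1 # flow to the right: upstream is left
  up <- which(sign(d) == upstream_sign)
  dn <- which(sign(d) == -upstream_sign)
  if (length(up) == 0 || length(dn) == 0) {
    abort("no nullcline crossing on one flank of the peak")
  }
  cL <- unname(c_cross[up[which.min(abs(d[up]))]])
  cR <- unname(c_cross[dn[which.min(abs(d[dn]))]])
  # signed shoelace area of the closed (m, c) polygon in x order
  mm <- m; cc <- c
  area <- 0.5 * sum(mm * c(cc[-1], cc[1]) - c(mm[-1], mm[1]) * cc)
  fbs_slope <- -sys$Dm / sys$Dc
  b <- mean(cc - fbs_slope * mm)
  dist <- abs(cc - fbs_slope * mm - b) / sqrt(1 + fbs_slope^2)
  extent <- sqrt(diff(range(mm))^2 + diff(range(cc))^2)
  structure(
    list(points = tibble::tibble(x = x, m = m, c = c),
         loop_area = area, cL = cL, cR = cR,
         crossings = tibble::tibble(x = x_cross, m = m_cross, c = c_cross),
         fbs_slope = fbs_slope, fbs_intercept = b,
         fbs_max_dev = max(dist) / extent, vf = vf),
    class = "phase_trajectory"
  )
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf(
    "<phase_trajectory> %d points | loop area %.4g, cL=%.5g, cR=%.5g, max FBS dev %.3g\n",
    nrow(x$points), x$loop_area, x$cL, x$cR, x$fbs_max_dev))
  invisible(x)
}

#' @export
tidy.phase_trajectory <- function(x, ...) x$points

#' @export
glance.phase_trajectory <- function(x, ...) {
  tibble::tibble(loop_area = x$loop_area, cL = x$cL, cR = x$cR,
                 dcLR = x$cL - x$cR, fbs_slope = x$fbs_slope,
                 fbs_max_dev = x$fbs_max_dev, vf = x$vf)
}

#' Linear-stability prediction of the peak speed
#'
#' Predicts the propagation speed of a single-peak pattern from the phase
#' velocity of the longest unstable wavelength, `-Im sigma(q_max) / q_max`,
#' evaluated at the composition of the pattern's inflection point. The
#' inflection point of a stationary no-flow pattern sits at the middle
#' intersection of the flux-balance subspace with the reactive nullcline, so
#' that composition is extracted from the supplied reference pattern, turned
#' into a local linearization, and the band edge `q_max` is computed there
#' for the requested flow speed.
#'
#' @param ref_field a stationary no-flow [polarity_field()] (single peak)
#'   that anchors the FBS line.
#' @param sys a [system_params()].
#' @param vf flow speed (um/s) at which to predict.
#' @return A list: `v_p_pred` (um/s), the inflection composition
#'   `m_infl`, `c_infl`, and `q_max` there. `v_p_pred` is `NA` (with a
#'   warning) if the local band is empty.
#' @export
predict_vp_lsa <- function(ref_field, sys, vf) {
  fbs_slope <- -sys$Dm / sys$Dc
  b <- mean(ref_field$c - fbs_slope * ref_field$m)
  h <- function(m) nullcline_c(m, sys$reaction) - (b + fbs_slope * m)
  roots <- find_roots(h, 0, 1.5 * max(ref_field$m), n_scan = 1000)
  if (length(roots) < 2) {
    abort("fewer than two FBS-nullcline intersections; cannot locate the inflection composition")
  }
  m_i <- roots[2] # low plateau first, inflection second
  c_i <- nullcline_c(m_i, sys$reaction)
  st <- local_state(m_i, c_i, sys$reaction)
  band <- unstable_band(st, sys, vf = vf)
  if (band$empty) {
    warn("empty unstable band at the inflection composition; no speed prediction")
    return(list(v_p_pred = NA_real_, m_infl = m_i, c_infl = c_i,
                q_max = NA_real_))
  }
  sig <- dispersion(band$q_max, st, sys, vf = vf)$sigma
  list(v_p_pred = -Im(sig) / band$q_max, m_infl = m_i, c_infl = c_i,
       q_max = band$q_max)
}

#' Classify a steady-state pattern as homogeneous, mesa, or peak
#'
#' A mesa pattern has low- and high-density plateaus joined by interfaces and
#' its amplitude is set by the reactive balance: the top plateau sits at the
#' upper intersection of the flux-balance subspace with the reactive
#' nullcline, i.e. the composition at the pattern maximum is a local reactive
#' equilibrium. A peak is two interfaces concatenated directly: attachment
#' never saturates, the upper intersection is out of reach, and the amplitude
#' is limited by the total mass available -- the composition at the top is
#' far from reactive equilibrium (the curvature term balances a finite net
#' attachment flux). The classifier therefore labels a non-homogeneous
#' pattern `mesa` when the relative reactive imbalance at the top,
#' `|f(m, c)| / (d(m) m)` evaluated at the pattern maximum, is below
#' `eq_tol`, and `peak` otherwise; this works unchanged under flow, where
#' the cytosol profile flattens and the effective resupply line in the phase
#' plane is shallower than the no-flow FBS. The profile is `homogeneous`
#' when the amplitude `max(m) - min(m)` is below `homog_tol * n_bar`.
#'
#' Geometric shape diagnostics are always reported alongside the label: the
#' width of the contiguous top band (`m` within `top_band` of the amplitude
#' below the maximum) and the interface width (10--90% amplitude rise
#' distance, averaged over both flanks).
#'
#' @param field a [polarity_field()] at steady state.
#' @param sys a [system_params()].
#' @param eq_tol relative reactive imbalance at the pattern top below which
#'   the top counts as a saturated (mesa) plateau; default 0.1.
#' @param top_band top-band depth as a fraction of the amplitude (default
#'   0.05), diagnostics only.
#' @param homog_tol homogeneity threshold as a fraction of `n_bar` (default
#'   1e-3).
#' @return An object of class `pattern_class`: `label`, `amplitude`,
#'   `top_imbalance`, `plateau_fraction`, `plateau_width`,
#'   `interface_width`.
#' @export
classify_pattern <- function(field, sys, eq_tol = 0.1, top_band = 0.05,
                             homog_tol = 1e-3) {
  m <- field$m
  N <- length(m)
  dx <- sys$L / N
  amp <- max(m) - min(m)
  if (amp < homog_tol * sys$n_bar) {
    return(new_pattern_class("homogeneous", amp, 0, 0, 0, NA_real_))
  }
  i <- which.max(m)
  p <- sys$reaction
  rel_imbalance <- abs(reaction_rate(m[i], field$c[i], p)) /
    (detach_rate(m[i], p) * m[i])
  top <- m >= max(m) - top_band * amp
  plateau_cells <- longest_run(top, periodic = sys$boundary == "periodic")
  iw <- interface_width(field, sys)
  label <- if (rel_imbalance < eq_tol) "mesa" else "peak"
  new_pattern_class(label, amp, rel_imbalance, sum(top) / N,
                    plateau_cells * dx, iw)
}

new_pattern_class <- function(label, amplitude, top_imbalance,
                              plateau_fraction, plateau_width,
                              interface_width) {
  structure(
    list(label = label, amplitude = amplitude, top_imbalance = top_imbalance,
         plateau_fraction = plateau_fraction, plateau_width = plateau_width,
         interface_width = interface_width),
    class = "pattern_class"
  )
}

#' @export
print.pattern_class <- function(x, ...) {
  cat(sprintf(
    "<pattern_class> %s | amplitude %.4g, top imbalance %.3g, plateau %.4g um (%.1f%% of domain), interface %.4g um\n",
    x$label, x$amplitude, x$top_imbalance, x$plateau_width,
    100 * x$plateau_fraction, x$interface_width))
  invisible(x)
}

#' @export
tidy.pattern_class <- function(x, ...) {
  tibble::tibble(label = x$label, amplitude = x$amplitude,
                 top_imbalance = x$top_imbalance,
                 plateau_fraction = x$plateau_fraction,
                 plateau_width = x$plateau_width,
                 interface_width = x$interface_width)
}

longest_run <- function(flag, periodic = FALSE) {
  if (!any(flag)) return(0L)
  if (all(flag)) return(length(flag))
  r <- rle(flag)
  runs <- r$lengths[r$values]
  best <- max(runs)
  if (periodic && flag[1] && flag[length(flag)]) {
    wrap <- r$lengths[1] + r$lengths[length(r$lengths)]
    best <- max(best, wrap)
  }
  as.integer(best)
}

# 10-90% amplitude rise distance, averaged over the two flanks of the peak
interface_width <- function(field, sys) {
  m <- field$m
  N <- length(m)
  dx <- sys$L / N
  periodic <- sys$boundary == "periodic"
  lo <- min(m) + 0.1 * (max(m) - min(m))
  hi <- min(m) + 0.9 * (max(m) - min(m))
  ip <- which.max(m)
  walk <- function(step) {
    x_hi <- NA_real_; x_lo <- NA_real_
    i <- ip
    for (k in seq_len(N)) {
      j <- i + step
      if (periodic) j <- ((j - 1) %% N) + 1 else if (j < 1 || j > N) break
      if (is.na(x_hi) && m[j] <= hi && m[i] > hi) {
        x_hi <- (k - 1) + (m[i] - hi) / (m[i] - m[j])
      }
      if (m[j] <= lo && m[i] > lo) {
        x_lo <- (k - 1) + (m[i] - lo) / (m[i] - m[j])
        break
      }
      i <- j
    }
    if (is.na(x_hi) || is.na(x_lo)) NA_real_ else (x_lo - x_hi) * dx
  }
  w <- c(walk(-1L), walk(1L))
  if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
}

#' Laterally unstable range of total densities
#'
#' Scans the total density, evaluates the nullcline slope of the local
#' equilibrium via [local_equilibria()], and returns the maximal contiguous
#' interval where the flow-modified instability criterion
#' ([instability_criterion()]) holds, with edges refined by bracketed
#' root-finding. Flow widens this interval. The interval may be empty (e.g.
#' `Dm = Dc` without flow requires `s_nc < -1`, excluded by homogeneous
#' stability), and the upper edge is reported as open when the criterion
#' still holds at `n_max`.
#'
#' @param sys a [system_params()].
#' @param vf uniform flow speed (um/s); default 0 (the diffusion-driven
#'   criterion `s_nc < -Dm/Dc`).
#' @param n_max upper end of the scanned density range (1/um).
#' @param n_grid number of scan points.
#' @return A list: `empty`, `n_minus`, `n_plus`, `open_above` (TRUE when the
#'   interval is cut off at `n_max`).
#' @export
unstable_density_range <- function(sys, vf = 0, n_max = 4 * sys$n_bar,
                                   n_grid = 200) {
  crit_at <- function(n) {
    st <- homogeneous_state(n, sys$reaction)
    if (st$sigma1 >= 0) return(NA_real_) # homogeneously unstable: excluded
    st$s_nc - instability_criterion(st, sys, vf = vf)$threshold
  }
  ns <- seq(n_max / n_grid, n_max, length.out = n_grid)
  h <- vapply(ns, crit_at, numeric(1))
  unstable <- !is.na(h) & h < 0
  if (!any(unstable)) {
    return(list(empty = TRUE, n_minus = NA_real_, n_plus = NA_real_,
                open_above = FALSE))
  }
  r <- rle(unstable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  k <- runs[which.max(r$lengths[runs])]
  i0 <- starts[k]; i1 <- ends[k]
  refine <- function(ia, ib) {
    uniroot(crit_at, c(ns[ia], ns[ib]), tol = 1e-10)$root
  }
  n_minus <- if (i0 > 1 && !is.na(h[i0 - 1])) refine(i0 - 1, i0) else ns[i0]
  open_above <- i1 == n_grid
  n_plus <- if (!open_above && !is.na(h[i1 + 1])) refine(i1, i1 + 1) else ns[i1]
  list(empty = FALSE, n_minus = n_minus, n_plus = n_plus,
       open_above = open_above)
}

#' Detect a regional lateral instability
#'
#' Marks the cells whose local total density `n(x) = m + c` lies inside the
#' laterally unstable density range (no-flow criterion, as the regional
#' argument compares the nullcline slope with the FBS slope `-Dm/Dc`), and
#' raises the trigger flag when a contiguous marked region is wider than the
#' shortest unstable wavelength `2 pi / q_max` evaluated at the region's mean
#' composition -- a region narrower than the shortest unstable mode cannot
#' host the instability.
#'
#' @param field a [polarity_field()].
#' @param sys a [system_params()].
#' @param range optional precomputed [unstable_density_range()] result
#'   (computed at `vf = 0` when omitted).
#' @return A list: `mask` (logical per cell), `regions` (tibble with one row
#'   per contiguous marked region: `x_lo`, `x_hi`, `width`, `lambda_min`,
#'   `trigger`), and `triggered` (any region wide enough).
#' @export
regional_instability <- function(field, sys, range = NULL) {
  rng <- range %||% unstable_density_range(sys, vf = 0)
  n <- field$m + field$c
  if (rng$empty) {
    return(list(mask = rep(FALSE, length(n)),
                regions = empty_region_table(), triggered = FALSE))
  }
  n_plus <- if (rng$open_above) Inf else rng$n_plus
  mask <- n >= rng$n_minus & n <= n_plus
  if (!any(mask)) {
    return(list(mask = mask, regions = empty_region_table(), triggered = FALSE))
  }
  dx <- sys$L / length(n)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ks <- which(r$values)
  rows <- purrr::map(ks, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    width <- (i1 - i0 + 1) * dx
    st <- homogeneous_state(mean(n[i0:i1]), sys$reaction)
    band <- unstable_band(st, sys, vf = 0)
    lam <- if (band$empty) Inf else 2 * pi / band$q_max
    tibble::tibble(x_lo = field$x[i0], x_hi = field$x[i1], width = width,
                   lambda_min = lam, trigger = width > lam)
  })
  regions <- dplyr::bind_rows(rows)
  list(mask = mask, regions = regions, triggered = any(regions$trigger))
}

empty_region_table <- function() {
  tibble::tibble(x_lo = numeric(), x_hi = numeric(), width = numeric(),
                 lambda_min = numeric(), trigger = logical())
}

#' Complex growth rate of one Fourier mode of the membrane profile
#'
#' Fits the early-time evolution of the complex Fourier coefficient of `m` at
#' discrete wavenumber `q_k = 2 pi k / L` (periodic domains): the slope of
#' `log |a_k(t)|` gives the growth rate, the slope of the unwrapped phase the
#' drift `Im sigma`. Used to validate the linear-regime simulation against
#' the dispersion relation.
#'
#' @param sim a `polar_sim` on a periodic domain.
#' @param k mode index (1 = one wavelength per domain).
#' @param window time range of the fit; choose it inside the linear regime
#'   (amplitudes small against the homogeneous state).
#' @return A list: `sigma_hat` (complex, fitted), `q` (1/um), and the
#'   per-frame coefficient table.
#' @export
measure_mode_growth <- function(sim, k, window = range(sim$times)) {
  if (sim$sys$boundary != "periodic") {
    abort("Fourier mode growth is defined for periodic domains")
  }
  keep <- sim$times >= window[1] & sim$times <= window[2]
  if (sum(keep) < 3) abort("window contains fewer than 3 saved frames")
  tt <- sim$times[keep]
  N <- ncol(sim$m)
  a <- apply(sim$m[keep, , drop = FALSE], 1, function(m) fft(m)[k + 1] / N)
  amp <- log(Mod(a))
  ph <- unwrap_phase(Arg(a))
  re <- unname(coef(lm(amp ~ tt))[2])
  im <- unname(coef(lm(ph ~ tt))[2])
  list(sigma_hat = complex(real = re, imaginary = im),
       q = 2 * pi * k / sim$sys$L,
       coefficients = tibble::tibble(t = tt, amplitude = Mod(a), phase = ph))
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- ((d + pi) %% (2 * pi)) - pi
  phi[1] + c(0, cumsum(d))
}

#' Sweep the uniform flow speed and measure the pattern response
#'
#' For each flow speed: start from a shared stationary single-peak state,
#' switch on uniform flow, integrate to steady propagation, and record the
#' peak speed ([track_peak()] over the later half of the run), the
#' phase-plane loop diagnostics ([phase_trajectory()]), and the pattern
#' class. The peak speed is maximal in magnitude at intermediate flow and is
#' proportional to `cL - cR` across the whole sweep.
#'
#' @param sys a [system_params()] (periodic boundary).
#' @param vf_values flow speeds to probe (um/s).
#' @param init optional stationary single-peak [polarity_field()]; computed
#'   by [make_initial()] when omitted.
#' @param t_flow integration time under flow per speed (s).
#' @param measure_from start of the measurement window, as a fraction of
#'   `t_flow`.
#' @param save_every snapshot spacing (s).
#' @return A tibble with one row per flow speed: `vf`, `v_p`, `v_p_stderr`,
#'   `steady`, `cL`, `cR`, `dcLR`, `loop_area`, `label`.
#' @export
sweep_vf <- function(sys, vf_values, init = NULL, t_flow = 120,
                     measure_from = 0.5, save_every = 2) {
  init <- init %||% make_initial(sys, "single-peak")
  rows <- purrr::map(vf_values, function(vf) {
    sys_f <- sys
    sys_f$flow <- flow_profile("uniform", vf = vf)
    sim <- simulate_polarity(init, sys_f, t_end = t_flow,
                             save_every = save_every)
    win <- c(measure_from * t_flow, t_flow)
    trk <- track_peak(sim, window = win)
    fin <- final_field(sim)
    ph <- phase_trajectory(fin, sys_f)
    cls <- classify_pattern(fin, sys_f)
    dplyr::bind_cols(
      tibble::tibble(vf = vf),
      glance(trk)[, c("v_p", "v_p_stderr", "steady")],
      glance(ph)[, c("cL", "cR", "dcLR", "loop_area")],
      tibble::tibble(label = cls$label,
                     c_range = max(fin$c) - min(fin$c))
    )
  })
  dplyr::bind_rows(rows)
}
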