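# synthetic kymograph of a Gaussian peak translating at a known speed
synthetic_moving_sim <- function(v, L = 10, N = 200, times = seq(0, 50, 2)) {
  sys <- system_params(L = L, N = N)
  x <- polarflow:::grid_centers(sys)
  M <- t(vapply(times, function(t) {
    d <- ((x - (L / 2 + v * t) + L / 2) %% L) - L / 2
    1 + 5 * exp(-(d / 0.8)^2)
  }, numeric(N)))
  structure(list(times = times, x = x, m = M, c = M * 0 + 0.2,
                 n_bar_series = rowMeans(M + 0.2), sys = sys,
                 scheme = "upwind", seed = NULL),
            class = "polar_sim")
}

test_that("peak tracking recovers a known propagation speed across the wrap", {
  for (v in c(0.03, -0.08)) {
    trk <- track_peak(synthetic_moving_sim(v))
    expect_equal(trk$v_p, v, tolerance = 1e-3)
    expect_true(trk$steady)
    expect_false(trk$multi_peak)
  }
})

test_that("multi-peak frames are flagged and the speed is withheld", {
  sim <- synthetic_moving_sim(0.05)
  x <- sim$x
  two <- 1 + 5 * exp(-((x - 2.5) / 0.6)^2) + 4.8 * exp(-((x - 7.5) / 0.6)^2)
  sim$m <- matrix(rep(two, length(sim$times)), nrow = length(sim$times),
                  byrow = TRUE)
  trk <- track_peak(sim)
  expect_true(trk$multi_peak)
  expect_true(is.na(trk$v_p))
})

test_that("a stationary pattern's phase trajectory lies in the flux-balance subspace", {
  sys <- system_params(N = 256)
  init <- default_peak_init()
  ph <- phase_trajectory(init, sys)
  expect_lt(ph$fbs_max_dev, 1e-3)
  expect_lt(abs(ph$loop_area), 1e-6 * max(init$m) * max(init$c))
  expect_equal(ph$cL, ph$cR, tolerance = 1e-6)
  # crossings satisfy the nullcline relation
  cc <- ph$crossings
  expect_lt(max(abs(cc$c - nullcline_c(cc$m, sys$reaction))), 1e-3)
  expect_equal(ph$fbs_slope, -sys$Dm / sys$Dc)
})

test_that("flow opens the loop with higher cytosolic density upstream", {
  sys <- system_params(N = 256, flow = flow_profile("uniform", vf = 20))
  init <- default_peak_init()
  sim <- simulate_polarity(init, sys, t_end = 120, save_every = 10)
  ph <- phase_trajectory(final_field(sim), sys)
  expect_gt(ph$cL, ph$cR)
  expect_gt(abs(ph$loop_area), 1e-4)
  expect_gt(ph$fbs_max_dev, 1e-5) # no longer embedded in the FBS
  expect_error(phase_trajectory(
    make_initial(sys, "homogeneous-noise", amplitude = 0), sys),
    "crossings")
})

test_that("reversing the flow reverses the propagation and the loop orientation", {
  sys <- system_params(N = 256, flow = flow_profile("uniform", vf = -20))
  init <- default_peak_init()
  sim <- simulate_polarity(init, sys, t_end = 120, save_every = 2)
  trk <- track_peak(sim, window = c(60, 120))
  expect_gt(trk$v_p, 1e-3) # against a leftward flow: rightward motion
  ph <- phase_trajectory(final_field(sim), sys)
  expect_gt(ph$cL, ph$cR) # upstream flank (now the right one) is enriched
})

test_that("LSA speed prediction vanishes without flow and matches slow flow in sign and scale", {
  sys <- system_params(N = 256)
  init <- default_peak_init()
  expect_identical(predict_vp_lsa(init, sys, vf = 0)$v_p_pred, 0)
  for (vf in c(0.5, 1)) {
    pred <- predict_vp_lsa(init, sys, vf = vf)
    sys_f <- sys
    sys_f$flow <- flow_profile("uniform", vf = vf)
    sim <- simulate_polarity(init, sys_f, t_end = 120, save_every = 2)
    v_meas <- track_peak(sim, window = c(60, 120))$v_p
    expect_lt(pred$v_p_pred, 0)
    expect_lt(v_meas, 0)
    expect_lt(abs(pred$v_p_pred / v_meas - 1), 1) # within a factor of 2
  }
  # predicted speed scales linearly at slow flow, as 1/vf at fast flow
  p_lin <- vapply(c(0.25, 0.5), function(v) predict_vp_lsa(init, sys, v)$v_p_pred,
                  numeric(1))
  expect_equal(p_lin[2] / p_lin[1], 2, tolerance = 0.05)
  p_fast <- vapply(c(5e3, 1e4), function(v) predict_vp_lsa(init, sys, v)$v_p_pred,
                   numeric(1))
  expect_equal(p_fast[1] / p_fast[2], 2, tolerance = 0.05)
})

test_that("classification separates homogeneous, saturated-mesa and mass-limited-peak profiles", {
  sys <- system_params(N = 256)
  flat <- make_initial(sys, "homogeneous-noise", amplitude = 0)
  expect_identical(classify_pattern(flat, sys)$label, "homogeneous")
  # the default stationary pattern concentrates all excess mass: a peak
  cls_peak <- classify_pattern(default_peak_init(), sys)
  expect_identical(cls_peak$label, "peak")
  expect_gt(cls_peak$top_imbalance, 0.1)
  # synthetic mesa: trapezoid whose top sits at a reactive equilibrium
  x <- polarflow:::grid_centers(sys)
  m_top <- 18
  prof <- pmin(m_top, pmax(0.2, m_top * (1 - abs(x - 5) / 2.5)))
  mesa <- polarity_field(x, prof, nullcline_c(prof, sys$reaction))
  cls_mesa <- classify_pattern(mesa, sys)
  expect_identical(cls_mesa$label, "mesa")
  expect_lt(cls_mesa$top_imbalance, 0.01)
  expect_gt(cls_mesa$plateau_width, 0)
})

test_that("the laterally unstable density interval behaves as the criterion dictates", {
  sys <- system_params()
  rng0 <- unstable_density_range(sys, vf = 0, n_max = 20)
  expect_false(rng0$empty)
  expect_true(rng0$n_minus < 5) # the default operating point lies inside
  st5 <- homogeneous_state(5)
  expect_false(unstable_band(st5, sys, vf = 0)$empty)
  # flow widens the interval
  rng_f <- unstable_density_range(sys, vf = 50, n_max = 20)
  expect_lt(rng_f$n_minus, rng0$n_minus)
  # equal diffusion constants admit no laterally unstable density at all
  sys_eq <- system_params(Dm = 10, Dc = 10)
  expect_true(unstable_density_range(sys_eq, vf = 0, n_max = 20)$empty)
})

test_that("regional instability requires both local density and region width", {
  sys <- system_params(N = 256, boundary = "noflux")
  x <- polarflow:::grid_centers(sys)
  rng <- unstable_density_range(sys, vf = 0, n_max = 20)
  # homogeneous laterally stable field: nothing marked
  n_lo <- 0.9 * rng$n_minus
  eq <- local_equilibria(n_lo, sys$reaction)
  flat <- polarity_field(x, rep(eq$m_star, 256), rep(eq$c_star, 256))
  ri0 <- regional_instability(flat, sys, range = rng)
  expect_false(any(ri0$mask))
  expect_false(ri0$triggered)
  # wide supercritical plug: marked and triggered
  n_prof <- ifelse(x > 6, 1.2 * rng$n_minus, n_lo)
  eqp <- local_equilibria(n_prof, sys$reaction)
  plug <- polarity_field(x, eqp$m_star, eqp$c_star)
  ri1 <- regional_instability(plug, sys, range = rng)
  expect_true(ri1$triggered)
  expect_true(all(which(ri1$mask) %in% which(x > 6)))
  # sliver narrower than the shortest unstable wavelength: marked, not triggered
  n_prof2 <- ifelse(x > 6 & x < 6.4, 1.2 * rng$n_minus, n_lo)
  eq2 <- local_equilibria(n_prof2, sys$reaction)
  ri2 <- regional_instability(polarity_field(x, eq2$m_star, eq2$c_star),
                              sys, range = rng)
  expect_true(any(ri2$mask))
  expect_false(ri2$triggered)
})
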