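test_that("rhs vanishes at the homogeneous steady state for any uniform flow", {
  for (vf in c(0, 20)) {
    sys <- system_params(N = 64, flow = flow_profile("uniform", vf = vf))
    st <- homogeneous_state(sys$n_bar, sys$reaction)
    fld <- polarity_field(polarflow:::grid_centers(sys),
                          rep(st$m_star, 64), rep(st$c_star, 64))
    d <- polarity_rhs(fld, sys)
    expect_lt(max(abs(c(d$dm, d$dc))), 1e-12)
  }
})

test_that("discrete total mass has exactly zero time derivative on random fields", {
  set.seed(5)
  # periodic domain with uniform flow
  sys <- system_params(N = 128, flow = flow_profile("uniform", vf = 13))
  x <- polarflow:::grid_centers(sys)
  fld <- polarity_field(x, runif(128, 0.1, 6), runif(128, 0.1, 2))
  d <- polarity_rhs(fld, sys)
  scale <- max(abs(c(d$dm, d$dc)))
  expect_lt(abs(sum(d$dm + d$dc)) / (128 * scale), 1e-14)
  # no-flux walls with a parabolic profile that vanishes there
  sys2 <- system_params(N = 128, boundary = "noflux",
                        flow = flow_profile("parabolic", vmax = 7))
  d2 <- polarity_rhs(fld, sys2)
  scale2 <- max(abs(c(d2$dm, d2$dc)))
  expect_lt(abs(sum(d2$dm + d2$dc)) / (128 * scale2), 1e-14)
  # both advection schemes
  d3 <- polarity_rhs(fld, sys, scheme = "central")
  expect_lt(abs(sum(d3$dm + d3$dc)) / (128 * max(abs(c(d3$dm, d3$dc)))), 1e-14)
})

test_that("noise initial conditions are mass-neutral, seeded, and bounded", {
  sys <- system_params(N = 128)
  st <- homogeneous_state(sys$n_bar, sys$reaction)
  f0 <- make_initial(sys, "homogeneous-noise", amplitude = 0)
  expect_equal(f0$m, rep(st$m_star, 128), tolerance = 1e-15)
  f1 <- make_initial(sys, "homogeneous-noise", seed = 99)
  f2 <- make_initial(sys, "homogeneous-noise", seed = 99)
  expect_identical(f1$m, f2$m) # bit-identical under the same seed
  expect_false(identical(f1$m, make_initial(sys, "homogeneous-noise", seed = 100)$m))
  expect_equal(mean(f1$m + f1$c), sys$n_bar, tolerance = 1e-14)
  expect_true(all(f1$m + f1$c - sys$n_bar < 1e-13)) # pointwise mass-neutral
  expect_error(make_initial(sys, "homogeneous-noise", amplitude = 10, seed = 1),
               "negative")
})

test_that("an unperturbed homogeneous state stays put and conserves mass", {
  sys <- system_params(N = 64)
  init <- make_initial(sys, "homogeneous-noise", amplitude = 0)
  sim <- simulate_polarity(init, sys, t_end = 50, save_every = 10)
  expect_lt(max(abs(sweep(sim$m, 2, sim$m[1, ]))), 1e-7)
  expect_lt(mass_drift(sim), 1e-6)
})

test_that("flow onset at t0 splits cleanly: stationary before, moving after", {
  sys <- system_params(N = 256, flow = flow_profile("uniform", vf = 20, t0 = 40))
  init <- default_peak_init()
  sim <- simulate_polarity(init, sys, t_end = 100, save_every = 2)
  pre <- track_peak(sim, window = c(0, 40))
  post <- track_peak(sim, window = c(60, 100))
  expect_lt(abs(pre$v_p), 1e-4)
  expect_lt(post$v_p, -1e-3) # upstream, against the rightward flow
  expect_lt(mass_drift(sim), 1e-6)
})

test_that("simulated mode growth matches the dispersion relation in the linear regime", {
  sys <- system_params(N = 256)
  st <- homogeneous_state(sys$n_bar, sys$reaction)
  for (vf in c(0, 1, 20)) {
    band <- unstable_band(st, sys, vf = vf)
    k <- max(1, round(band$q_star * sys$L / (2 * pi)))
    qk <- 2 * pi * k / sys$L
    sig <- dispersion(qk, st, sys, vf = vf)$sigma
    sys_f <- sys
    sys_f$flow <- flow_profile("uniform", vf = vf)
    init <- make_initial(sys_f, "homogeneous-noise", amplitude = 5e-4, seed = 42)
    sim <- simulate_polarity(init, sys_f, t_end = 15, save_every = 0.5)
    g <- measure_mode_growth(sim, k, window = c(2, 12))
    expect_equal(Re(g$sigma_hat), Re(sig), tolerance = 0.05)
    if (vf > 0) {
      expect_equal(Im(g$sigma_hat), Im(sig), tolerance = 0.05)
    } else {
      expect_lt(abs(Im(g$sigma_hat)), 1e-5)
    }
  }
})

test_that("the relaxed single-peak state is stationary without flow", {
  sys <- system_params(N = 256)
  init <- default_peak_init()
  sim <- simulate_polarity(init, sys, t_end = 100, save_every = 5)
  trk <- track_peak(sim)
  expect_lt(abs(trk$v_p), 1e-4) # um/s drift over 100 s
  expect_lt(mass_drift(sim), 1e-6)
})

test_that("integration reports failure diagnostics instead of silent nonsense", {
  sys <- system_params(N = 16)
  init <- make_initial(sys, "homogeneous-noise", amplitude = 0)
  expect_error(simulate_polarity(init, sys, t_end = -5), "t_end > 0")
  sys_bad <- system_params(N = 32)
  expect_error(simulate_polarity(init, sys_bad, t_end = 1), "length")
})
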