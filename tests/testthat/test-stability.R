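test_that("q = 0 eigenvalues are exactly {0, fm - fc}", {
  st <- homogeneous_state(5)
  sys <- system_params()
  d <- dispersion(0, st, sys, vf = 0)
  vals <- sort(Re(c(d$sigma, d$sigma_minor)))
  expect_equal(vals, sort(c(0, st$fm - st$fc)), tolerance = 1e-12)
  expect_equal(Im(c(d$sigma, d$sigma_minor)), c(0, 0), tolerance = 1e-12)
})

test_that("without flow the spectrum of a homogeneously stable state is real", {
  st <- homogeneous_state(5)
  sys <- system_params()
  qs <- c(10^seq(-3, 0.8, length.out = 40))
  d <- dispersion(qs, st, sys, vf = 0)
  expect_true(all(abs(Im(d$sigma)) < 1e-12))
})

test_that("diagonalization agrees with the quadratic-formula oracle on random draws", {
  set.seed(101)
  for (i in 1:200) {
    s <- rand_setup()
    q <- runif(1, 0, 10)
    vf <- runif(1, -100, 100)
    d <- dispersion(q, s$st, s$sys, vf = vf)
    o <- sigma_quadratic_oracle(q, s$st, s$sys, vf)
    scale <- max(1, Mod(o))
    expect_lt(max(Mod(c(d$sigma, d$sigma_minor) - o)) / scale, 1e-10)
    # internal fast path must agree with the exported route
    f <- polarflow:::dispersion_fast(q, s$st, s$sys, vf)
    expect_lt(max(Mod(c(f$sigma, f$sigma_minor) - c(d$sigma, d$sigma_minor))) /
                scale, 1e-10)
  }
})

test_that("non-uniform flow profiles are rejected by the linear analysis", {
  st <- homogeneous_state(5)
  sys <- system_params(flow = flow_profile("parabolic", vmax = 5))
  expect_error(dispersion(1, st, sys), "uniform")
  expect_silent(dispersion(1, st, sys, vf = 5)) # explicit vf is fine
})

test_that("the unstable band is located with a clean edge and empties when stable", {
  sys <- system_params()
  st <- homogeneous_state(5)
  band <- unstable_band(st, sys, vf = 0)
  expect_false(band$empty)
  edge <- dispersion(band$q_max, st, sys, vf = 0)$sigma
  expect_lt(abs(Re(edge)), 1e-8)
  expect_gt(Re(dispersion(band$q_star, st, sys, vf = 0)$sigma), 0)
  expect_equal(band$lambda_star, 2 * pi / band$q_star)
  # below the critical density the state is laterally stable: empty band
  st_lo <- homogeneous_state(1.2)
  band_lo <- unstable_band(st_lo, sys, vf = 0)
  expect_true(band_lo$empty)
})

test_that("instability criterion reduces to the slope criterion and tightens to zero with flow", {
  sys <- system_params()
  st <- homogeneous_state(5)
  crit0 <- instability_criterion(st, sys, vf = 0)
  expect_equal(crit0$threshold, -sys$Dm / sys$Dc, tolerance = 1e-12)
  expect_true(crit0$unstable)
  # threshold -> 0 from below as vf grows; |threshold| monotone decreasing
  vfs <- c(0, 1, 10, 100, 1e3, 1e5)
  thr <- vapply(vfs, function(v) instability_criterion(st, sys, vf = v)$threshold,
                numeric(1))
  expect_true(all(thr < 0))
  expect_true(all(diff(abs(thr)) < 0))
  expect_lt(abs(thr[length(thr)]), 1e-6)
  # with Dc = 0 flow alone can drive the instability
  sys0 <- system_params(Dc = 0)
  expect_error(instability_criterion(st, sys0, vf = 0), "Dc = 0")
  crit_flow <- instability_criterion(st, sys0, vf = 50)
  expect_true(crit_flow$threshold < 0 && crit_flow$unstable)
})

test_that("criterion agrees with band non-emptiness across a density sweep", {
  sys <- system_params()
  for (n in seq(0.4, 10, length.out = 12)) {
    st <- homogeneous_state(n)
    if (st$sigma1 >= 0) next
    for (vf in c(0, 20)) {
      crit <- instability_criterion(st, sys, vf = vf)$unstable
      band <- !unstable_band(st, sys, vf = vf)$empty
      expect_identical(crit, band)
    }
  }
})

test_that("long-wavelength expansion converges to the dispersion relation as q -> 0", {
  st <- homogeneous_state(5)
  sys <- system_params()
  vf <- 20
  qs <- 10^seq(-4, -1, length.out = 12)
  full <- dispersion(qs, st, sys, vf = vf)$sigma
  appr <- long_wavelength_sigma(qs, st, sys, vf = vf)
  rel <- Mod(appr - full) / Mod(full)
  # at least linear decay of the relative error over three decades in q
  expect_lt(rel[1], rel[length(rel)] * (qs[1] / qs[length(qs)]) * 10)
  expect_lt(rel[1], 1e-3)
  # no flow: purely real expansion
  expect_true(all(Im(long_wavelength_sigma(qs, st, sys, vf = 0)) == 0))
  # q-independent phase velocity at long wavelength
  vp_lw <- long_wavelength_phase_velocity(st, sys, vf = vf)
  expect_equal(vp_lw, vf * st$s_nc / (1 + st$s_nc))
  vp_num <- dispersion(1e-4, st, sys, vf = vf)$v_phase
  expect_equal(vp_num, vp_lw, tolerance = 1e-3)
})

test_that("slow-flow coefficient is positive on the band and modes drift upstream", {
  st <- homogeneous_state(5)
  sys <- system_params()
  band <- unstable_band(st, sys, vf = 0)
  qs <- seq(band$q_max / 20, band$q_max * 0.95, length.out = 15)
  A <- slow_flow_coefficient(qs, st, sys)
  expect_true(all(A > 0))
  # Richardson step-halving: vf_eps 1e-3 vs 1e-4 agree to 1%
  A2 <- slow_flow_coefficient(qs, st, sys, vf_eps = 1e-4)
  expect_equal(A, A2, tolerance = 1e-2)
  # sign(Im sigma) = sign(vf) on the unstable band
  for (vf in c(-100, -10, -1, -0.1, 0.1, 1, 10, 100)) {
    im <- Im(dispersion(qs, st, sys, vf = vf)$sigma)
    expect_true(all(sign(im) == sign(vf)))
  }
})

test_that("fast-flow limit matches the dispersion relation and decays as 1/vf", {
  st <- homogeneous_state(5)
  sys <- system_params()
  band <- unstable_band(st, sys, vf = 1e4)
  q <- band$q_star
  approx <- fast_flow_sigma(q, st, sys, vf = 1e4)
  full <- dispersion(q, st, sys, vf = 1e4)$sigma
  expect_lt(Mod(approx - full) / Mod(full), 0.02)
  # real part independent of Dc and vf
  expect_equal(Re(fast_flow_sigma(q, st, sys, vf = 1e4)),
               Re(fast_flow_sigma(q, st, system_params(Dc = 0.1), vf = 333)))
  # phase velocity magnitude ~ 1/vf at fixed q
  v1 <- fast_flow_phase_velocity(q, st, sys, vf = 1e4)
  v2 <- fast_flow_phase_velocity(q, st, sys, vf = 2e4)
  expect_equal(v1 / v2, 2, tolerance = 1e-12)
  expect_error(fast_flow_sigma(q, st, sys, vf = 0), "vf != 0")
})

test_that("membrane-cytosol eigenmode phase shift grows with flow and saturates", {
  st <- homogeneous_state(5)
  sys <- system_params()
  band <- unstable_band(st, sys, vf = 0)
  q <- band$q_star
  # no flow: real eigenvector, shift 0 or pi
  ps0 <- eigenvector_phase_shift(q, st, sys, vf = 0)
  expect_lt(min(abs(ps0), abs(abs(ps0) - pi)), 1e-10)
  shifts <- abs(abs(vapply(c(1, 10, 100, 1e3),
                           function(v) eigenvector_phase_shift(q, st, sys, vf = v),
                           numeric(1))) - pi)
  expect_true(all(diff(shifts) > 0)) # offset from the no-flow alignment grows
  # saturation: one decade further in vf changes the shift by < 1%
  s5 <- abs(abs(eigenvector_phase_shift(q, st, sys, vf = 1e5)) - pi)
  s6 <- abs(abs(eigenvector_phase_shift(q, st, sys, vf = 1e6)) - pi)
  expect_equal(s5, s6, tolerance = 0.01)
})

test_that("dispersion_relation bundles the grid with band diagnostics and tidies", {
  st <- homogeneous_state(5)
  sys <- system_params()
  dr <- dispersion_relation(st, sys, vf = 20)
  expect_s3_class(dr, "dispersion_result")
  expect_false(dr$empty)
  td <- tidy(dr)
  expect_true(all(c("q", "re_sigma", "im_sigma", "v_phase") %in% names(td)))
  gl <- glance(dr)
  expect_equal(gl$vf, 20)
  expect_gt(gl$q_max, gl$q_star)
})
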