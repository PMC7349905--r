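#' Scenario presets
#'
#' Self-contained end-to-end protocols, each bundling parameters, a
#' simulation recipe and the list of property checks it must satisfy:
#'
#' * `"fig2"` -- linear regime: dispersion relation at the default operating
#'   point, early-time growth of a small random perturbation, and the
#'   upstream drift of unstable modes under flow.
#' * `"fig4"` -- nonlinear propagation: a stationary single-peak pattern on a
#'   periodic domain (L = 10 um), uniform flow `vf = 20` um/s switched on at
#'   `t0 = 240` s; the peak must propagate upstream.
#' * `"fig5"` -- pattern-type transition at `n_bar = 7`, `Dm = 0.1`,
#'   `L = 20`: mesa without/with slow flow (1 um/s), peak under fast flow
#'   (50 um/s) or hundredfold-faster cytosolic diffusion. The slow/fast
#'   values are reconstructions chosen to bracket the transition (the sweep
#'   utilities report the transition point itself).
#' * `"fig6"` -- flow-induced pattern formation: no-flux walls, parabolic
#'   flow profile, mean density set at run time to 95% of the lower edge of
#'   the laterally unstable density range (so the homogeneous state is
#'   laterally stable), `vmax = 1` um/s; a regional lateral instability must
#'   trigger before the pattern grows, and the pattern must persist after
#'   the flow is switched off. A low-mass variant (50% of the edge,
#'   `vmax = 5`) forms a flow-maintained pattern that decays once the flow
#'   stops.
#'
#' @param name one of `"fig2"`, `"fig4"`, `"fig5"`, `"fig6"`.
#' @return An object of class `scenario_preset`.
#' @export
scenario_preset <- function(name = c("fig2", "fig4", "fig5", "fig6")) {
  name <- match.arg(name)
  preset <- switch(name,
    fig2 = list(
      sys = system_params(N = 256),
      sim = list(t_end = 15, save_every = 0.5, noise_amplitude = 5e-4,
                 window = c(2, 12), vf_flow = 20),
      checks = c("band_nonempty", "mode_growth_matches_lsa",
                 "modes_drift_upstream", "mass_conserved")
    ),
    fig4 = list(
      sys = system_params(
        N = 256, L = 10,
        flow = flow_profile("uniform", vf = 20, t0 = 240)),
      sim = list(t_end = 360, save_every = 2, window = c(300, 360)),
      checks = c("peak_moves_upstream", "loop_opens", "mass_conserved")
    ),
    fig5 = list(
      sys = system_params(Dm = 0.1, Dc = 10, L = 20, n_bar = 7, N = 256),
      sim = list(t_settle = 400, save_every = 40, vf_slow = 1, vf_fast = 50,
                 Dc_fast = 1000),
      checks = c("no_flow_mesa", "slow_flow_mesa", "fast_flow_peak",
                 "fast_diffusion_peak", "mass_conserved")
    ),
    fig6 = list(
      sys = system_params(N = 256, boundary = "noflux",
                          flow = flow_profile("parabolic", vmax = 1)),
      sim = list(t_flow = 600, save_every = 5, t_off = 500,
                 n_frac = 0.95, n_frac_low = 0.50, vmax_low = 5,
                 noise_amplitude_rel = 1e-3),
      checks = c("homogeneous_state_stable", "trigger_precedes_pattern",
                 "peak_at_downstream_edge", "persists_after_flow_off",
                 "low_mass_decays_after_flow_off", "mass_conserved")
    )
  )
  structure(c(list(name = name), preset), class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("<scenario_preset> %s | checks: %s\n", x$name,
              paste(x$checks, collapse = ", ")))
  invisible(x)
}

#' Run a scenario end-to-end and evaluate its checks
#'
#' Executes the preset's protocol with the given seed and returns a report
#' with one row per expected check. With `out_dir` set, the kymograph, mass
#' ledger and a YAML run manifest are written there, so the run can be
#' re-executed bit-identically from the manifest alone.
#'
#' @param preset a [scenario_preset()] or its name.
#' @param seed integer seed for every stochastic ingredient.
#' @param out_dir optional output directory for artifacts.
#' @return An object of class `scenario_report`: tibble `checks` (columns
#'   `check`, `pass`, `detail`), `passed` (all checks green), and the main
#'   simulation(s) under `artifacts`.
#' @export
run_scenario <- function(preset, seed = 1, out_dir = NULL) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  runner <- switch(preset$name,
    fig2 = scenario_fig2, fig4 = scenario_fig4,
    fig5 = scenario_fig5, fig6 = scenario_fig6)
  res <- runner(preset, seed)
  report <- structure(
    list(name = preset$name, seed = seed, checks = res$checks,
         passed = all(res$checks$pass), artifacts = res$artifacts),
    class = "scenario_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sims <- res$artifacts[vapply(res$artifacts, inherits, logical(1), "polar_sim")]
    for (nm in names(sims)) {
      write_kymograph_tsv(sims[[nm]], file.path(out_dir, paste0(nm, "_kymograph.tsv")))
      write_mass_ledger_tsv(sims[[nm]], file.path(out_dir, paste0(nm, "_mass.tsv")))
      write_manifest(sims[[nm]], file.path(out_dir, paste0(nm, "_manifest.yaml")),
                     extra = list(scenario = preset$name, seed = seed))
    }
    readr::write_tsv(res$checks, file.path(out_dir, "checks.tsv"))
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s (seed %d): %s\n", x$name, x$seed,
              if (x$passed) "all checks passed" else "CHECK FAILURES"))
  df <- x$checks
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  [%s] %s: %s\n", if (df$pass[i]) "ok" else "FAIL",
                df$check[i], df$detail[i]))
  }
  invisible(x)
}

#' @export
tidy.scenario_report <- function(x, ...) x$checks

check_row <- function(check, pass, detail) {
  tibble::tibble(check = check, pass = pass, detail = detail)
}

scenario_fig2 <- function(preset, seed) {
  sys <- preset$sys
  sm <- preset$sim
  st <- homogeneous_state(sys$n_bar, sys$reaction)
  band <- unstable_band(st, sys, vf = 0)
  checks <- check_row("band_nonempty", !band$empty,
                      sprintf("q_max=%.4g, q*=%.4g", band$q_max, band$q_star))
  # growth of the discrete mode nearest the fastest-growing wavelength, vf=0
  k <- max(1, round(band$q_star * sys$L / (2 * pi)))
  qk <- 2 * pi * k / sys$L
  init <- make_initial(sys, "homogeneous-noise",
                       amplitude = sm$noise_amplitude, seed = seed)
  sim0 <- simulate_polarity(init, sys, t_end = sm$t_end,
                            save_every = sm$save_every, seed = seed)
  g0 <- measure_mode_growth(sim0, k, window = sm$window)
  sig0 <- dispersion(qk, st, sys, vf = 0)$sigma
  err0 <- abs(Re(g0$sigma_hat) - Re(sig0)) / abs(Re(sig0))
  checks <- rbind(checks, check_row(
    "mode_growth_matches_lsa", err0 < 0.05,
    sprintf("mode k=%d: measured %.5g vs LSA %.5g (rel err %.2g)",
            k, Re(g0$sigma_hat), Re(sig0), err0)))
  # drift under flow: Im sigma has the sign of vf => upstream propagation
  sys_f <- sys
  sys_f$flow <- flow_profile("uniform", vf = sm$vf_flow)
  sim_f <- simulate_polarity(init, sys_f, t_end = sm$t_end,
                             save_every = sm$save_every, seed = seed)
  band_f <- unstable_band(st, sys, vf = sm$vf_flow)
  kf <- max(1, round(band_f$q_star * sys$L / (2 * pi)))
  gf <- measure_mode_growth(sim_f, kf, window = sm$window)
  checks <- rbind(checks, check_row(
    "modes_drift_upstream", sign(Im(gf$sigma_hat)) == sign(sm$vf_flow),
    sprintf("Im sigma_hat = %.4g at vf = %g", Im(gf$sigma_hat), sm$vf_flow)))
  checks <- rbind(checks, mass_check(sim0, sim_f))
  list(checks = checks, artifacts = list(noflow = sim0, flow = sim_f))
}

scenario_fig4 <- function(preset, seed) {
  sys <- preset$sys
  sm <- preset$sim
  init <- make_initial(sys, "single-peak")
  sim <- simulate_polarity(init, sys, t_end = sm$t_end,
                           save_every = sm$save_every, seed = seed)
  trk <- track_peak(sim, window = sm$window)
  checks <- check_row(
    "peak_moves_upstream", !is.na(trk$v_p) && trk$v_p < 0,
    sprintf("v_p = %.4g um/s under vf = %g", trk$v_p, sys$flow$vf))
  ph <- phase_trajectory(final_field(sim), sys, vf = sys$flow$vf)
  checks <- rbind(checks, check_row(
    "loop_opens", ph$cL > ph$cR && abs(ph$loop_area) > 0,
    sprintf("cL - cR = %.4g, loop area %.4g", ph$cL - ph$cR, ph$loop_area)))
  checks <- rbind(checks, mass_check(sim))
  list(checks = checks, artifacts = list(run = sim))
}

scenario_fig5 <- function(preset, seed) {
  sys <- preset$sys
  sm <- preset$sim
  init <- make_initial(sys, "single-peak")
  settle <- function(s, ini) {
    simulate_polarity(ini, s, t_end = sm$t_settle, save_every = sm$save_every,
                      seed = seed)
  }
  label_of <- function(s, sim) classify_pattern(final_field(sim), s)$label
  sims <- list()
  s0 <- sys
  sims$no_flow <- settle(s0, init)
  lab0 <- label_of(s0, sims$no_flow)
  s1 <- sys; s1$flow <- flow_profile("uniform", vf = sm$vf_slow)
  sims$slow_flow <- settle(s1, init)
  lab1 <- label_of(s1, sims$slow_flow)
  s2 <- sys; s2$flow <- flow_profile("uniform", vf = sm$vf_fast)
  sims$fast_flow <- settle(s2, init)
  lab2 <- label_of(s2, sims$fast_flow)
  s3 <- sys; s3$Dc <- sm$Dc_fast
  init3 <- make_initial(s3, "single-peak")
  sims$fast_diffusion <- settle(s3, init3)
  lab3 <- label_of(s3, sims$fast_diffusion)
  checks <- rbind(
    check_row("no_flow_mesa", lab0 == "mesa", sprintf("label: %s", lab0)),
    check_row("slow_flow_mesa", lab1 == "mesa",
              sprintf("label: %s at vf=%g", lab1, sm$vf_slow)),
    check_row("fast_flow_peak", lab2 == "peak",
              sprintf("label: %s at vf=%g", lab2, sm$vf_fast)),
    check_row("fast_diffusion_peak", lab3 == "peak",
              sprintf("label: %s at Dc=%g", lab3, sm$Dc_fast)),
    do.call(mass_check, unname(sims)))
  list(checks = checks, artifacts = sims)
}

scenario_fig6 <- function(preset, seed) {
  sm <- preset$sim
  base <- preset$sys
  rng <- unstable_density_range(system_params(
    Dm = base$Dm, Dc = base$Dc, L = base$L, n_bar = 5,
    reaction = base$reaction), vf = 0)
  run_variant <- function(n_frac, vmax) {
    sys <- base
    sys$n_bar <- n_frac * rng$n_minus
    sys$flow <- flow_profile("parabolic", vmax = vmax)
    init <- make_initial(sys, "homogeneous-noise",
                         amplitude = sm$noise_amplitude_rel * sys$n_bar,
                         seed = seed)
    sim <- simulate_polarity(init, sys, t_end = sm$t_flow,
                             save_every = sm$save_every, seed = seed)
    sys_off <- sys
    sys_off$flow <- flow_profile("uniform", vf = 0)
    sim_off <- simulate_polarity(final_field(sim), sys_off,
                                 t_end = sm$t_off, save_every = sm$t_off / 10,
                                 seed = seed)
    list(sys = sys, sim = sim, sim_off = sim_off, rng = rng)
  }
  main <- run_variant(sm$n_frac, base$flow$vmax)
  st <- homogeneous_state(main$sys$n_bar, main$sys$reaction)
  crit <- instability_criterion(st, main$sys, vf = 0)
  checks <- check_row(
    "homogeneous_state_stable", !crit$unstable,
    sprintf("n_bar = %.4g (95%% of n_minus = %.4g): s_nc = %.4g > threshold %.4g",
            main$sys$n_bar, rng$n_minus, crit$s_nc, crit$threshold))
  # causal ordering: regional trigger before the amplitude reaches 10% of final
  amp <- apply(main$sim$m, 1, max) - apply(main$sim$m, 1, min)
  amp_final <- amp[length(amp)]
  t_amp <- main$sim$times[min(which(amp > 0.1 * amp_final))]
  t_trig <- NA_real_
  for (tt in main$sim$times) {
    ri <- regional_instability(field_at(main$sim, tt), main$sys, range = rng)
    if (ri$triggered) { t_trig <- tt; break }
  }
  checks <- rbind(checks, check_row(
    "trigger_precedes_pattern", !is.na(t_trig) && t_trig < t_amp,
    sprintf("trigger at t = %.4g s, 10%% amplitude at t = %.4g s", t_trig, t_amp)))
  fin <- final_field(main$sim)
  checks <- rbind(checks, check_row(
    "peak_at_downstream_edge", fin$x[which.max(fin$m)] > main$sys$L / 2,
    sprintf("peak at x = %.4g of L = %g", fin$x[which.max(fin$m)], main$sys$L)))
  amp_off <- apply(main$sim_off$m, 1, max) - apply(main$sim_off$m, 1, min)
  rel_change <- abs(amp_off[length(amp_off)] - amp_off[1]) / amp_off[1]
  checks <- rbind(checks, check_row(
    "persists_after_flow_off", rel_change < 0.05,
    sprintf("amplitude change %.2f%% over %g s without flow",
            100 * rel_change, sm$t_off)))
  low <- run_variant(sm$n_frac_low, sm$vmax_low)
  amp_low <- apply(low$sim_off$m, 1, max) - apply(low$sim_off$m, 1, min)
  formed <- max(apply(low$sim$m, 1, max) - apply(low$sim$m, 1, min)) >
    0.1 * low$sys$n_bar
  decayed <- amp_low[length(amp_low)] < 1e-3 * low$sys$n_bar
  checks <- rbind(checks, check_row(
    "low_mass_decays_after_flow_off", formed && decayed,
    sprintf("flow-maintained amplitude %.3g decays to %.3g at n_bar = %.4g",
            amp_low[1], amp_low[length(amp_low)], low$sys$n_bar)))
  checks <- rbind(checks, mass_check(main$sim, main$sim_off, low$sim, low$sim_off))
  list(checks = checks,
       artifacts = list(flow = main$sim, flow_off = main$sim_off,
                        low_mass = low$sim, low_mass_off = low$sim_off))
}

mass_check <- function(...) {
  drifts <- vapply(list(...), mass_drift, numeric(1))
  check_row("mass_conserved", all(drifts < 1e-6),
            sprintf("max relative drift %.2e", max(drifts)))
}
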