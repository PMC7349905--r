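#' Reaction kinetics parameters
#'
#' Attachment--detachment kinetics of the form `f(m, c) = a(m) c - d(m) m`,
#' where `a(m)` is the attachment rate from the cytosol to the membrane and
#' `d(m)` the detachment rate. The shipped default is
#' `a(m) = kon + kfb * m` (basal attachment plus self-recruitment) and
#' `d(m) = koff / (KD + m)` (enzyme-driven detachment with Michaelis--Menten
#' saturation). Alternative kinetics can be supplied through the
#' `attach`/`detach` hooks; the model's behaviour does not hinge on the
#' specific functional form, only on the `a(m) c - d(m) m` decomposition.
#'
#' @param kon basal attachment rate (1/s); default 1.
#' @param kfb self-recruitment rate (um/s); default 1.
#' @param koff detachment rate (1/s); default 2.
#' @param KD Michaelis--Menten constant of detachment (1/um); default 1.
#' @param attach,detach optional replacement kinetics: functions of the
#'   membrane concentration `m` returning `a(m)` resp. `d(m)`.
#' @param d_attach,d_detach derivatives `a'(m)`, `d'(m)`; required when
#'   `attach`/`detach` are supplied (closed-form partials are used throughout
#'   the stability analysis).
#'
#' @return An object of class `reaction_params`.
#' @examples
#' p <- reaction_params()
#' reaction_rate(1, 1, p) # (kon + kfb) * 1 - koff * 1 / (KD + 1) = 1
#' @export
reaction_params <- function(kon = 1, kfb = 1, koff = 2, KD = 1,
                            attach = NULL, detach = NULL,
                            d_attach = NULL, d_detach = NULL) {
  custom <- !is.null(attach) || !is.null(detach)
  if (custom) {
    if (is.null(attach) || is.null(detach) ||
        is.null(d_attach) || is.null(d_detach)) {
      abort("custom kinetics need all four of attach, detach, d_attach, d_detach")
    }
  } else {
    vals <- c(kon = kon, kfb = kfb, koff = koff, KD = KD)
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      abort("kinetic constants kon, kfb, koff, KD must be strictly positive")
    }
  }
  structure(
    list(kon = kon, kfb = kfb, koff = koff, KD = KD,
         attach = attach, detach = detach,
         d_attach = d_attach, d_detach = d_detach,
         custom = custom),
    class = "reaction_params"
  )
}

#' @export
print.reaction_params <- function(x, ...) {
  if (x$custom) {
    cat("<reaction_params> custom a(m), d(m) kinetics\n")
  } else {
    cat(sprintf(
      "<reaction_params> kon=%g 1/s, kfb=%g um/s, koff=%g 1/s, KD=%g 1/um\n",
      x$kon, x$kfb, x$koff, x$KD))
  }
  invisible(x)
}

# attachment rate a(m) and derivative
attach_rate <- function(m, p) {
  if (p$custom) p$attach(m) else p$kon + p$kfb * m
}
attach_rate_deriv <- function(m, p) {
  if (p$custom) p$d_attach(m) else rep_len(p$kfb, length(m))
}
# detachment rate d(m) and derivative
detach_rate <- function(m, p) {
  if (p$custom) p$detach(m) else p$koff / (p$KD + m)
}
detach_rate_deriv <- function(m, p) {
  if (p$custom) p$d_detach(m) else -p$koff / (p$KD + m)^2
}

#' Cytosolic flow profile
#'
#' Describes the advective flow acting on the cytosolic species. Two kinds are
#' supported: `"uniform"` (constant speed `vf`, signed; with periodic
#' boundaries this represents circular cytoplasmic streaming) and
#' `"parabolic"` (`vmax * (1 - 4 * (x/L - 1/2)^2)`, vanishing at both walls;
#' a minimal model of cortical flow near a no-flux boundary). The flow can be
#' switched on at time `t0`: before `t0` it is identically zero.
#'
#' @param kind `"uniform"` or `"parabolic"`.
#' @param vf uniform flow speed (um/s, signed). Used when `kind = "uniform"`.
#' @param vmax peak speed of the parabolic profile (um/s).
#' @param t0 onset time (s); the flow is zero for `t < t0`. Default 0.
#' @return An object of class `flow_profile`.
#' @examples
#' flow_profile("uniform", vf = 20, t0 = 240)
#' @export
flow_profile <- function(kind = c("uniform", "parabolic"), vf = 0,
                         vmax = NULL, t0 = 0) {
  kind <- match.arg(kind)
  if (kind == "parabolic" && is.null(vmax)) {
    abort("parabolic flow needs `vmax`")
  }
  stopifnot(is.numeric(t0), length(t0) == 1, t0 >= 0)
  structure(list(kind = kind, vf = vf, vmax = vmax, t0 = t0),
            class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("<flow_profile> uniform vf=%g um/s, onset t0=%g s\n", x$vf, x$t0))
  } else {
    cat(sprintf("<flow_profile> parabolic vmax=%g um/s, onset t0=%g s\n",
                x$vmax, x$t0))
  }
  invisible(x)
}

#' Evaluate the flow speed at given positions and time
#'
#' @param flow a [flow_profile()].
#' @param x positions (um).
#' @param L domain length (um).
#' @param t time (s); flows with an onset `t0` are zero before `t0`.
#' @return Flow speed (um/s) at each `x`.
#' @export
flow_velocity <- function(flow, x, L, t = Inf) {
  if (t < flow$t0) return(rep_len(0, length(x)))
  switch(flow$kind,
    uniform = rep_len(flow$vf, length(x)),
    parabolic = flow$vmax * (1 - 4 * (x / L - 0.5)^2)
  )
}

is_uniform_flow <- function(flow) flow$kind == "uniform"

#' System parameters for the polarity model
#'
#' Bundles transport constants, domain geometry, boundary condition, flow
#' profile, mean total density and the reaction kinetics. Defaults are the
#' standard operating point of the model: `Dm = 0.01`, `Dc = 10` um^2/s
#' (membrane diffusion a thousandfold slower than cytosolic diffusion),
#' `L = 10` um, `n_bar = 5` 1/um, periodic boundaries, no flow.
#'
#' @param Dm membrane diffusion constant (um^2/s).
#' @param Dc cytosolic diffusion constant (um^2/s).
#' @param L domain length (um).
#' @param n_bar mean total protein density (1/um), conserved by the dynamics.
#' @param boundary `"periodic"` or `"noflux"` (zero diffusive and advective
#'   flux at both walls).
#' @param flow a [flow_profile()].
#' @param reaction a [reaction_params()].
#' @param N number of finite-volume cells used by the integrator.
#' @return An object of class `system_params`.
#' @examples
#' sys <- system_params(L = 10, flow = flow_profile("uniform", vf = 20, t0 = 240))
#' @export
system_params <- function(Dm = 0.01, Dc = 10, L = 10, n_bar = 5,
                          boundary = c("periodic", "noflux"),
                          flow = flow_profile(),
                          reaction = reaction_params(),
                          N = 512) {
  boundary <- match.arg(boundary)
  stopifnot(Dm >= 0, Dc >= 0, L > 0, n_bar >= 0, N >= 8)
  stopifnot(inherits(flow, "flow_profile"), inherits(reaction, "reaction_params"))
  structure(
    list(Dm = Dm, Dc = Dc, L = L, n_bar = n_bar, boundary = boundary,
         flow = flow, reaction = reaction, N = as.integer(N)),
    class = "system_params"
  )
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf(
    "<system_params> Dm=%g, Dc=%g um^2/s | L=%g um, N=%d, %s | n_bar=%g 1/um\n",
    x$Dm, x$Dc, x$L, x$N, x$boundary, x$n_bar))
  print(x$flow)
  print(x$reaction)
  invisible(x)
}

#' Read system parameters from a YAML config file
#'
#' The schema mirrors the parameter objects:
#' ```yaml
#' system:   {Dm, Dc, L, n_bar, boundary}
#' flow:     {kind, vf, vmax, t0}
#' reaction: {kon, kfb, koff, KD}
#' sim:      {N, t_end, save_every, seed, noise_amplitude}
#' ```
#' Every field is optional; omitted fields fall back to the package defaults.
#'
#' @param path path to a YAML file.
#' @return A list with elements `sys` (a [system_params()]) and `sim`
#'   (a list of simulation settings: `t_end`, `save_every`, `seed`,
#'   `noise_amplitude`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rx <- do.call(reaction_params, cfg$reaction %||% list())
  fl <- do.call(flow_profile, cfg$flow %||% list())
  sys_args <- cfg$system %||% list()
  sys_args$flow <- fl
  sys_args$reaction <- rx
  if (!is.null(cfg$sim$N)) sys_args$N <- cfg$sim$N
  sys <- do.call(system_params, sys_args)
  sim <- modifyList(
    list(t_end = 600, save_every = 2, seed = 1, noise_amplitude = NULL),
    cfg$sim %||% list())
  sim$N <- NULL
  list(sys = sys, sim = sim)
}

#' Write system parameters to a YAML config file
#'
#' Inverse of [read_config()]; the written file round-trips.
#'
#' @param sys a [system_params()].
#' @param path output path.
#' @param sim optional list of simulation settings to embed under `sim:`.
#' @return `path`, invisibly.
#' @export
write_config <- function(sys, path, sim = list()) {
  fl <- sys$flow
  flow_block <- list(kind = fl$kind, t0 = fl$t0)
  if (fl$kind == "uniform") flow_block$vf <- fl$vf else flow_block$vmax <- fl$vmax
  rx <- sys$reaction
  cfg <- list(
    system = list(Dm = sys$Dm, Dc = sys$Dc, L = sys$L, n_bar = sys$n_bar,
                  boundary = sys$boundary),
    flow = flow_block,
    reaction = list(kon = rx$kon, kfb = rx$kfb, koff = rx$koff, KD = rx$KD),
    sim = c(list(N = sys$N), sim)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
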