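---
title: "Methods: flow-driven pattern dynamics in a mass-conserving two-component model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-driven pattern dynamics in a mass-conserving two-component model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`polarflow` implements a one-dimensional two-component mass-conserving
reaction–diffusion–advection model of cell polarity. One protein species
cycles between a membrane-bound state `m(x, t)` and a cytosolic state
`c(x, t)`:

$$\partial_t c + \partial_x\!\big(v_f(x)\, c\big) = D_c \partial_x^2 c - f(m, c),
\qquad
\partial_t m = D_m \partial_x^2 m + f(m, c),$$

on a domain of length $L$ with periodic or no-flux walls. Only the cytosol
is advected: the membrane-bound state is anchored to the cortex. The
reactions exchange protein between the two states but never create or
destroy it, so the mean total density $\bar n = L^{-1}\!\int (m + c)\,dx$ is
a conserved control parameter — the defining structural property of this
model class, and the reason patterns here are governed by mass
redistribution rather than by a characteristic Turing wavelength.

The kinetics take the attachment–detachment form
$f(m, c) = a(m)\,c - d(m)\,m$ with $a, d > 0$. The shipped realization is

$$a(m) = k_\mathrm{on} + k_\mathrm{fb} m, \qquad d(m) = \frac{k_\mathrm{off}}{K_D + m}:$$

basal attachment, self-recruitment by the membrane-bound form, and
enzyme-driven detachment that saturates at high membrane density. The
qualitative phenomena do not hinge on this choice — any $a, d$ pair
producing a nullcline with a sufficiently steep negative-slope section
behaves alike — so `reaction_params()` accepts user-supplied `(a, d)`
functions with their derivatives, and the whole analysis runs unchanged on
them.

### Parameters, units, defaults

Units are micrometres and seconds package-wide; concentrations are 1/µm.

| parameter | meaning | default | why |
|---|---|---|---|
| `kon` | basal attachment rate (1/s) | 1 | order-one reaction scale |
| `kfb` | self-recruitment rate (µm/s) | 1 | strong enough positive feedback for a steep nullcline section |
| `koff` | detachment rate (1/s) | 2 | balances attachment at order-one densities |
| `KD` | detachment saturation constant (1/µm) | 1 | saturation within the explored density range |
| `Dm` | membrane diffusion (µm²/s) | 0.01 | membrane diffusion is typically 2–3 orders slower than cytosolic |
| `Dc` | cytosol diffusion (µm²/s) | 10 | typical cytosolic mobility |
| `L` | domain length (µm) | 10 | cell-scale domain, several pattern wavelengths |
| `n_bar` | mean total density (1/µm) | 5 | inside the laterally unstable range of the default kinetics |
| `vf` / `vmax` | flow speed (µm/s) | 0 | set per protocol |

At the default operating point the homogeneous state is
$m^\ast = 4.7111$, $c^\ast = 0.2889$, with nullcline slope
$s_{nc} = -f_m/f_c = -0.0398$: homogeneously stable
($\sigma_1 = f_m - f_c < 0$, equivalently $s_{nc} > -1$) but laterally
unstable ($s_{nc} < -D_m/D_c = -10^{-3}$).

### Homogeneous states and the smallest-root convention

`homogeneous_state(n_bar)` solves $f(m^*, c^*) = 0$ with
$m^* + c^* = \bar n$ by scanning
$g(m) = a(m)(\bar n - m) - d(m) m$ on $[0, \bar n]$ for sign changes and
polishing each bracket with `uniroot` (residual tolerance $10^{-12}$).
For the shipped kinetics the root is unique over the explored range, but
general $(a, d)$ pairs may admit several; the package then returns the
smallest-$m$ root — the branch continuously connected to $(0, 0)$ as
$\bar n$ grows — and warns, listing all roots. This is a convention, not a
claim about the model: downstream analyses (`local_equilibria()`,
`unstable_density_range()`) inherit it, so continuation in $n$ is monotone
with no branch jumping.

## Linear stability under uniform flow

Fourier modes $\propto e^{\sigma t + iqx}$ about the homogeneous state obey
a 2×2 complex eigenvalue problem whose matrix couples
$-D_c q^2 - i v_f q - f_c$ (cytosol) and $-D_m q^2 + f_m$ (membrane)
through the linearized reactions $f_m, f_c$. `dispersion()` diagonalizes
this matrix per wavenumber (LAPACK); an independent closed-form
trace/determinant root is kept in the test suite as an oracle, and a
vectorized closed-form evaluation backs the internal band scans where
per-`q` LAPACK calls would dominate runtime. The two routes agree to
$10^{-10}$ on randomized parameter draws.

Conventions and numerical choices:

* **Branch labeling.** "The" dispersion relation $\sigma(q)$ is the branch
  with the larger real part at each $q$; ties break toward the larger
  imaginary part. Continuity across $q$ is not enforced — at branch
  crossings the dominant label may switch, which is what stability analysis
  needs.
* **At $q = 0$** the branches are exactly $\{0, f_m - f_c\}$; the zero mode
  reflects mass conservation (it shifts the steady state along the
  nullcline) and is excluded from lateral-stability statements.
* **Band edges.** `unstable_band()` scans 2048 points up to an adaptive cap
  (initial guess $\sqrt{f_m/D_m}$, the fast-flow real-part zero, doubled up
  to six times if needed), then brackets $\mathrm{Re}\,\sigma(q_{max}) = 0$
  with `uniroot` at $10^{-10}$ tolerance and maximizes
  $\mathrm{Re}\,\sigma$ on $(0, q_{max})$ for $q^\ast$. An empty band is a
  result, not an error.
* **Instability criterion.** The long-wavelength band-opening condition is
  $s_{nc} < -(D_m/D_c)\,[1 + v_f^2 (1+s_{nc})^2/(D_c f_c)]^{-1}$. It is
  evaluated in the equivalent form $-D_m/(D_c + v_f^2(1+s_{nc})^2/f_c)$,
  which stays well-defined at $D_c = 0$ with flow (advection alone can
  drive the instability); $D_c = 0$ without flow is rejected. Without flow
  it reduces to $s_{nc} < -D_m/D_c$; the threshold rises monotonically
  toward $0^-$ with $|v_f|$, so flow only ever widens the unstable range.
* **Slow-flow coefficient $A(q)$.** To linear order in $v_f$ the spectrum
  acquires $\mathrm{Im}\,\sigma = v_f q^2 A(q)$. The literature notation
  for the associated phase velocity is ambiguous by one power of $q$, so
  the package defines $A(q)$ purely operationally: a central difference of
  $\mathrm{Im}\,\sigma$ in $v_f$ at $\pm v_{f,\varepsilon}$
  (default $10^{-3}$ µm/s, verified by step-halving to 1%). Phase
  velocities are always reported directly as $-\mathrm{Im}\,\sigma/q$,
  never through $A(q)$.
* **Eigenvector phase shift.** The spatial offset between the membrane and
  cytosol components of the dominant mode is exposed as
  `eigenvector_phase_shift()` (the argument of $\hat c/\hat m$). Its
  magnitude grows with flow from the no-flow anti-phase alignment and
  saturates at large $v_f$; the package measures this saturation rather
  than asserting a particular limiting value, since the diagnostic depends
  on which eigenvector convention is fixed.

## Conservative finite-volume dynamics

The integrator discretizes the equations as $N$ uniform cells
(default $N = 512$) with all transport written as differences of face
fluxes: central face gradients for diffusion and the conservative advective
flux $v_f(x_\mathrm{face})\, c_\mathrm{face}$ with first-order upwinding by
the sign of the face velocity. Because every flux appears once with each
sign, the discrete total mass derivative telescopes to zero *exactly* — in
periodic domains and in no-flux domains (zero diffusive and advective wall
flux; the parabolic profile vanishes at the walls anyway, which is the
physically meaningful pairing). Mass conservation in simulations is
therefore limited only by the time integrator; every shipped scenario
checks relative drift below $10^{-6}$ and typically achieves $10^{-14}$.

First-order upwinding adds a numerical diffusivity $v_f \Delta x / 2$; at
the main operating point ($v_f = 20$, $N = 512$, $L = 10$) the cell Péclet
number $v_f \Delta x / D_c \approx 0.04$, so this correction is ~2% of
$D_c$ at worst. A `central` face-value option is provided for convergence
studies; halving $\Delta x$ changes the measured peak speed by under 2%.

Time integration uses the stiff sparse solver `deSolve::lsodes` with
relative tolerance $10^{-8}$ and absolute $10^{-10}$. A flow onset $t_0$ is
handled by splitting the integration interval at $t_0$, so the
discontinuity never sits inside a solver step. Saved fields are clamped at
zero; undershoot beyond $-10^{-12}$ raises a warning (none is observed in
the shipped scenarios).

### Initial conditions: what the generator emulates

Two seeded fixtures emulate the protocols used throughout:

* `homogeneous-noise` — the homogeneous state plus zero-mean noise applied
  antisymmetrically ($m^\ast + \xi$, $c^\ast - \xi$; default amplitude
  $10^{-3}\bar n$), so the local total density is *exactly* unperturbed.
  This isolates the reactive/lateral response from trivial mass noise. Real
  perturbations of course also carry mass fluctuations; since the zero
  eigenvalue makes those marginal, omitting them changes nothing
  qualitative while making mass ledgers exact.
* `single-peak` — a mass-neutral Gaussian bump on the membrane profile
  relaxed without flow until the sup-norm change per 10 s falls below
  $10^{-8}$, reconstructing the "stationary pattern, then switch the flow
  on" protocol. The relaxation endpoint, not the bump, is the fixture:
  bump height and width defaults ($\bar n/5$, $L/20$) only need to land in
  the single-peak basin. Mesa-type states approach stationarity
  asymptotically slowly; the relaxer caps at a configurable `relax_max`
  (warning if hit) and the residual drift is orders below the diagnostics
  that consume these states.

Passing tests on these fixtures demonstrates the model's internal
consistency (simulation vs linear theory, conservation, protocol
reproduction); it does not, of course, validate the model against any
measured cell.

## Pattern diagnostics

* **Peak tracking.** Sub-grid positions by parabolic interpolation through
  the maximum and its neighbours, unwrapped across the periodic seam;
  $v_p$ is the least-squares slope over the analysis window, with standard
  error. "Steady propagation" means the relative spread of instantaneous
  frame-to-frame speeds is below 2%; frames with more than one prominent
  peak (local maxima above the half-amplitude level) withhold $v_p$
  entirely. For stationary states the spread test is meaningless
  (division by a near-zero mean speed), so stationarity is asserted by
  $|v_p|$ itself.
* **Phase-plane loop.** Nullcline crossings of the trajectory
  $x \mapsto (m(x), c(x))$ are located by sign change of
  $c - c_{nc}(m)$ with linear interpolation; `cL`/`cR` are the crossings
  nearest the peak on its upstream/downstream flank, with "upstream"
  determined by the sign of $v_f$ (for $v_f = 0$ the left flank is called
  upstream by convention — the two are then equal to tolerance anyway).
  The loop area is the signed shoelace area of the $x$-ordered closed
  polygon. Deviation from the flux-balance subspace is measured against
  the best-fit line of fixed slope $-D_m/D_c$, normalized by the
  trajectory extent.
* **Mesa vs peak.** The decisive property is where the amplitude comes
  from: a mesa's top plateau sits at the upper intersection of the
  flux-balance line with the nullcline (attachment–detachment balance —
  local reactive equilibrium), while a peak's amplitude is mass-limited
  and its top is held against the reactions by membrane-diffusive
  curvature. The classifier therefore tests the relative reactive
  imbalance $|f|/(d(m)m)$ at the pattern maximum against `eq_tol`
  (default 0.1). A purely geometric rule (top-band width vs interface
  width) was tried first and rejected: genuinely saturated mesas near the
  transition have rounded tops that fail any fixed width ratio, while the
  reactive-imbalance criterion varies monotonically along both transition
  paths (flow speed and cytosol diffusivity) and flips exactly once.
  The geometric quantities (amplitude, top-band plateau width and
  fraction, 10–90% interface width) are still computed and reported as
  shape diagnostics, and all thresholds are exposed as arguments.
* **Speed prediction from linear theory.** The peak's propagation is
  carried by the unstable mode spanning its interfacial region, whose
  wavelength is set at the pattern's inflection point — the middle
  intersection of the flux-balance line with the nullcline.
  `predict_vp_lsa()` extracts that composition from a stationary no-flow
  reference pattern, linearizes there, and reports
  $-\mathrm{Im}\,\sigma(q_{max})/q_{max}$. It is a scaling estimate: exact
  at $v_f = 0$, sign-correct and within a factor of ~2 in the slow-flow
  regime, with the correct $\propto v_f$ and $\propto 1/v_f$ asymptotics.
* **Regional instability.** A cell is marked when its local total density
  lies in the laterally unstable interval of `unstable_density_range()`
  (evaluated without flow, since the regional argument compares the local
  nullcline slope with the flux-balance slope); a contiguous marked region
  triggers the instability only if wider than the shortest unstable
  wavelength $2\pi/q_{max}$ at the region's mean composition.

## Scenario reconstructions and problem sizes

The four presets pin down protocol details the figure-level descriptions
leave open; all reconstructed values are reported in run manifests.

* `fig2` (linear regime): $N = 256$, noise amplitude $5\times10^{-4}$,
  growth fitted on $t \in [2, 12]$ s — late enough for transients of the
  minor branch to die, early enough that the tracked mode is still below
  ~1% of $m^\ast$.
* `fig4` (upstream propagation): $L = 10$, periodic, relaxed single peak,
  flow $v_f = 20$ switched on at $t_0 = 240$ s, tracked over the last 60 s
  of a 120 s flow window. The flow-speed sweep uses
  $v_f \in \{0.5, 1, 2, 5, 10, 20, 50, 100, 200\}$.
* `fig5` (mesa→peak): $\bar n = 7$, $D_m = 0.1$, $L = 20$. "Slow" and
  "fast" flow are 1 and 50 µm/s and "fast diffusion" is $100 \times D_c$ —
  chosen to bracket the transition, which the sweep utilities then locate
  (between $v_f = 5$ and 10, and between $D_c = 10$ and 30, at these
  parameters). Settling time 400 s from the relaxed single-peak state.
* `fig6` (flow-induced polarization): no-flux walls, parabolic profile.
  The mean density is computed at run time as 95% of the lower edge
  $n_-$ of the no-flow laterally unstable interval ($n_- = 1.5046$ for the
  defaults), making the homogeneous state laterally stable but close to
  threshold; $v_{max} = 1$ µm/s is just strong enough to push the
  downstream edge across $n_-$ within the 600 s run while keeping the
  flow-deformed pattern close to its no-flow shape, so that switching the
  flow off changes the amplitude by under 5% over 500 s. The low-mass
  variant (50% of $n_-$, $v_{max} = 5$) sits below the range where any
  stationary pattern exists without flow: the flow-maintained peak
  collapses to the homogeneous state once the flow stops. The 50%/95%
  pair was located by scanning the no-flow survival of flow-formed
  patterns; the package recomputes $n_-$ rather than hard-coding it.

Protocol scenarios and sweeps run at $N = 256$ cells, where the measured
peak speed differs from $N = 512$ by 1.9% (under the 2% convergence
bound); the package default remains $N = 512$ for production use.

## Known limitations

* One spatial dimension, fixed domain, single protein species; no
  concentration-dependent or time-varying flow fields beyond the onset
  switch.
* The linear analysis is defined for uniform flow only; non-uniform
  profiles are handled by simulation plus the local (no-flow) regional
  criterion.
* First-order upwinding is diffusive at high cell Péclet numbers; for
  $|v_f| \gtrsim 100$ at default resolution, check the `central` scheme or
  refine the grid.
* The mesa/peak `eq_tol` and the regional-trigger width rule are sharp
  thresholds applied to smooth crossovers; near a transition the label is
  resolution- and tolerance-sensitive by nature, which is why the
  continuous diagnostics (`top_imbalance`, widths, loop area) are always
  reported alongside.
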