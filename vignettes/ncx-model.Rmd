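---
title: "Modelling allosterically regulated NCX dynamics in thin astrocyte processes"
author: "ncxdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allosterically regulated NCX dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncxdyn)
```

## The model and its assumptions

`ncxdyn` models calcium dynamics in a thin, endoplasmic-reticulum-free
astrocytic process in which the sodium–calcium exchanger (NCX) is the only
nonlinear membrane mechanism. The exchanger swaps 3 Na⁺ for 1 Ca²⁺ per
cycle; its net calcium flux is written as a product

$$J_\mathrm{ncx} = \bar J \; n_\infty([\mathrm{Ca}]_i)\; h \;
  J_{\Delta E}([\mathrm{Ca}]_i, [\mathrm{Na}]_i, V),$$

where $J_{\Delta E}$ is the normalized net rate of the main transport
cycle in the standard ping-pong bi-bi approximation (positive in reverse
mode, i.e. calcium entry), and the two gates describe allosteric
regulation from the cytosolic side:

* $n_\infty = 1/(1 + (K_n/[\mathrm{Ca}]_i)^2)$ — the fast, high-affinity
  calcium site. Its kinetics are an order of magnitude faster than the slow
  site's, so it is treated as instantaneous.
* $h$ — the slow gate: sodium drives the exchanger into an inactive state,
  calcium binding at a low-affinity site relieves it. Its steady state
  $h_\infty$ falls with $[\mathrm{Na}]_i$ and rises with
  $[\mathrm{Ca}]_i$; its time constant
  $\tau_h = \tau_\mathrm{min} + \tau_0/(1+([\mathrm{Ca}]_i/K_\tau)^{H_\tau})$
  shrinks from $\tau_\mathrm{min}+\tau_0$ at rest to
  $\tau_\mathrm{min} = 0.25$ s at high calcium.

Everything else — calcium pumps and buffering (in the excess-buffer
approximation), and the Na/K-pump — is lumped into linear relaxation
toward resting concentrations with single time constants $\tau_{Ca}$ and
$\tau_{Na}$. This is a deliberate reduction: the model isolates the
exchanger's feedback loop (entering calcium disinhibits further entry)
from every other source of nonlinearity.

Three variants share this flux law:

1. **Clamped-sodium model** in $([\mathrm{Ca}]_i, h)$, sodium a parameter
   — the phase-plane object. Its calcium nullcline
   $h_{ca}(\mathrm{Ca}) = (\mathrm{Ca}-\mathrm{Ca}_\mathrm{rest}) /
   (\tau_{Ca}\,\bar J\, n_\infty\, J_{\Delta E})$ is discontinuous where
   $J_{\Delta E}=0$; because $J_\mathrm{ncx}$ vanishes there while the
   leak does not, the discontinuity does not affect trajectories.
2. **Point model** in $([\mathrm{Ca}]_i, [\mathrm{Na}]_i, h)$ with
   external stimulus fluxes; the sodium equation carries the NCX term with
   coefficient exactly $-3$ (stoichiometry), the single place where the
   3:1 ratio enters.
3. **1D thin-process model**: the point model in each 0.35 µm element of a
   sealed segment, plus Fickian diffusion of Ca²⁺ and Na⁺ (the gate is a
   membrane protein state and does not diffuse).

A fourth configuration, the **allosteric-off control**, sets
$n \equiv h \equiv 1$ and rescales $\bar J$ by
$n_\infty(\mathrm{Ca}_\mathrm{rest})\,
h_\infty(\mathrm{Ca}_\mathrm{rest}, \mathrm{Na}_\mathrm{rest})$ so that
both variants carry identical NCX flux at rest. This rest-state matching
rule is this package's interpretation of "reduce $\bar J$ to compensate
for the higher ratio of active transporters"; any comparison between the
two variants is a comparison of *regulation*, not of flux capacity.

## Parameters: defaults and provenance

All defaults live in `inst/extdata/default_params.yaml`; nothing is
hard-coded in the formulas. Units: mM, s, mV at the interface (volts
inside exponentials, converted once in `cell_env()`), µm.

**Electrochemical constants** ($K_{M\cdot}$, $\eta = 0.35$,
$k_{sat} = 0.27$) are the Weber et al. (2001) cardiac NCX1 values, adopted
unchanged — the standard literature parameterization of $J_{\Delta E}$.

**Allosteric constants are not experimentally known for astrocytic NCX.**
The shipped values were chosen once, within physiological guidance, so
that the model exhibits the qualitative regimes the mechanism predicts,
and then frozen:

| parameter | default | rationale |
|---|---|---|
| $K_n$ | 0.1 µM | fast gate half-activates in the ~100 nM range |
| $K_{Ca}, H_{Ca}$ | 1 µM, 2 | slow-gate relief at the ~1 µM level |
| $K_{Na}, H_{Na}$ | 8 mM, 4 | inactivation already engaged at resting Na (15–20 mM), saturated by ~25 mM |
| $\tau_0, K_\tau, H_\tau, \tau_\mathrm{min}$ | 10 s, 1 µM, 2, 0.25 s | slow recovery at rest, fast (0.25 s) at high calcium |
| $\bar J$ | 0.02 mM/s | flux scale giving a monostable rest and a bistable Na-loaded regime at −80 mV |

With these values the resting gate is ~91% inactivated
(`h_inf(1e-4, 15)` ≈ 0.086) — sodium inhibits the exchanger already at
rest — and the bistable region in the $(V, \mathrm{Na}_i)$ plane has a
monotone boundary: more depolarization, less sodium needed. The choice
$K_{Na} < \mathrm{Na}_\mathrm{rest}$ with a steep Hill coefficient is
what makes the low-calcium state robust across the physiological voltage
range; shallower sodium dependence confines bistability to a
hyperpolarized corner.

**Homeostasis**: $\mathrm{Ca}_\mathrm{rest} = 0.1$ µM,
$\tau_{Ca} = 5$ s (lumped pump + buffer clearance),
$\mathrm{Na}_\mathrm{rest} = 15$ mM, $\tau_{Na} = 20$ s (Na/K-pump;
activity-dependent sodium transients in astrocytes decay on tens of
seconds). **Environment**: 2 mM Ca²⁺ and 140 mM Na⁺ outside, −80 mV,
310 K.

Because the exchanger is generally *not* at its reversal point at rest,
the true unstimulated equilibrium differs slightly from the nominal
$(\mathrm{Ca}_\mathrm{rest}, \mathrm{Na}_\mathrm{rest})$. All simulations
therefore start from the variant's own numerically determined rest state
(`find_rest_state()`); superposition analyses would otherwise be
contaminated by settling drift that masquerades as nonlinearity at small
pulse amplitudes.

## Stimulation presets: what they emulate

Stimuli are additive boxcar flux pulses — idealized "virtual pipettes",
standing in for transporter-mediated sodium entry and brief
channel-mediated calcium entry. The presets are YAML data, not code.

* **Paired short pulses** (`preset_fig2a`): two events, each a 15 s sodium
  pulse (0.8 then 1.6 mM/s) with a simultaneous 5 s calcium pulse
  (10⁻⁴ mM/s). The measured quantity is the amplification index: the peak
  of the joint response minus the peak of the linear sum of the
  single-species responses, normalized by the joint peak excursion. A
  quarter-amplitude family probes the linear regime, where the
  allosteric-off control stays within 5% of additivity.
* **Long sodium elevation** (`preset_fig2b`): sodium influx from t = 50 to
  500 s at one of four amplitudes (quasi-steady plateaus ≈25, 30, 35,
  45 mM), calcium probes at t = 200 and 600 s. The window follows the
  50–500 s timing; the amplitude ladder was chosen so that the transient
  half-width grows monotonically and only the top level sustains a
  high-calcium state until sodium offset.
* **Wave** (`preset_wave`): 40 µm sealed domain, dx = 0.35 µm; sodium
  influx (10 mM/s) on the interval [0, 10] µm from t = 10–30 s; a 2 s
  calcium pulse on the central 0.35 µm element at t = 20 s; anisotropy
  measured at t = 28 s.

A physical point decided the wave preset's shape. With any literature-
plausible sodium diffusivity, a *brief* one-sided sodium pulse cannot
maintain a gradient in a sealed 40 µm segment: the profile flattens
within seconds ($\sqrt{D_{Na}\tau_{Na}}$ exceeds the domain). A sustained
influx, in contrast, maintains a standing quasi-steady gradient of order
(source flux)/$D_{Na}$ — about 7 mM side-to-side here. The preset
therefore keeps the sodium source on through the measurement window, and
the calcium probe lands while the gradient stands. The resulting
anisotropy is genuine reaction–diffusion asymmetry: on the loaded side
the calcium cloud sits below the exchanger's reversal point (reverse
mode, amplification), on the other side partly above it (forward mode,
attenuation).

**Diffusion constants**: $D_{Ca} = 13$ µm²/s is a standard effective
(buffered) cytosolic value; $D_{Na} = 50$ µm²/s is deliberately an
*apparent* value well below free solution (~1300 µm²/s) — crowding and
tortuosity in a ~100 nm process — while staying several-fold above
$D_{Ca}$. Both are plain config entries.

The sodium-deflection analysis (`sodium_drop_check()`) measures the
calcium pulse's effect on sodium against a matched control run without
the calcium pulse, not against the pre-pulse level: the homeostatic
relaxation toward the sodium plateau is orders of magnitude larger than
the exchanger's contribution and would otherwise hide the sign of the
effect (negative under loaded reverse-mode conditions, small positive at
rest).

What the presets do **not** emulate: stochastic channel openings, glial
geometry (varying radius, branching), electrodiffusion, potassium-driven
voltage changes (V is a parameter), or store-operated calcium dynamics.
Passing tests demonstrate the mechanism's internal consistency under
idealized drive, not quantitative agreement with recordings.

## Numerical choices

* **Integration**: `deSolve::lsoda` everywhere (stiffness-switching;
  $\tau_h$ reaches 0.25 s against 5–20 s relaxations), relative tolerance
  1e-8, absolute 1e-12. Protocol discontinuities are declared as
  integration breakpoints: the run is split at every pulse edge and the
  applied flux is constant on each piece, so the solver never steps across
  an edge. Halving tolerances moves endpoints by < 1e-6 relative (tested).
* **Negative concentrations** are rejected, never clipped — in the pure
  functions (domain guards) and at solver output. Clipping would hide
  integrator failures.
* **Spatial operator**: second differences with ghost cells mirrored
  across the boundary *face* (ghost = end cell). This choice makes the
  no-flux scheme exactly conservative — the sum of second differences
  telescopes to zero — which the conservation test verifies at 1e-8 over
  diffusion-only runs. Spatial pulse masks weight elements by fractional
  overlap with the pulse interval, so the injected amount is independent
  of dx; this is what makes grid-halving convergence (< 2% in sup-norm)
  a meaningful check. An optional fixed-step explicit mode exists for
  cross-checks and refuses any step above the diffusion stability bound
  $dx^2/(2\max D)$.
* **Equilibria**: a 2000-point log-spaced sign-change scan of the
  nullcline difference (excluding the reversal discontinuity, which is a
  sign change but not a root), `uniroot` refinement, then a damped-Newton
  polish with central-difference Jacobians (written in-package; residuals
  < 1e-10). Stability from 2×2 Jacobian eigenvalues; real parts within
  1e-9 of zero are labelled "marginal", never silently stable.
  Deduplication radius 1e-6 in scaled (µM, –) coordinates.
* **Basins**: forward integration per grid cell with an event function
  stopping at 1% of the smallest inter-equilibrium distance (scaled
  coordinates); horizon 10·max($\tau_{Ca}$, $\tau_0$) by default; cells
  that run out of horizon are counted as unresolved rather than guessed.
* **Degenerate inputs**: $\bar J = 0$ is admitted as the exchanger-free
  control and handled analytically in the equilibrium finder (the system
  is then linear with a single equilibrium); $n_\infty(0) = 0$ and
  $h_\infty(\cdot, 0) = 1$ are computed exactly at the limits.

Problem sizes used by the shipped tests: 50×50 bifurcation scans, 115–229
element spatial grids, 800 s point-model runs — each chosen as the
smallest size at which the corresponding claim is cleanly resolved.

## Known limitations

* All allosteric constants are calibrated, not measured; the package
  reproduces mechanisms and orderings, and makes no claim of numeric
  agreement with any particular recording or figure.
* The kinetic basis is cardiac NCX1 data; astrocytic isoform mixtures and
  tissue-dependent kinetics are not represented.
* Membrane potential is a fixed parameter; sodium loading in reality
  coexists with potassium-driven depolarization, which the bifurcation
  maps explore only statically.
* The 1D model is a sealed, uniform-radius segment. Open boundaries or a
  coupled soma would act as sinks and shrink the bistable/propagating
  regimes.
* Lumped linear homeostasis ignores pump saturation; at large sodium
  loads the real Na/K-pump would saturate and prolong recovery.
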