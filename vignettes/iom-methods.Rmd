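---
title: "The Integrated Oscillator Model in betaburst: equations, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Integrated Oscillator Model in betaburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(betaburst)
```

## The model

`betaburst` implements the Integrated Oscillator Model (IOM) of the
pancreatic β-cell: three coupled biophysical modules whose interaction
produces the cell's characteristic bursting electrical activity and the
parallel oscillations in Ca²⁺ and metabolism.

**Electrical activity and Ca²⁺ handling.** The membrane carries four
currents — a voltage-dependent Ca²⁺ current with instantaneous activation
$m_\infty(V)$, a delayed-rectifier K⁺ current with one gating variable $n$,
a Ca²⁺-activated K⁺ current (K(Ca)) with Hill activation in cytosolic Ca²⁺,
and the ATP-sensitive K⁺ current

$$I_{K(ATP)} = g_{K(ATP)}\, o_\infty(ATP, ADP)\, (V - V_K),$$

whose open fraction

$$o_\infty = \frac{0.08 + 0.89\,(MgADP/k_{dd})^2 + 0.16\,(MgADP/k_{dd})}
  {(1 + MgADP/k_{dd})^2\,\bigl(1 + ATP^{4-}/k_{tt} + ADP^{3-}/k_{td}\bigr)}$$

couples metabolism to the membrane.  The channel-regulating species are
fixed fractions of the cytosolic totals ($MgADP = 0.165\,ADP$,
$ADP^{3-} = 0.135\,ADP$, $ATP^{4-} = 0.05\,ATP$).  Cytosolic Ca²⁺ exchanges
with the ER (SERCA pump, passive leak) and with mitochondria, and drives
the plasma-membrane Ca²⁺-ATPase.

**Glycolysis.** Glucose enters solely through a saturating glucokinase
flux.  The allosteric phosphofructokinase (PFK) step uses a
weighted-binding-state (tetramer) formulation with activators AMP and FBP,
inhibitor ATP, and cooperatively bound substrate F6P; each ligand enters as
a squared concentration, which gives the FBP product-activation the
cooperativity required for the autocatalytic switch underlying intrinsic
glycolytic oscillations.  FBP is drained by the Ca²⁺-sensitive
glycerol-3-phosphate dehydrogenase reaction,

$$J_{GPDH} = \frac{Ca_m^2}{K_{GPDH} + Ca_m^2}\,FBP,$$

so mitochondrial Ca²⁺ sets the effective drain rate.  AMP follows the
adenylate-kinase equilibrium $AMP = ADP^2/ATP$.

**Mitochondria and nucleotides.** Pyruvate dehydrogenase feeds the
NADH pool,

$$J_{PDH} = v_{PDH}\,\frac{1}{K_{PDH} + NADH_m/NAD_m}\,J_{GPDH},$$

respiration oxidizes NADH and pumps protons, the F1F0 ATP synthase and the
adenine nucleotide translocator (ANT) convert the inner-membrane potential
$\Delta\psi_m$ into cytosolic ATP, and an exponential proton leak is the
dominant charge sink that stabilizes $\Delta\psi_m$.  Ca²⁺ crosses the
inner membrane through the uniporter,

$$J_{uni} = (p_{21}\,\Delta\psi_m - p_{22})\,Ca_c,$$

and returns through the electrogenic Na⁺/Ca²⁺ exchanger.  Cytosolic ATP is
consumed at a basal rate plus a Ca²⁺-dependent term representing the plasma
membrane and ER Ca²⁺ pumps, $J_{hyd} = (k_{hyd} + k_{hyd,Ca}\,Ca_c)\,ATP_c$.

Three totals are conserved exactly: mitochondrial NAD(H), mitochondrial and
cytosolic adenine nucleotides.

## The two oscillation mechanisms

The model houses the two rhythm generators whose competition the package's
analysis layer classifies:

* **Passive metabolic oscillations (PMO).**  Ca²⁺ oscillations drive
  metabolism: each active phase raises hydrolysis and perturbs the
  mitochondrial fluxes, so ATP/ADP oscillates *because* Ca²⁺ does.  Holding
  Ca²⁺ constant kills the metabolic rhythm.  At `vpdh = 0.4` the FBP time
  course is a sawtooth locked to the burst cycle.
* **Active metabolic oscillations (AMO).**  The PFK product-activation
  switch plus substrate depletion — amplified around the loop
  FBP → PDH → NADH → ψ_m → Ca_m → GPDH drain → FBP, whose gain scales with
  `vpdh` — generates an intrinsic metabolic rhythm that persists at a
  suitable *constant* Ca²⁺ level.  At `vpdh = 2` FBP is pulsatile: sharp
  peaks decaying to near zero.

`classify_mechanism()` operationalizes the distinction exactly as an
experiment would: clamp cytosolic Ca²⁺ at a scan of fixed levels and ask
whether FBP oscillations survive at any of them.

## Parameters

Only a handful of constants are fixed by the literature this model family
rests on: the nucleotide partition fractions and the numeric constants of
$o_\infty$, the diazoxide and KCl conventions (`ktt` 1→2 µM, `vk`
−75→−70 mV), the regime knobs `vpdh` ∈ {0.4, 2, 3, 7} µM/ms and `gkca` ∈
{150, 600} pS, the uniporter slopes `p21` ∈ {0.013, 0.03}, and the glucose
levels 11 and 5 mM.  Every remaining rate, conductance, and dissociation
constant in `iom_parameters()` is a package-level calibration chosen once so
that the default parameter set reproduces the canonical regimes
simultaneously:

* slow bursting with sawtooth FBP at `vpdh = 0.4` and pulsatile FBP at
  `vpdh = 2` (both with oscillating ATP);
* compound bursting — fast bursts grouped into ≈5-minute episodes — when
  `gkca` rises from 150 to 600 pS;
* clamp-persistent metabolic oscillations at `vpdh = 2` and clamp-killed
  ones at `vpdh = 0.4`.

Choices that carry mechanistic weight (each was found to be necessary
during calibration, not decorative):

* **Squared PFK ligand weights** (`k1`–`k4` are dissociation constants for
  the *squared* concentrations).  With first-order FBP binding the product
  activation cannot fold against the linear GPDH drain and no glycolytic
  limit cycle exists.
* **Exponential proton leak** (`p17`, `p18`).  The leak is the dominant
  ψ_m sink; its steepness sets both the resting ψ_m and how far ψ_m spreads
  across the `vpdh` regimes, which in turn positions each regime's Ca_m and
  therefore its GPDH drain.
* **Weak mitochondria→cytosol Ca²⁺ coupling** (`deltam = 0.1`).  The
  uniporter/exchanger fluxes, fed back at full weight, act as a slow
  Ca²⁺ feedback that entrains the membrane to a 2–3-minute rhythm and
  masks the fast K(Ca) burst mechanism; reducing their weight in the
  cytosolic balance exposes the fast bursting that compound oscillations
  require.
* **Slow mitochondrial relay** (`gamma`, `cmito`, `fm`).  The
  NADH–ψ_m–Ca_m loop is the clock of the compound-bursting envelope; its
  timescales were set so the episode period lands near 5 minutes.  The
  trade-off is documented under Limitations.
* **PFK activation knee** (`k2 = 0.04` µM²).  The knee sits between the
  FBP scales of the two slow-bursting regimes, so the `vpdh = 2` regime
  switches through it every cycle (pulsatile) while the `vpdh = 0.4` regime
  stays above it (sawtooth).

Units are ms, mV, pS, fA, and µM (glucose in mM); all fluxes are
cytosol-referenced, with `gamma`, `fm`, and `cmito` lumping the
volume-ratio and buffering conversions for the mitochondrial pools.

## Protocols, solver, and numerical choices

Protocols are ordered timed events (`proto_dz()`, `proto_kcl()`,
`proto_glucose()`, `proto_clamp()`, `proto_set()`).  Integration restarts
at each event with the pre-event state: parameter jumps are discontinuous
and restarting is exact, so no event interpolation is used.  The Ca²⁺
clamp zeroes the cytosolic Ca²⁺ derivative and pins its value (ER and
mitochondrial Ca²⁺ stay dynamic); a clamp without a stated level uses the
silent-phase level, the 10th percentile of cytosolic Ca²⁺ over the
preceding 5 minutes.

The stiff system is integrated with `deSolve::ode` (lsoda) at `rtol = 1e-8`,
`atol = 1e-10`; output is sampled every 100 ms and all derived fluxes,
currents, and concentrations are recomputed from the state at output times.
The compiled C right-hand side is the production path; a pure-R reference
implementation of the same equations is kept and the two are asserted equal
in the test suite.  Measured burst periods change by well under 1% when
both tolerances are tightened tenfold.

The documented initial state is a fixed, arbitrary interior point; every
analysis discards a 20-minute transient, and `equilibrate_iom()` uses the
same 20-minute convention.  The model is multistable in parts of parameter
space (notably at `gkca = 600`, where a slow-bursting attractor coexists
with the compound one), so a single transient convention — rather than a
long pre-equilibration that can land on a different attractor — keeps all
scenario measurements on the attractor that develops from the documented
state.

## The analysis layer

`detect_bursts()` applies a hysteresis criterion to a 2-s moving average of
V, with entry/exit thresholds at the 60th/40th percentiles of the smoothed
trace (clamped away from its extremes so both thresholds remain crossable).
`measure_period_amplitude()` takes the period from the dominant
autocorrelation peak and averages max–min over complete cycles only.
`classify_fbp_waveform()` calls a trace pulsatile when at least 30% of each
cycle sits below 10% of the cycle peak.  `detect_episodes()` splits burst
sequences at gaps exceeding twice the median gap.  All thresholds are
arguments with the defaults above; reports record the thresholds used.
These are model-facing choices: the corresponding experimental traces are
noisy enough that the sawtooth/pulsatile distinction is hard in practice,
and no claim is made that these thresholds are robust to recording noise.

## Worked example

```{r example, eval = FALSE}
## compound bursting at g_K(Ca) = 600 pS
traj <- simulate_iom(iom_parameters(vpdh = 2, gkca = 600),
                     t_span = 60, init = iom_initial_state())
kept <- traj[traj$t >= 20, ]
bursts <- detect_bursts(kept$t, kept$v)
detect_episodes(bursts)$episode_period   # ~5 min
plot(traj, vars = c("v", "cac", "fbp", "atpc"))
```

## What the simulations do and do not show

The package simulates a deterministic representative cell in a
well-synchronized islet.  Channel noise, cell-to-cell heterogeneity,
gap-junction coupling, and insulin secretion itself are all out of scope,
so agreement between the package's regime classifications and its own
simulated trajectories says nothing about the variability of real islet
recordings.

**Limitations of this calibration.**  Because the original model archive
for this family is not bundled, all unprinted constants are reconstructed,
and one calibration cannot currently satisfy every canonical behavior at
once:

* The ψ_m phase relation during bursts (hyperpolarizing at `p21 = 0.013`,
  depolarizing at 0.03) requires the mitochondrial variables to respond
  *within* an active phase, while the ≈5-minute compound envelope requires
  the same variables to be slow.  With the envelope prioritized, the
  default calibration measures a flat ψ_m phase at `p21 = 0.013`.
* ATP production is nearly flat in glucose between 5 and 11 mM (a side
  effect of the redox compensation in the PDH term), so electrical
  activity does not shut off at 5 mM; the subthreshold-oscillation
  protocol reproduces persisting FBP oscillations but not electrical
  silence.
* In the diazoxide/KCl matrix, the clamp-rescue ladder across `vpdh`
  reproduces its extremes (`vpdh = 0.4` never rescued; a clamp window
  exists for `vpdh = 2`) but not the full four-row ordering.

These gaps are measured by the acceptance suite rather than hidden by it:
the corresponding assertions are written at the canonical expectations and
fail honestly under the default calibration.
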