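# betaburst

Simulation and analysis of the **Integrated Oscillator Model (IOM)** of the
pancreatic β-cell: a stiff 11-variable ODE system coupling membrane
electrical activity and Ca²⁺ handling, an allosteric-PFK glycolytic
oscillator, and a reduced mitochondrial bioenergetics module.  The package
is for modelers and quantitative physiologists who want to run the model's
canonical in-silico experiments — diazoxide, KCl depolarization, cytosolic
Ca²⁺ clamps, glucose steps — and to phenotype the resulting rhythms
automatically.

## The model in brief

Membrane potential obeys a current balance over four currents,

    dV/dt = −(I_Ca + I_K + I_K(Ca) + I_K(ATP)) / C_m,

where the K(ATP) current ties electrical activity to metabolism through the
equilibrium open fraction

    o∞ = [0.08 + 0.89 (MgADP/k_dd)² + 0.16 (MgADP/k_dd)]
         / [(1 + MgADP/k_dd)² (1 + ATP⁴⁻/k_tt + ADP³⁻/k_td)],

with MgADP = 0.165·ADP, ADP³⁻ = 0.135·ADP, ATP⁴⁻ = 0.05·ATP.  Glycolysis
feeds mitochondria through the Ca²⁺-activated GPDH reaction
J_GPDH = Ca_m²/(K_GPDH + Ca_m²)·FBP and the PDH reaction
J_PDH = v_PDH·J_GPDH/(K + NADH_m/NAD_m); Ca²⁺ enters mitochondria through
the uniporter J_uni = (p21·ψ_m − p22)·Ca_c.  Two slow rhythm generators
coexist: a Ca²⁺-driven (passive) metabolic oscillation and an intrinsic
(active) glycolytic one; which dominates depends chiefly on `vpdh`.

## Worked example

```r
library(betaburst)

## compound bursting: raise the K(Ca) conductance from 150 to 600 pS
params <- iom_parameters(vpdh = 2, gkca = 600)
traj <- simulate_iom(params, t_span = 60, init = iom_initial_state())

kept <- traj[traj$t >= 20, ]            # discard the 20-min transient
bursts <- detect_bursts(kept$t, kept$v)
detect_episodes(bursts)$episode_period
#> [1] 5.421429
```

The number printed is the mean spacing (minutes) between onsets of burst
*episodes* — groups of fast bursts packaged by the slow metabolic
oscillation — and is the model's counterpart of the ~5-minute period of
pulsatile insulin secretion.

Other entry points:

```r
run_scenario("fig3_amo")      # preset regimes with phenotype assertions
iom_protocol(proto_dz(15), proto_kcl(30))   # timed pharmacology
classify_mechanism(iom_parameters(vpdh = 2))  # PMO vs AMO clamp experiment
regime_scan(list(vpdh = c(0.4, 2, 3, 7)))     # labeled parameter sweeps
```

A thin command-line wrapper is installed as `exec/betaburst`
(`simulate`, `scenario`, `analyze`, `scan`, `--list-scenarios`).

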