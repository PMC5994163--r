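---
title: "From kinetic logic to jet-lag simulation: the methods behind clocknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From kinetic logic to jet-lag simulation: the methods behind clocknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clocknet)
```

clocknet models the coupling between the mammalian circadian clock and the
cell-cycle regulators MYC and p53, and asks how jet-lag-like disruption of
the clock propagates to those two proteins. The pipeline has three stages,
each of which this vignette describes together with the assumptions,
parameters and numerical choices behind it: a qualitative (kinetic-logic)
regulatory network whose unknown logical parameters are inferred by CTL
model checking, a timed continuous Petri net derived from the selected
logical model, and three simulation scenarios — normal, mild and chronic
jet lag — compared through oscillation metrics.

## The regulatory network and its kinetic-logic semantics

The network couples six boolean entities: BMAL1 (`Bmal`), the CLOCK-BMAL1
complex (`CB`), the PER-CRY complex (`PC`), the REV-ERB nuclear receptors
(`Rev`), and the cell-cycle proteins `Myc` and `p53`. Six interactions are
activations (Bmal→CB, CB→PC, CB→Rev, Bmal→p53, Myc→p53 and the Myc
self-loop) and four are inhibitions (PC→CB, Rev→Bmal, CB→Myc, p53→Myc);
every threshold is 1, so the system is boolean. The positive Myc self-loop
encodes its repeated mitogen-driven activation; the Myc→p53 activation
encodes oncogenic-stress signalling; CB and p53 jointly restrain Myc.

Dynamics follow Thomas' kinetic logic. In a state (one level per entity),
the *resources* of an entity are the regulators currently helping it:
activators at or above their threshold and inhibitors below theirs (an
absent inhibitor counts as help). A *K-parameter* `K_entity{resources}`
gives the level the entity then moves toward. Transitions are
*asynchronous and unit-step*: each entity whose target differs from its
current level yields one successor in which that entity alone moves one
level toward the target. States with no enabled change receive a
self-loop, so the transition relation is total and CTL's next-state
operators are well defined everywhere. Resource sets are canonicalised by
sorting regulator names, which gives stable parameter-table keys.

```{r toy}
toy <- toy_fixture()
g <- build_state_graph(toy$network, toy$params)
g
```

The two-entity fixture above (X activates Y, Y inhibits X) produces the
classic four-state closed cycle — the smallest demonstration that
asynchronous kinetic logic, unlike synchronous boolean updating, sustains
oscillation.

## Parameter inference by CTL model checking

Most K-parameters of the clock/MYC/p53 network are pinned by the biology
(e.g. `K_PC{CB} = 1`: PER-CRY rises while CLOCK-BMAL1 is present). Three
entries are genuinely uncertain, and `circadian_fixture()$space` leaves
exactly those free: `K_CB{Bmal}`, `K_Myc{Myc}` and `K_Myc{CB,p53}`, giving
a candidate space of 2³ = 8 parameter tables. Candidates are enumerated in
lexicographic key order so that reported indices are reproducible, and
`enumerate_tables(space, snoussi = TRUE)` optionally applies the
resource-monotonicity restriction (K may not decrease when a resource is
added), which here pins `K_Myc{Myc} = 0` because `K_Myc{Myc,p53}` is fixed
at 0.

Five temporal-logic properties (`psi_library()`) encode the observed
behaviour: ψ1 homeostasis (the near-zero resting state keeps returning),
ψ2 clock trough recurrence together with reachable persistent
Myc-high/p53-off expression, ψ3 a p53 recovery path (`E[p53=0 U p53=1]` —
the until is existential, matching the existential outer connectives), ψ4
reachable persistent Myc over-expression, and ψ5 reachable persistent p53
suppression. A candidate model is accepted when the conjunction holds in
**every** state of its graph (all-states acceptance, the convention of
checking with every state initial).

Two design points deserve emphasis:

* **ψ1's initial state deliberately omits Bmal.** The resting state is
  written `CB=0 ∧ PC=0 ∧ Rev=0 ∧ Myc=0 ∧ p53=0` with Bmal free, although
  "all entities at zero" would suggest including it. The formula is kept
  as specified; with Bmal free, homeostasis is demanded from both Bmal
  phases of the trough, which is the stronger and biologically sensible
  reading.
* **Persistence is encoded with the existential globally (`EG`), not
  `AG`.** In asynchronous semantics a poised antagonist always has a path
  on which it fires: from any Myc-high state there is a path on which p53
  rises (its activation by Myc is fixed at 1) and Myc subsequently falls,
  so `EF(AG Myc=1)` holds in *no* state for *any* table of the candidate
  space — the universal reading makes the property vacuously
  unsatisfiable rather than discriminating. ψ2 already expresses the same
  biological condition ("Myc persistently high while p53 is off") as
  `EF(EG …)`, and ψ4/ψ5 follow that idiom. `psi_library(universal =
  TRUE)` exposes the `AG` variants, and the test suite verifies their
  space-wide unsatisfiability so the choice stays visible.

```{r select}
circ <- circadian_fixture()
select_models(circ$space, psi_library()$psi_all)
```

Four of the eight candidates pass; they differ only in K_CB and K_Myc
entries, and the biologically designated table (`circ$selected`) is among
them. The model checker itself is a textbook explicit-state labeller
(least fixed points for EF/AF/EU/AU, greatest for EG/AG); an independent
oracle (`brute_force_ctl`) recomputes satisfaction through reachability
algebra on the adjacency matrix, and the two are required to agree
state-by-state on hundreds of randomly generated network/formula pairs.

## The timed continuous Petri net

`logical_to_petrinet()` converts the selected boolean model into a
continuous Petri net with *complementary places*: entity E gets `P_E`
(expression) and `P_E_n` (its complement) with `P_E + P_E_n = 1` at all
times, plus an activation transition `t_E_p` (moves marking `P_E_n → P_E`)
and an inhibition transition `t_E_n` (the reverse). Enabling encodes the
K-logic: markings are thresholded at 0.5 (the midpoint of the boolean
range, symmetric in both directions), and `t_E_p` is enabled when the
resulting discrete state gives E the target 1, `t_E_n` when the target
is 0. An enabled transition fires at speed `rate × marking(source place)`
— mass action in the source place — so trajectories are smooth saturating
exponentials rather than piecewise-linear ramps.

Oscillation timing is imposed by a *gate subnet* of deterministic delayed
transitions. Each gated clock entity has a gate toggled on and off once
per 24 h period; while on, only `t_E_p` may fire, while off only `t_E_n`.
The default schedule (`default_gate_schedule()`) is calibrated so that
with the normal rates the expression maxima fall at the experimentally
reported clock times — BMAL1 ≈ 06:00 (on 18, off 6), REV-ERBs ≈ 08:00 (on
0, off 8), PER-CRY ≈ 18:00 (on 6, off 18). CLOCK-BMAL1 is left ungated:
it simply tracks the thresholded BMAL1 marking through its K-logic, which
places its peak ≈ 40 min after BMAL1's. Myc and p53 are never gated —
they evolve only through their regulators, which is the whole point of
the model — and `attach_gates()` rejects schedules that name them. The
delay values of the gate subnet are a reconstruction targeted at the
quoted peak times; they are configurable, and all downstream claims are
made relative to this default.

Kinetic rates (`rate_preset()`, per hour) are the per-scenario knob:

| entity | normal (act/inh) | mild | chronic |
|---|---|---|---|
| BMAL1 | 1 / 1 | 0.50 / 1.3 | 0.15 / 2 |
| CLOCK-BMAL1 | 1 / 1 | 1 / 1 | 1 / 1 |
| PER-CRY | 0.97 / 1 | 0.40 / 1.3 | 0.20 / 2 |
| REV-ERB | 0.97 / 1 | 0.40 / 1 | 0.20 / 1 |
| Myc, p53 | 1 / 1 | 1 / 1 | 1 / 1 |

Jet lag is modelled purely as damped activation / strengthened inhibition
of the light-sensitive clock proteins; the Myc/p53 module keeps unit
rates throughout, so any change in its behaviour is transmitted through
the clock.

## Numerical integration

Between events every marking obeys a scalar linear ODE
`dm/dt = act·(1−m)·[p enabled] − inh·m·[n enabled]`, so the simulator
propagates the *exact* exponential solution segment by segment and
restarts at each event: delayed gate firings (known times) and 0.5
threshold crossings (solved in closed form per segment). The output
`step` argument (default 0.05 h) only controls the sampling grid; halving
it leaves shared samples bitwise-stable, which the suite asserts at 1e-4.
Complementary conservation is exact by construction and checked to 1e-6
over 120 h horizons.

One genuine numerical subtlety arises from the Myc–p53 negative loop.
During the part of the day when the clock leaves both proteins
unconstrained, the switched dynamics spiral into the point where both
markings sit on the 0.5 switching surface, with switching intervals
shrinking geometrically — a Zeno accumulation: infinitely many crossings
in finite time. The simulator handles this in the Filippov sense: a long
run of near-instantaneous crossings (50 events shorter than 1e-4 h)
freezes the markings caught on the surface at exactly 0.5, and a frozen
set is released only when a *consistent escape mode* exists — an
assignment of levels to the frozen places under which every frozen
marking's field pushes it to the side of 0.5 that the assignment claims.
In practice Myc and p53 slide at 0.5 until the next BMAL1 threshold
crossing re-polarises them. The clamp perturbs the stored trajectory by
less than the 1e-3 capture radius and keeps the event count finite
without touching the exact integration elsewhere.

Simulations start from the all-zero marking (every entity at level 0,
clock time midnight), matching the resting state of ψ1, and the first
24 h are discarded from every metric as transient. The shipped analyses
use a 120 h horizon (five periods: one transient + four analysed) at step
0.05 h; these sizes were chosen so that four full post-transient cycles
support the period, phase and ordering statistics.

## Scenario metrics and the severity ordering

`run_scenario()` chains the whole pipeline and reports, per entity, the
oscillation period (mean spacing of post-transient local maxima), the
peak clock time (circular mean of per-cycle argmax times modulo 24), peak
and trough values and amplitude, plus the Myc/p53 anti-phase score — the
Pearson correlation of the two markings after the transient, "opposite"
when negative. In the normal scenario the clock proteins oscillate with
period 24 h and peaks at 6.0 (BMAL1), 8.0 (REV-ERB) and 18.0 (PER-CRY),
and the Myc/p53 correlation is strongly negative (≈ −0.94).

`compare_scenarios()` derives three ordering verdicts, computed from the
stored trajectories and never asserted independently:

* **p53 suppression** — the maximum p53 marking within each full
  post-transient 24 h cycle decreases strictly from normal to mild to
  chronic. Because p53 keeps unit rates and the gate dwell is long, its
  per-cycle maxima sit near saturation and the strict decreases are small
  in absolute terms; they are nonetheless exact, deterministic and stable
  across output steps. Mid-range suppression (window means) is far more
  visible but the maxima are the contract here.
* **Myc persistence** — the persistence index (minimum/maximum marking
  over the comparison time frames 10–20, 30–40, 50–60 and 80–90 h)
  increases strictly with severity: normal Myc collapses almost to zero
  each cycle, chronic Myc stays measurably above its floor.
* **clock amplitude damping** — each gated clock protein's post-transient
  amplitude decreases strictly with severity.

`severity_rates(alpha)` interpolates linearly between the normal and
chronic presets, which turns the three discrete scenarios into a sweep;
p53 suppression is monotone along it. The shipped mild preset is its own
calibration, not the sweep midpoint — `severity_rates(0.5)` gives BMAL1
activation 0.575 whereas the mild preset uses 0.50 — so the sweep is a
generalisation, not a re-derivation, of the mild scenario.

## What the synthetic generators emulate — and what they do not

`random_brn()` draws weakly connected signed boolean digraphs with
complete (optionally Snoussi-monotone) parameter tables, and
`random_ctl_formula()` samples bounded-depth formulas (depth ≤ 4, atom
probability 0.4 at inner nodes — deep enough to nest every operator while
keeping the brute-force oracle trivial). These match the structural class
of the circadian instance (boolean, threshold-1, signed) and exist to
fuzz the checker and the graph machinery; they make no claim to emulate
wet-lab expression data. The pipeline is fully deterministic end to end —
there is no noise model anywhere, so passing tests demonstrate logical
and numerical correctness of the reconstruction, not robustness to
biological variability.

## Known limitations

* Multi-valued entities (thresholds above 1) are supported by the
  state-graph machinery but not by the Petri net conversion, which
  requires boolean networks; the circadian instance is entirely boolean.
* The gate subnet is a phase-calibrated reconstruction; absolute marking
  values ("relative expression") are not meaningful beyond the orderings
  and phases reported, and the per-cycle p53 maxima separate scenarios
  only marginally under unit p53 rates (see above).
* All-states CTL acceptance and the existential persistence reading are
  conventions; both are surfaced in the API (`ctl_satisfies`,
  `psi_library(universal = TRUE)`) rather than buried.
* The model checker is explicit-state and intended for small graphs
  (≤ a few thousand states); there is no symbolic (BDD) backend, no
  fairness, and no LTL.
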