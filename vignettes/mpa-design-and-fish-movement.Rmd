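---
title: "How movement assumptions shape no-take area design: the model behind mpaschool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How movement assumptions shape no-take area design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpaschool)
```

## The question

A no-take marine protected area (MPA) can rebuild an overfished stock and,
through spillover, feed the fishery that surrounds it. How large the closure
must be depends on how far and how coherently the fish move: a sedentary
stock is protected by a small closure, a highly mobile one exports itself to
the fleet. `mpaschool` implements an individual-based model of an
anchovy-like small pelagic stock coupled to a density-following fishing
fleet, and asks how the *optimal* MPA size — the closed fraction that
maximizes long-run landings — changes along a ladder of movement
assumptions:

* **(a) diffusion** — every fish performs an isotropic random walk;
* **(b) schooling** — fish interact through zones of repulsion,
  orientation and attraction (a Vicsek-type model with metric zones);
* **(c) schooling + temperature taxis** — schools also climb the gradient
  of a thermal comfort function toward their preferred 16–18 °C band;
* **(d) schooling + taxis + currents** — fish are additionally advected by
  a static surface-current field.

The scenarios are strictly nested: with the temperature weight set to zero
and a still current field, scenario (d) reduces numerically to (b) (there
is a regression test asserting bit-identical output).

## State, units and time structure

The ocean is a rectangle of `nx x ny` unit *sectors* (100 x 40 at full
scale); the sector side is the unit of length, so all speeds are in
sectors/day. Each fish carries a continuous position, a heading, a scalar
speed, an age in days, and a personal reproduction day-of-year. Stages are
set by age: egg/larva to 183 d, juvenile to 365 d, adult afterwards.

Each simulated day runs, in order: (1) ageing and stage transitions;
(2) natural mortality; (3) spawning; (4) five movement sub-steps of
`dt = 0.2` d; (5) fleet reallocation and fishing mortality. An annual
census on January 1st refreshes the recruitment target. Years are 365 days.

## Movement

In scenarios (b)–(d), fish `k` updates its speed to the mean speed of its
orientation set and its heading from

\[
d_k = \frac{1}{N_R + N_O + N_A}\Big(
  \sum_{r \in N_R} \frac{q_k - q_r}{\lVert q_k - q_r \rVert}
  + \sum_{o \in N_O} (\cos\phi_o, \sin\phi_o)
  + \sum_{a \in N_A} \frac{q_a - q_k}{\lVert q_a - q_k \rVert}\Big),
\]

where the repulsion, orientation and attraction sets collect neighbors at
distances in \((0, r_r]\), \((r_r, r_o]\) and \((r_o, r_a]\). The focal fish
counts itself in its orientation set, which keeps the speed average defined
for isolated fish and lets them persist on their heading. The travel
direction blends the social direction with the temperature response,
\(D_k = \alpha\, \hat d_k + \beta\, \hat g_k\) with \(\alpha + \beta = 1\)
(defaults 0.995 / 0.005), where \(\hat g_k\) is the normalized gradient of
the thermal discomfort function

\[
r(T) = \begin{cases}
 -(T - T_1)^2 & T < T_1 \\
 0 & T_1 \le T \le T_2 \\
 -(T - T_2)^2 & T > T_2,
\end{cases}
\]

evaluated by central finite differences on the sector grid. The position
advances by \(\Delta t\, v_k \hat D_k\) plus, in scenario (d), the current
displacement \(\Delta t\, C(q_k)\). Two conventions deserve notice:

* **Current scaling.** The current term is scaled by \(\Delta t\) so that
  a field in sectors/day advects a fish one day's worth per day regardless
  of the sub-step size (an un-scaled term would apply a full day of
  advection five times a day).
* **Zero-norm directions.** Where \(\lVert d_k \rVert\) or
  \(\lVert D_k \rVert\) falls below \(10^{-12}\) the fish keeps its
  previous heading; a coincident repulsion pair contributes a random unit
  vector (the normalization is undefined at zero distance).

At the calibrated radii \(r_r = 0.02, r_o = r_a = 0.10\) the attraction
annulus \((r_o, r_a]\) is empty, so cohesion is inactive by default; the
radius is configurable and the annulus is implemented faithfully.

Scenario (a) replaces all of this by Gaussian displacements with per-axis
variance \(2 D \Delta t\) (so the planar mean-squared displacement is
\(4 D t\); the default `D = 0.0069` gives an RMS annual displacement of
about 3 sectors). Borders repel in every scenario: positions reflect off
the domain walls and the normal heading component flips; in addition the
border band of the temperature field is set far above any interior value so
that, when taxis is active, the gradient response always points inward
there.

Eggs and larvae do not school. They receive a natal speed drawn
U(0, 0.1) on a random fixed heading that decays linearly to zero over the
egg/larva stage, spreading a cohort a few sectors from its spawning point
before recruitment (plus current transport in scenario (d)). We initially
tried a one-week decay; it leaves sibling cohorts essentially co-located,
and they then mature into dense, nearly stationary knots — an artifact
that both distorts the fishery (knots hide inside any closure) and
dominates the neighbor-search cost. The stage-long decay is the package's
default; the length is configurable. Juveniles school, with speed capped
by a linear ramp from their natal speed at 183 d to a personal adult
cruise speed drawn U(0.42, 0.50) at maturity.

## Population dynamics

Natural mortality is a daily Bernoulli per fish: `7e-4`/d for post-larval
fish under five years, `3e-3`/d for older fish. Reproduction is an annual
population event: each adult carries a reproduction day drawn from
round(N(250, 20)) and, on that day, releases 10 eggs at its own position,
then redraws its day for the next cycle. A fish spawns only once it is at
least one year old.

Egg survival is where the Gordon–Schaefer (logistic surplus production)
model enters. The January census of adults \(N_t\) sets a recruitment
target \(Rec = r N_t (1 - N_t/K)\) (defaults \(r = 1.2\),
\(K = 30{,}000\)); each day, every egg survives with probability
\(\min(1, Rec / N_{eggs})\), recomputed from the standing egg count. A
fresh cohort is therefore thinned toward the target within days and then
passes through (the survival probability clamps to 1), so the number of
fish recruiting to the adult stage each year tracks the logistic
production of the stock. One could instead read the ratio as a one-shot
thinning at recruitment; the daily-recompute-and-clamp scheme was chosen
because it is self-stabilizing under partial spawning seasons and egg
mortality of any timing (the package's tests verify that the unfished
stock equilibrates at or below `K`). Note that background
mortality of juveniles and adults acts on top of the logistic recruitment,
so the unfished equilibrium sits noticeably below `K` (about 70% of it at
the default rates) — the carrying capacity bounds recruitment, it is not
itself the equilibrium.

## The fleet

Fishing effort follows adult density. Each day the relative effort in an
open sector with adult count \(N\) is \(\exp[-c(1 - N/M)]\), with \(M\) the
maximum adult count over open sectors and \(c = 3\) by default; closed
sectors get zero; 5,000 boats (full scale) are then allocated
proportionally (fractional boats are kept — only the product of boats and
catchability matters). The per-fish daily capture probability in a sector
with \(B\) boats is \(1 - \exp(-F_{365} \cdot B \cdot q)\), where
\(F_{365}\) is the daily share of the target annual fishing mortality
\(F = 1.27\,\mathrm{y}^{-1}\) and `q` is a catchability scalar.

`q` is calibrated by `calibrate_catchability()`: fixed-point iteration
until a no-MPA run realizes a mean annual fishing mortality equal to the
target. "Mean" is abundance-weighted — the average daily hazard per
fish-day over all fished days, annualized — which is the natural reading
of an "average over space and time" and is smooth in `q`. The unweighted
mean over years is bimodal: once the stock is nearly gone, the gravity
allocation piles the whole fleet onto the few surviving hotspots, and the
per-capita hazard on the survivors explodes. That overshoot is the
intended overfishing regime (the target F exceeds the intrinsic rate of
increase precisely so that the unmanaged stock collapses), not something
the calibration should chase. Calibration is per movement scenario, since
the density field the fleet responds to differs between scenarios.

## The synthetic environment

The environmental forcing this model is designed for is a satellite
August monthly-mean SST snapshot and annual-mean geostrophic currents over
an eastern-boundary upwelling region (the Peru–Chile anchovy habitat);
fetching remote-sensing products is out of scope for this package, so
`synth_environment()` generates fields with the same structural
properties:

* interior SST spanning values below, inside and above the preference
  band, with smooth, seeded perturbations;
* a gradient oriented **zonally** (cross-shore), as over an
  eastern-boundary upwelling system: cold inshore, warm offshore. This
  matters for the study design: the thermal comfort band is then a
  meridional corridor that *crosses* the east–west MPA strip. (A
  meridional gradient would put the entire comfort band on the domain's
  mid-latitude — exactly where the MPA strip sits — and taxis would
  trivially herd every school into the closure, a degeneracy the real
  fields do not have.)
* a one-sector border frame at the interior maximum plus 100 °C, so the
  taxis response points inward at the walls;
* in `gyre` mode, a single-gyre current field from a sinusoidal
  streamfunction (peak 0.1 sector/day, roughly a fifth of adult cruise
  speed, in the range of geostrophic speeds off Peru relative to anchovy
  swimming), with both eastward and westward zonal flow.

Fields are static throughout a run, shared across replicates, and
read/written through a self-describing JSON container (or per-layer CSV).

## Schedule, MPA geometry and experiments

Full scale runs 70 years: 20 unfished burn-in years, fishing everywhere
from year 21, and from year 31 an east–west no-take strip centered on the
mid-latitude covering a configurable fraction of the area (whole rows plus
a centered partial row, so the closed-sector count is exact). The MPA-size
sweep (`mpa_sweep()`) runs scenarios x fractions x replicates, summarizes
density (juveniles + adults) and annual landings over an equilibrium
window (the last 10 years of the run; trajectories have equilibrated well
before that at the default schedule), and `optimal_fraction()` picks the yield
argmax, breaking ties toward the smaller closure. `recovery_metrics()`
reports years until density first reaches 95% of its post-MPA plateau
(mean of the final five years; censored if never reached).
`sensitivity_scan()` varies boat aggregation `c` (1–5), fecundity (5–15)
or F (1.10–1.50) one at a time at a fixed 30% closure under scenario (d).

Because the closure has no effect before its start year, runs that differ
only in MPA fraction share a bit-identical prefix; sweeps compute that
prefix once per replicate and resume each run from a checkpoint (a test
asserts that resumed and uninterrupted runs match exactly). Replicate
seeds are fixed offsets from a base seed, so any run can be reproduced in
isolation.

## Desk scale

The tests and the acceptance experiments use `scaled_config()`: 2,500
fish, K = 3,000, 500 boats, a 50 x 20 grid, 35 years with fishing from
year 10 and the MPA from year 15, and an equilibrium window of 10 years —
a factor-10 reduction in population and fleet on a quarter-area grid.
All rates, radii, speeds and the thermal band are unchanged.

Two distortions of this reduction are worth knowing about when comparing
desk-scale output to full-scale values:

* **Strip-width physics for diffusion.** Diffusive retention depends on
  the *absolute* strip width relative to the annual diffusion length
  (about 3 sectors at the default D) — a first-passage property, not an
  area share. Halving the row count halves the strip width at any given
  fraction, so the diffusion scenario needs roughly twice the closed
  *fraction* to retain a stock at desk scale: its optimum migrates from
  ~10% (full scale) toward ~30–40%, and small closures that are viable at
  full scale go extinct. The schooling scenarios are far less affected
  (their exposure is set by school transit times across the closure, which
  scale more nearly with the area share).
* **Per-sector density.** 2,500 fish on 1,000 sectors is 2.5 per sector
  versus 6.25 at full scale, which thins schools and lowers absolute
  yields relative to a naive 1/10 of the full-scale table.

The synthetic environment also differs from the satellite fields in ways
that bound what desk-scale agreement can show: real SST has mesoscale
filaments and a land mask, and real currents are not a single smooth gyre.
Passing tests demonstrate the mechanics and the qualitative ordering of
scenarios, not quantitative prediction for any real stock.

## Numerical choices

* Field sampling is nearest-sector (floor of the continuous coordinates,
  half-open intervals, upper boundary clamped into the last sector) —
  fields are per-sector values, so no interpolation is implied.
* Gradient normalization tolerance `1e-12`; below it the taxis response is
  the zero vector (comfort plateaus have no preferred direction).
* Neighbor search uses a cell list with cell side equal to the attraction
  radius, packed per sub-step into cell-ordered arrays; a property test
  checks it against a brute-force all-pairs oracle on clustered
  configurations.
* All randomness flows through R's RNG (also inside the compiled core),
  so a run is a pure function of configuration and seed.
* Boats are fractional; conservation of the fleet total is checked daily
  and surfaced as a run diagnostic.

## Known limitations

* No growth, length/weight structure, age-dependent fecundity, economics,
  temporal environmental variability, or vertical movement.
* The likelihood-of-capture scaling of the original fleet model is not
  published; the single calibrated scalar `q` reproduces only the stated
  constraint (mean annual F), not that scaling's possible density
  dependence.
* Desk-scale results inherit the strip-width distortion described above;
  full-scale runs (the default `sim_config()`) reproduce the intended
  geometry but take hours, not minutes.
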