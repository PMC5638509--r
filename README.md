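# mpaschool

Individual-based simulation of a schooling pelagic fish stock and a
density-following fishing fleet, built to answer a management question:
**how large must a no-take marine protected area (MPA) be to rebuild an
overfished stock and maximize long-run fisheries yield — and how much does
the answer depend on what you assume about fish movement?**

The model is an anchovy-like small pelagic (short iteroparous life cycle,
annual spawning peak in early September, heavy industrial exploitation).
Four nested movement scenarios are compared:

| scenario | movement |
|---|---|
| a | isotropic diffusion (random walk, `MSD = 4Dt`, D = 0.0069 sector²/d) |
| b | zonal schooling: repulsion / orientation / attraction neighborhoods |
| c | schooling + taxis toward a 16–18 °C thermal preference band |
| d | schooling + taxis + passive transport by surface currents |

## The model in brief

Fish `k` carries position `q_k`, speed `v_k`, heading `φ_k`, and age.
Schooling follows a Vicsek-type interaction with metric zones
(radii `r_r = 0.02`, `r_o = r_a = 0.10` sectors):

    v_k(t+Δt) = mean of v_j over the orientation set (self included)
    d_k ∝ Σ_repulsion -(q_j−q_k)/‖·‖ + Σ_orientation (cos φ_j, sin φ_j)
          + Σ_attraction (q_j−q_k)/‖·‖
    D_k = α d̂_k + β ∇r(T(q_k))/‖∇r‖,   α + β = 1
    q_k(t+Δt) = q_k(t) + Δt v_k D̂_k + Δt C(q_k)

with thermal discomfort `r(T) = 0` inside `[T1, T2]` and `−(T−T1)²` /
`−(T−T2)²` below/above. Demography: daily natural mortality by age class,
10 eggs per adult per annual spawning event, and density-dependent egg
survival `S = min(1, Rec/N_eggs)` anchored to a Gordon–Schaefer model
`Rec = r N (1 − N/K)` (so recruitment tracks logistic surplus production,
with MSY = K·r/4). The fleet reallocates 5,000 boats daily in proportion
to `exp[−c(1 − N_ij/M)]` over open sectors and converts local boat density
into a per-fish capture probability, with a catchability scalar calibrated
so that a no-MPA run realizes a mean annual fishing mortality of
F = 1.27 y⁻¹. The daily event loop and neighbor search run in compiled
code (Rcpp); every operation also has a plain-R reference implementation
that the tests check against brute-force oracles.

See the vignette (`vignettes/mpa-design-and-fish-movement.Rmd`) for the
full account: assumptions, parameter table, numerical conventions, the
synthetic SST/current generator, and known limitations.

## Worked example

A desk-scale run (2,500 fish, 50×20 grid, 35 years; fishing from year 10,
a 30% closure from year 15) under the full scenario:

```r
library(mpaschool)

cal <- calibrate_catchability(scaled_config("d"), seed = 1)
cfg <- scaled_config("d", mpa_fraction = 0.30)
cfg$fleet$q_scale <- cal$q_scale   # 0.7868: realized F = 1.253, target 1.27

run <- run_simulation(cfg, seed = 1)
run
#> <mpa_run> scenario d, MPA 30%, 35 years, seed 1
#>   final density 1248 (juv+adult), last-year landings 402

tail(run$annual[c("year", "adults", "density", "landings")], 3)
#>    year adults density landings
#> 33   33   1128    1168      396
#> 34   34   1168    1211      393
#> 35   35   1211    1248      402
```

Reading the output: the unfished stock equilibrates near 2,100 fish
(about 70% of the scaled K = 3,000 — background mortality acts on top of
logistic recruitment); five years of fleet-wide F = 1.27 crash it to a few
percent of that before the closure takes effect; by the final decade the
30% closure has rebuilt the stock to over half its unfished level while
the fleet lands ~400 fish a year from spillover — about 45% of the scaled
MSY of 900.

`mpa_sweep()` repeats this across closure fractions, scenarios and
replicates and `optimal_fraction()` extracts the yield-maximizing closure;
`inst/cli/simulate.R` and `inst/cli/sweep.R` are shell wrappers over the
same functions.

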