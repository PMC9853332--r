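# riverspom

Metapopulation dynamics on expanding and contracting stream networks.

Most rivers are partly *temporary*: whole reaches of the channel network
stop flowing during recessions and rewet after rain. For aquatic species
that disperse along the channel, the habitat is therefore a graph whose
nodes blink on and off and whose connectivity pulses with discharge.
riverspom is a simulation toolkit for ecohydrologists and freshwater
ecologists who want to quantify what that pulsing does to species
persistence. It couples:

1. **A stochastic streamflow generator.** Daily effective rainfall is a
   marked Poisson process (frequency λ, exponential depths of mean α)
   feeding a linear reservoir with recession rate k, so specific discharge
   Q(t) has the stationary Gamma(λ/k, αk) law — mean αλ, CV² = k/λ.
2. **Hierarchical network activation.** Each reach i of a dendritic
   network carries a threshold Q\*ᵢ and flows iff Q(t) ≥ Q\*ᵢ. Thresholds
   are set from a persistency ranking (spatially random, TWI-based, or
   contributing-area-based) via uniform quantiles of a reference flow
   distribution, so reaches always activate from the most to the least
   persistent. Connectivity is tracked by the largest connected portion
   (LCP) of the active network and its duration curve.
3. **A dynamic stochastic patch occupancy model (SPOM).** Occupancy
   wᵢ(t) ∈ {0,1} is a synchronous daily Markov chain with
   Φ_C = 1 − exp(−CᵢΔt), Φ_E = 1 − exp(−EᵢΔt), where

   C_i(t) = c Σ_{j≠i} exp(−d_ij(t)/δ) S_j(t) w_j(t−Δt),  E_i(t) = e / S_i(t),

   suitability Sᵢ = Δlᵢ·Wᵢ·Xᵢ(t) is the wetted stream-bed area, and the
   along-channel distance d_ij(t) is finite only when the whole path
   between i and j is flowing. Dry reaches lose their populations
   (Φ_E = 1) and cannot be colonised.

Scenario drivers run 50-replicate Monte-Carlo ensembles over three climate
presets (dry / intermediate / wet) crossed with the three persistency
configurations, always alongside a *static-equivalent* benchmark network
whose constant flowing length equals the mean active length of the dynamic
runs, plus survival sensitivity maps over (c, e) trait grids and an exact
2^N Markov-chain oracle for validating the stochastic engine on small
networks.

## Worked example

```r
library(riverspom)

net <- generate_network(300, cell_size = 100, seed = 1)
net
#> <stream_network> 300 nodes, outlet 9, total length 30000 m, NND 100 m

climate_preset("wet")
#> <climate_params> wet: alpha=10 mm, lambda_p=0.55 /d, E_p=2 mm/d,
#>   lambda=0.37 /d, k=0.35 /d, P_t=5.5 mm/d, E_a=1.8 mm/d

res <- run_scenario(scenario_config("wet", "area", net,
                                    n_mc = 10, base_seed = 1))
glance(res)
#> # A tibble: 1 × 14
#>   climate scenario  n_mc survival_dynamic survival_static cv_dynamic cv_static
#> 1 wet     area        10                1               1      0.393    0.0237
#>   cv_n_dynamic mean_omega_dynamic mean_omega_static mean_persistency
#> 1           10              0.546             0.552            0.627
#>   mean_active_m mean_lcp_m target_length_m
#> 1        18323.     18323.          18323.
```

Reading the row: under the wet climate with area-ranked persistency all 10
dynamic and static replicates survive the year (`survival_* = 1`); the
pulsing network keeps mean occupancy slightly below the static benchmark
(0.546 vs 0.552 of total channel length) while amplifying its temporal
variability more than tenfold (CV 0.393 vs 0.024); the network-mean
persistency under this climate is 0.627, the mean active length 18.3 of
30 km, and — area ranking keeps the active network fully connected — the
mean LCP equals the mean active length. `tidy(res)` returns the
replicate-by-day Ω(t) series, `autoplot(res)` draws the ensemble,
`local_occupancy`/`plot_node_map` map where on the network the species
persists, and `sensitivity_analysis()` sweeps colonization/extinction
grids for survival maps.

A command-line front end over the same functions is installed at
`inst/cli/riverspom.R` (subcommands `generate-network`,
`simulate-hydrology`, `run-scenario`, `sensitivity`).

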