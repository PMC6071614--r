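# fishcensus

An agent-based simulator for studying **bias and precision of underwater
visual census (UVC)** — the diver-based fish counts used on temperate and
coral reefs for monitoring, conservation and fisheries decisions.  Field
surveys can never compare their estimates against the true density; in the
simulator the true density is set by construction, so the error of a survey
design can be measured directly.

Who it is for: marine ecologists choosing between survey designs (transect
dimensions and swim speed, point-count radius, duration and rotation), and
methodologists studying how fish behaviour — schooling, crypsis, diver
avoidance or attraction — interacts with non-instantaneous sampling.

## The model in brief

Fish are agents on a 20 × 80 m toroidal arena (visibility 6 m, default true
density Dt = 0.3 fish/m², hence 480 fish).  Movement follows a
steering-vector scheme on 0.1 s ticks: each behavioural state weighs eight
"urges" (schoolmate alignment / cohesion / spacing, wander, rest, cruise,
patch gathering, diver avoidance); the weighted sum is clipped at the
type's maximum acceleration, quadratic friction drag decelerates, and speed
is capped at the sustained speed — or the burst speed while reacting to the
diver.  Every 10 s each fish re-picks a state by frequency-weighted
sampling with replacement and redraws a hidden flag from the state's
detectability.  Four packaged trait archetypes (`schooling`, `cryptic`,
`shy`, `bold`) reproduce the published parameter tables.

A diver runs either protocol and counts once per second: closest visible
fish first, at most 3 per second, remembering counted fish so they are not
recounted while they stay in sight.  Density is estimated as

    De = count / area        (area = length x width, or pi x radius^2)

and survey performance per parameter combination is summarised as

    bias:      delta = 100 * |mean(De) - Dt| / Dt        (% of Dt)
    precision: CV    = 100 * sd(De) / Dt                 (% of Dt)

over replicate surveys with reshuffled fish.

## Worked example

```r
library(fishcensus)

shy <- builtin_fish_types("shy")
tr  <- survey_config("transect", length_m = 30, width_m = 4, speed_m_min = 6)
run_survey(world_config(), shy, tr, seed = 42)
#> <fc_survey_result> shy | transect | count 186 | area 120.0 m^2 | De 1.5500 (Dt 0.3000)
```

One 30 × 4 m transect swum at 6 m/min through shy (diver-avoiding,
0.4 m/s) fish counts 186 fish where an instantaneous census of the strip
would expect `0.3 × 120 = 36`: mobile fish keep entering the strip ahead
of the diver during the 5-minute swim, so the density estimate
(1.55 fish/m²) overshoots the true 0.3 fish/m² five-fold — a bias of
+417%, dwarfing the detectability effects UVC discussions usually focus
on.

A small sweep over point-count designs, 3 replicates per cell:

```r
sw <- run_sweep("point", "cryptic",
                grid = expand.grid(radius_m = c(2, 4), time_min = c(3, 7, 11),
                                   rotation_deg_s = c(2, 10)),
                replicates = 3, base_seed = 1)
summarise_trait(sw)
#>     trait protocol mean_bias_pct min_bias_pct max_bias_pct mean_cv_pct
#> 1 cryptic    point      369.3597     114.4171     549.8827    105.4679
#>   min_cv_pct max_cv_pct n_cells
#> 1   34.02999   180.5576      12
marginal_bias(sw, "time_min")
#>   level     mean
#> 1     3 211.1258
#> 2     7 374.1491
#> 3    11 522.8042
```

`bias_pct` is the absolute deviation of the mean estimate from truth as a
percentage of truth (114–550% across these cells); `cv_pct` the replicate
coefficient of variation.  The marginal means show the characteristic
time effect: the longer a stationary diver counts, the more entering fish
are added, and bias grows monotonically.  `heatmap_export(sw, "out/")`
writes the per-trait-scaled heatmap panels and the same matrices as CSV;
`regression_summary(sw)` adds a descriptive linear model of bias on the
design parameters.

## Fish type files

Types load from a two-block CSV (`read_fish_type()`, `write_fish_type()`;
the four packaged files live in `inst/extdata/fish_types/`).  Block 1 has
columns `attribute,value` with rows `name`, `size_m`, `id_distance_m`,
`approach_distance_m`, `perception_distance_m`, `perception_angle_deg`,
`max_acceleration_m_s2`, `max_sustained_speed_m_s`, `burst_speed_m_s`.
After a blank line, block 2 has one column per behavioural state (header
`attribute,<state names...>`) and rows `frequency`, `detectability`,
`schooling`, `schooling_distance_bl`, `patch_distance_m`, `align`,
`centre`, `spacing`, `wander`, `rest`, `cruise`, `patch_gathering`,
`diver_avoidance`.  Empty cells mean "not used" (urge weights default to
zero).

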