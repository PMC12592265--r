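# antnav

Quantitative analysis of vertically ascending ant trajectories digitised
as frame-by-frame head and thorax coordinates, and of how those
trajectories change when a novel odour is placed across the foraging
route.

Nocturnal bull ants forage by climbing the trunk of their nest tree
along a well-maintained corridor. Point-tracking software turns each
videotaped ascent (25 frames/s) into two coordinate streams per ant —
the tip of the head and the centre of the thorax, in arena-frame
millimetres with the y axis pointing up the trunk. `antnav` takes those
streams and computes everything between raw coordinates and the final
statistical report:

- **Kinematics** — step lengths and headings (thorax displacement
  between consecutive frames), turning angles wrapped to (−180°, 180°],
  stop-excluded speed (steps below `v_stop = 0.01` mm/s are excluded
  from both the distance and the time entering the mean), body-axis
  orientation (thorax → head) and its angular velocity.
- **Path straightness** — sinuosity
  `S = 2 [ p ( (1+c)/(1−c) + b² ) ]^(−1/2)` where `p` is the mean step
  length, `c` the mean cosine of turning angles and `b` the step-length
  CV; and the maximum expected displacement `E^a_max = β/(1−β)` with
  `β = c`, a dimensionless asymptotic straightness in units of steps.
- **Scanning bouts** — maximal stationary intervals in which the ant
  rotates on the spot (thorax within `r_max` of the interval centroid,
  cumulative |Δorientation| ≥ `θ_min`, duration ≥ `min_dur`), with
  per-trip counts and durations.
- **Route outcomes** — each ascent is classified against a horizontal
  odour band as *walked over*, *detour* (around the band's lateral
  edge), *U-turn* (back down the trunk) or *incomplete*, and outcome
  frequencies get exact binomial intervals.
- **Inference** — Welch t-tests (fractional Satterthwaite df) for
  control-vs-test comparisons, one-way repeated-measures ANOVA for the
  repeated-exposure design, and the three a priori Helmert contrasts:
  control vs all test days, test day 1 vs days 2–3, day 2 vs day 3.
- **Synthetic foragers** — a correlated-random-walk generator (gamma
  step lengths, wrapped-normal turning angles with known mean cosine)
  that climbs through a configurable arena, executes a scripted band
  response, and implants stop and scanning episodes with exact
  ground-truth timing, so every analysis stage is testable without any
  field recording.

## Worked example

```r
library(antnav)

arena <- arena_geometry()                      # 700 x 1000 mm, 500 x 50 mm band
sim <- simulate_experiment(odour_effect_profiles(), n_per_cell = 15,
                           seed = 11, arena = arena)
tab <- summarise_trajectories(sim$trajectories, arena = arena)
ctl <- tab[tab$condition == "control", ]
tst <- tab[tab$condition == "test", ]

batch_compare(ctl, tst, c("S", "mean_speed", "n_scans"))[, 1:6]
#>       metric          t       df            p     mean_x     mean_y
#> 1          S -89.841211 17.92136 3.041679e-25  0.1916943  0.6240258
#> 2 mean_speed 129.507737 25.24331 3.670293e-37 37.5160001 24.9957523
#> 3    n_scans  -4.920512 16.71273 1.358209e-04  1.2666667  4.6666667
```

Control ants walk nearly straight (mean sinuosity 0.19 mm^−1/2 at
37.5 mm/s with about one scanning bout per trip); odour-exposed ants
meander (0.62), slow to 25 mm/s and scan ~4.7 times. The Welch t row
for each metric gives the statistic, fractional df, p-value and the two
group means; a negative t means the test group is larger.

Route classification on the same test-condition ants:

```r
outcomes <- sapply(sim$trajectories[sim$manifest$condition == "test"],
                   function(tr) classify_route(tr, arena)$category)
outcome_frequencies(outcomes)
#>      category n proportion      ci_lo     ci_hi
#> 1 walked_over 4  0.2666667 0.07787155 0.5510032
#> 2      detour 9  0.6000000 0.32286977 0.8366357
#> 3      u_turn 2  0.1333333 0.01657591 0.4046027
```

A command-line entry point mirrors the library (`inst/cli/antnav.R`):

```sh
Rscript inst/cli/antnav.R metrics --config analysis.yaml
```

with stages `simulate`, `metrics`, `events`, `classify` and `compare`.

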