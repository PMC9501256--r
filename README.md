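# magtrap

Magnetophoretic capture simulation and fluorescent-object counting for
microcapsule flow experiments.

Micron-sized polyelectrolyte capsules loaded with magnetite
nanoparticles (via repeated freezing/thawing of their porous vaterite
templates) can be pulled out of a flowing suspension by a permanent
magnet with a field concentrator — the working principle behind
magnetically targeted drug delivery and the magnetic separation of
labelled cells from flow.  Whether a given capsule is trapped is a
competition between two forces on a sphere of radius $R$ and volume
$V$:

* Stokes drag $\vec F_D = -6\pi\eta R\,\vec v_{rel}$, and
* the magnetic force
  $\vec F_M = \rho V(\vec M_0\cdot\nabla)\vec B +
  \frac{V\chi_{cap}}{\mu_0}(\vec B\cdot\nabla)\vec B$

acting on the capsule moment
$\vec m=\rho V\vec M_0+\frac{V\chi_{cap}}{\mu_0}\vec B$.  A capsule is
captured when its trajectory under
$m\,\mathrm{d}\vec v/\mathrm{d}t = \vec F_D + \vec F_M$ ends on the
channel wall with (near-)zero velocity.  `magtrap` implements this
model — parameter conversion from printed capsule descriptors, an
analytic concentrator-tip field calibrated to 0.3 T at the channel
edge, trajectory integration with a capture criterion, and
capture-efficiency sweeps over capsule size (1, 2.7, 5.5 um), payload
(1–3 loading cycles: 1.6/4.6/6.4% magnetite by mass) and flow velocity
(5–100 mm/s), including the minimal number of internalised capsules
needed to trap a 13 um cell.

It also implements the video-analysis side of such experiments: a
fluorescent-object counting algorithm (Sobel edge enhancement,
border-following contour extraction with Green's-formula areas, frame
differencing for movers, bright-spot area division for aggregates, and
centroid tracking for superimposed traces), validated against a
synthetic flow-video generator that produces exact per-frame ground
truth for the four regimes seen in real recordings: separated movers,
growing magnet-zone aggregates, weakly fluorescent objects, and
overlapping traces.

## Worked example: trapping physics

```r
library(magtrap)

spec <- capsule_spec(2.7, 0.4, n_freeze_cycles = 3)
spec
#> <capsule_spec> PAH/PSS, d = 2.7 +/- 0.4 um, payload 6.4% (chi_cap 0.0337)
#>   rho 1052 kg/m3, V 1.03e-17 m3, mass 1.08e-14 kg

env <- fluid_env(5e-3)          # 5 mm/s mean flow, 250 um channel
mag <- magnet_model()           # 0.3 T at the wall, pole at x = 1 mm

integrate_trajectory(spec, env, mag, start = list(position = c(0, 20e-6)))
#> <capture_result> captured at x = 1000.9 um after 0.482 s
```

A capsule entering 20 um above the magnet-side wall is dragged onto
the wall and stops just downstream of the pole.  Sweeping a population
(random diameters, random inlet heights, one seed):

```r
capture_efficiency_sweep(cycles = c(1, 3), velocities_mm_s = c(5, 20),
                         n_per_cell = 20, seed = 1)
#>  diameter_class_um cycles velocity_mm_s  n captured fraction
#>                1.0      1             5 20        2     0.10
#>                2.7      1             5 20        3     0.15
#>                5.5      1             5 20        4     0.20
#>                ...
#>                5.5      3             5 20        8     0.40
#>                5.5      3            20 20        4     0.20
```

Capture fractions fall with velocity and rise with payload and (in
this default geometry) with size.  A 13 um cell needs several
internalised capsules before it can be held at 5 mm/s:

```r
cell <- cell_spec(0, spec)
min_capsules_for_capture(cell, env, mag, 5)
#> [1] 16
```

## Worked example: counting objects in a video

```r
vid <- render_video(scene_config(seed = 1))   # mixed four-case clip
vid
#> <video_stream> 120 x 300 px, 200 frames, 50 true objects

rep <- count_video(vid, scene_count_config(vid$config))
rep
#> <count_report> 200 frames, avg single area 114.0 px, 12 accumulated

evaluate_accuracy(rep, vid$truth)
#> recovered 4518 of 4782 true object records (94.5%), overcount 1.4%
```

The `12 accumulated` is the algorithm's estimate of objects piled up
at the magnet zone in the final frame; this clip's ground truth has
exactly 12.  `run_sweep()`, `run_count()`, `run_benchmark()` and
`run_closure()` orchestrate full runs with YAML configs, CSV/JSON
artifacts and manifests (see `inst/extdata/example_run.yaml`;
`inst/cli/magtrap.R` wraps them for shell use).

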