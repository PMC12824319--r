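# campwave

Quantification of intracellular cAMP and Ca²⁺ signal wave propagation in
giant (multinucleated) *Dictyostelium discoideum* cells.

In normal-sized amoebae, cytosolic cAMP equilibrates faster than a typical
5-s imaging interval, so intracellular signal propagation is invisible. In
giant cells produced by partial cytokinesis inhibition, a front of rising
cAMP (inverted-response sensor) or Ca²⁺ (direct sensor) takes tens of
seconds to traverse the cell and can be measured. campwave turns such
time-lapse recordings — a sensor TIFF stack plus binary cell masks — into:

- normalized signal traces (inverted normalization
  `I_b = (I − max I)/min(I − max I)` for cAMP-type sensors, min–max for
  Ca²⁺-type; ratiometric correction for paired channels);
- logistic kinetic parameters per region or grid tile, from the model
  `L(t) = 1/(1 + exp(−a(t − b)))` with slope `a` (1/s) and half-time `b`
  (s);
- 7 × 7 kinetic maps of |a| and b over a 45 × 35 μm analysis box
  (tiles 6.429 × 5.000 μm), with per-tile validity;
- the finite-difference gradient of the half-time map (forward/backward at
  edges, central inside), its summary slope `ḡy/ḡx`, and the angle between
  migration direction and wave direction;
- a one-dimensional propagation velocity `v = d/|b_front − b_rear|` and a
  tagged apparent diffusion estimate `D = v²/|a|`;
- kymographs, centroid trajectories, front/rear region construction
  (x-parameterized ±20 μm offsets along the fitted migration axis).

It also implements a discrete-time stochastic growth/division (sizer) model
— synchronous doubling, then probabilistic division above a size threshold
with asymmetric partitioning, conserving `Total = N0·S0·2^T` — and a
synthetic movie generator with exact ground truth that stands in for
microscopy data in all tests.

## Worked example

```r
library(campwave)

mv  <- generate_wave_movie(movie_spec(seed = 1))   # known truth: v = 2.98 um/s
res <- run_pipeline(mv$stack, mv$mask)
res
#> <wave_analysis>
#>   migration slope 0.419 (direction +1), R2 1.000
#>   front rise: a 0.144 1/s, b 21.39 s | rear rise: a 0.1429 1/s, b 36.17 s
#>   gradient slope 0.434, migration/wave-source angle 0.7 deg
#>   v = 2.94 um/s (front_rear), D = 57.3 um^2/s (v2_over_a)
```

Reading the output: the centroid path fits a line of slope 0.419 (truth:
0.42) and the cell travels toward +x; the cAMP rise reaches half-maximum
14.8 s earlier at the front region than at the rear, and the two regions
are 43.4 μm apart, giving v = 2.94 μm/s against the generator's true
2.98 μm/s; the migration direction differs by 0.7° from the direction the
activation wave arrived from (the wave entered at the front, as
constructed). `write_results(res, "out/")` serializes the trajectory,
traces, fits, maps, gradient, and estimates as stamped CSV/JSON files.

A thin command-line wrapper for simulation and end-to-end runs is installed
at `inst/cli/campwave.R` (subcommands `simulate-movie`, `simulate-sizes`,
`run`).

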