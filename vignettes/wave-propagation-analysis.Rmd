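---
title: "Quantifying intracellular signal wave propagation in giant amoeboid cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular signal wave propagation in giant amoeboid cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campwave)
```

## The problem

In chemotacting *Dictyostelium discoideum*, cAMP acts both as the
extracellular relay signal and as an intracellular second messenger. In a
normal-sized cell (~8 μm across) cytosolic cAMP equilibrates faster than a
typical 5-s acquisition interval, so intracellular propagation is invisible.
Giant multinucleated cells — tens of micrometres across, produced by partial
cytokinesis inhibition — slow the *relative* traversal time enough that a
front of rising cAMP (reported by an inverted-response sensor such as
Flamindo2) or Ca²⁺ (reported by GCaMP6s) can be followed across the cell.

campwave packages the quantitative pipeline for such recordings: it turns a
sensor stack plus a cell-mask stack into normalized signal traces, logistic
kinetic parameters, grid-based activation-time maps, a propagation direction,
and a one-dimensional wave velocity. A stochastic growth/division model and a
fully synthetic movie generator with known ground truth round out the
package so that every stage is testable without microscopy data.

## Signal model

All kinetics are described by the two-parameter logistic

$$ L(t) = \frac{1}{1 + e^{-a (t - b)}} $$

with slope $a$ (1/s; negative for decay phases, heatmaps report $|a|$) and
half-time $b$ (s). Raw intensities are first converted to relative signal
levels:

* **Inverted normalization** (sensors whose fluorescence *falls* as the
  signal rises): $I_a = I - \max(I)$, $I_b = I_a / \min(I_a)$, so the
  dimmest frame maps to signal level 1.
* **Min–max normalization** (direct sensors): $I_a = I - \min(I)$,
  $I_b = I_a / \max(I_a)$.

Both are exact onto $[0, 1]$ and invariant under affine rescaling of the
camera values. The normalization window is always the trace the caller
passes — restrict with `trace_window()` to normalize per phase; there is no
hidden global state. For ratiometric pairs, `compute_ratio()` divides the
signal-insensitive reference channel by the sensor channel pixel-by-pixel
(the default, because shading cancellation is a per-pixel property), and the
rising ratio is then treated with min–max normalization.

## From movie to velocity

```{r}
mv <- generate_wave_movie(movie_spec(seed = 1))
res <- run_pipeline(mv$stack, mv$mask)
res
```

The pipeline stages, each available as a standalone function:

1. **Migration axis** — per-frame mask centroids (`compute_centroid`),
   least squares of y on x (`fit_trajectory`); the travel direction is the
   sign of the net x displacement, and near-vertical paths (|slope| > 5)
   are rejected rather than mis-parameterized.
2. **Front/rear regions** — `define_front_rear` places 11-μm circles at
   x-parameterized offsets $\pm(\Delta x, \mathrm{slope}\cdot\Delta x)$
   from the mean centroid (default 20 μm). x-parameterization (rather than
   arc length) is deliberate: it reproduces the conventional
   $(\pm 20, \pm \mathrm{slope} \cdot 20)$ construction exactly.
3. **Kinetics** — region traces (mask-intersected circle means; empty
   frames are flagged invalid, never zeroed), normalization, phase
   segmentation (`segment_phases`: 3-frame moving average, alternating
   extrema, 0.5 amplitude threshold — all configurable), and bounded
   Levenberg–Marquardt logistic fits (`fit_sigmoid`), initialized from the
   empirical 10–90% crossing times with $|a| \le 10$ 1/s and $b$ confined
   to the window. Logistic fits are initialization-sensitive; these
   defaults are declared choices, not inferred ones.
4. **Kinetic maps** — the analysis box (default 45 × 35 μm, centered on the
   mean centroid) is split into a 7 × 7 grid of half-open tiles
   (Δx = 6.429 μm, Δy = 5.000 μm), each roughly one normal cell footprint;
   per-tile traces are normalized per tile (a shared window is available)
   and fitted, storing $|a|$ and $b$. Tiles fail validation when coverage
   < 0.5, the fit does not converge, $b$ leaves the window, or residual per
   point exceeds 0.02 — poor fits are excluded, not imputed.
5. **Gradient** — the half-time map $T(i,j)$ is differentiated with the
   edge-aware stencil (forward at the first row/column, backward at the
   last, central elsewhere). On affine maps every stencil case is exact,
   which is what the test suite checks against a brute-force oracle. Tiles
   adjacent to invalid tiles fall back to the one-sided difference toward
   their valid neighbour — a real value where one exists, never an invented
   one. The summary direction is the mean gradient
   $(\bar g_x, \bar g_y)$ and the gradient slope $\bar g_y / \bar g_x$.
6. **Velocity and diffusion** — the default velocity estimator is
   front–rear distance over half-time difference,
   $v = d / |b_F - b_R|$, flagged unreliable when $|b_F - b_R|$ is below
   one frame interval; `velocity_from_gradient()` offers
   $v = 1/|(\bar g_x, \bar g_y)|$ as the alternative, and outputs always
   name their method. The apparent diffusion coefficient defaults to
   $D = v^2 / |a|$ (front width $v/|a|$ times speed); this formula is an
   explicit modelling choice, always reported with its method tag, because
   no unique derivation exists for an "apparent" D of a logistic front.

### Sign conventions

Coordinates are image-convention micrometres: origin at the top-left pixel
corner, x along columns, y increasing downward; grid row indices increase
downward to match. The half-time gradient $+\nabla T$ points from early to
late activation — *along* the wave's travel. `compare_direction()` therefore
reports, by default (`orient = "source"`), the angle between the migration
vector and $-\nabla T$, the direction the activation wave *arrived from*:
0° means the cell migrates toward the side where the signal entered, which
is the front–rear alignment question this analysis exists to answer.
`orient = "propagation"` compares against $+\nabla T$ instead (the two
differ by exactly 180°).

## The synthetic generator

`generate_wave_movie()` renders a migrating elliptical cell whose interior
intensity follows a traveling *planar* sigmoidal wavefront: the half-time at
position $x$ is affine, $b(x) = t_0 + (x - c_0)\cdot\hat w / v$. The
intensity model is logistic-in-time by construction — not a
reaction–diffusion solver — because the analysis pipeline assumes sigmoid
kinetics and parameter recovery should be well-posed: a recovered $v$ can
then be compared against a true $v$ without model mismatch. A pulse is a
logistic rise joined (by a pointwise minimum) to a mirrored logistic decay,
so within each phase the trace *equals* the analytic logistic.

Defaults, chosen once to mirror typical giant-cell acquisitions: 0.65 μm/px,
5-s frames, 30 frames, semi-axes 34 × 25 μm, migration at 0.03 μm/s along
the direction (1, 0.42), wave speed 2.98 μm/s, wave slope 0.139 1/s, pulse
at 30 s with a 60-s rise-to-decay spacing, baseline 100 and amplitude
60 a.u., inverted response, and additive Gaussian noise of 2 a.u. per pixel
per frame. The noise level of real recordings is not documented anywhere we
could calibrate against; 2 a.u. on a 60 a.u. swing (~3%) is a deliberately
ordinary choice for spinning-disk confocal data and is a free parameter.
Relay periodicity (~7 min) enters through `generate_relay_trace()` and
`pulse_times`. The frame is auto-sized so the ellipse plus its whole
migration path fits with a 3-μm margin; an explicit `frame_dim` that is too
small raises an error naming the first offending frame.

What the generator does *not* emulate: photobleaching, blinking, Poisson-
dominated shot noise (available as an option, not the default), 3-D optics,
wavefront curvature, and cell-shape change. Passing tests therefore
demonstrate correctness of the *analysis* under its stated model, not
robustness to every property of real microscopy data.

`generate_ratiometric_pair()` adds a reference channel sharing the identical
mask and multiplicative shading field but carrying no signal response, so
shading cancellation in the ratio is exactly testable.
`generate_biphasic_calcium()` produces per-tile two-pulse traces whose
onsets are delayed with tile distance from each phase's origin, emulating a
biphasic Ca²⁺ response entering from two different sites.

## The growth/division model

`run_model()` iterates, from `n0` cells of size `s0`, a growth phase (every
cell doubles — synchronous exponential growth) and a division phase: each
cell strictly exceeding `s_min` divides with probability `p_div`, splitting
as $s_1 = p s$, $s_2 = (1-p) s$ with $p \sim U(p_{\min}, p_{\max})$ drawn
per division. "Exceeding" is strict by definition of the model. Per step the
order is grow-then-divide, and daughters cannot re-divide within the step.
Whatever the parameters, total size is conserved exactly:
$\sum s = N_0 S_0 2^T$ — the package's conservation tests exercise this
over random configurations. One seeded RNG stream, consumed in population
order, makes runs exactly reproducible.

```{r}
ps <- run_model(size_model_params(n0 = 100, s0 = 50, steps = 8,
                                  p_div = 0.9, s_min = 50, seed = 1))
fin <- ps$states[[length(ps$states)]]$sizes
size_stats(fin)$median
```

The default parameter set (`n0 = 100`, `s0 = 50` μm², `T = 8`,
`p_div = 0.9`, `s_min = 50` μm², `p ∈ [0.4, 0.6]`) is a placeholder for
exploring the model's behaviour; it is not calibrated to any measured size
distribution, and lowering `p_div` shifts mass toward giant cells exactly
as the sizer-with-chance picture predicts.

## Numerical and design notes

* **Problem sizes.** The bundled tests and the acceptance script analyse
  movies of roughly 90 × 120 px × 30 frames and fit 49-tile maps; a full
  pipeline run takes well under a second, so the whole suite stays fast
  while still exercising every stage end to end.
* **Half-open tiles** avoid double-counting pixels on tile boundaries; the
  partition is exact for any box.
* **Degenerate inputs** fail loudly and early: constant traces (the
  normalizations would divide by zero), empty masks, regions outside the
  mask in every frame, zero net displacement (no definable front), axes
  steeper than slope 5, non-positive ratio denominators (reported with a
  pixel count).
* **Storage.** Stacks travel as 16-bit grayscale TIFF with the intensity
  scale in a JSON sidecar — arbitrary-unit intensities survive the round
  trip exactly on the stored grid; masks are 0/255 8-bit TIFF and anything
  else is rejected.
* **Determinism.** Every generator takes a seed, uses one local RNG stream,
  and restores the ambient RNG state; identical spec + seed is
  bit-identical output, and `run_pipeline` results serialize to
  byte-identical CSV/JSON under a fixed seed.
* **Known limitations.** The planar-wavefront assumption makes the
  half-time field affine, so curvature of real wavefronts is out of scope;
  the apparent-D formula is one defensible choice among several; period
  estimation needs at least two full cycles and flags anything less as
  unreliable.
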