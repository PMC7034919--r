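---
title: "Opponent visual memories and oscillatory homing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent visual memories and oscillatory homing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewhoming)
```

## The model in brief

`viewhoming` simulates an insect-like agent that homes using visual
familiarity alone. Its memory is two banks of low-resolution panoramic
snapshots taken around the nest and along a homing route: an
*attractive* bank memorised while facing the nest, and a *repulsive*
bank memorised while facing directly away from it. At every step the
agent renders the view in its current heading, scores it against both
banks, and subtracts the repulsive from the attractive familiarity.
This *opponent familiarity* drives steering directly: the agent's turn
direction alternates left/right every step (an oscillator it cannot
override), and only the turn *amplitude* is modulated,

\[
\text{turn} = \mathrm{clip}(\text{baseline} - \text{gain} \times D,\ 0°, 180°),
\qquad
\theta_{t+1} = \theta_t + \text{turn}\cdot(-1)^t + \text{noise},
\]

followed by one fixed-length step forward. No scanning, no mental
rotation, no path integration: one view per step, compared only at its
facing alignment.

The scientific point the package makes operational: the familiarity of
a single view against goal-facing memories alone does not tell the
agent whether to turn (it mostly reflects how far it is from the
memorised locations), whereas the opponent signal is normalised by
construction — whichever bank matches better wins — and tracks the
angular error of the current heading. The mapping module measures
exactly this, and the agent module shows the behavioural consequence:
robust homing over a wide swathe of (gain, baseline) space, including
infinite gain, versus fragile, finely-tuned homing for the
attractive-only variant.

## Views and familiarity

A view is a single-channel luminance grid over azimuth × elevation.
The default geometry is 72 columns at 5°/pixel — a typical ant eye —
and 12 rows covering 0–60° of elevation at 5°/pixel. Only the
above-horizon panorama is rendered; real below-horizon content is
dominated by ground texture that the model deliberately omits, and the
vertical span is configurable (`view_params()`). Sky is fixed at
luminance 1.0 and all terrestrial content is darker, mimicking the
strong sky/ground contrast in the blue/UV channel that navigating
insects rely on.

Mismatch between two views is the global root-mean-square pixel
difference at the facing alignment; neither view is rotated. Bank
familiarity is `1 - clip(min-mismatch / K, 0, 1)`. The normalisation
constant `K` defaults to 1, the theoretical maximum RMS for luminances
in [0, 1] (a full-contrast complement). This choice is
world-independent and deterministic; an empirical alternative — the
maximum mismatch over the calibration sample, a per-world scaling — is
available via `calibrate_average_world_familiarity(...,
normalization = "empirical")`. Typical view pairs in the default world
sit well below the theoretical bound, so familiarity values cluster
high (0.5–1.0); only differences matter to the opponent drive, so the
absolute level is immaterial in opponent mode.

The attractive-only drive needs an origin: it is centred on the
*average world familiarity*, estimated by rendering 32 views at
uniform-random positions and headings and averaging familiarity over
all C(32, 2) = 496 unordered pairs. "Average over all pairs" is an
interpretation (the estimate could also be defined over random
disjoint pairs); it uses every sample and is deterministic given the
seed, which is why it was chosen.

## The synthetic worlds

The original study rendered views inside LiDAR reconstructions of real
ant habitats. Those meshes are external data; `viewhoming` replaces
them with procedural stand-ins that preserve the *statistics* that
matter for view-based homing, not the photorealism. A world is a flat
plane with opaque vertical cylinders plus a periodic distant-skyline
profile (elevation and luminance per azimuth, standing at infinity).
Rendering is a column-wise occlusion painter: per azimuth column the
nearest subtending object — else the skyline — sets an occluding edge;
bins below it take the occluder's luminance, bins above are sky. This
makes rotation on the spot *exactly* a circular column shift, which
both the tests and the mapping module exploit.

Two archetypes are provided:

* `open_distant` (default arena: ±32 m): a smooth random harmonic
  skyline plus 25 large trees (radius 1.5–3.5 m, height 10–25 m)
  placed on an annulus between 40% and 95% of the bounds. Keeping all
  trees at middle distances from the central foraging area is
  deliberate: views then decorrelate smoothly and without saturating
  over tens of metres of displacement, so view difference carries
  usable gradient information everywhere in the mapped region. A stand
  of small near-nest objects would instead decorrelate within a metre
  or two and leave the rest of the map flat.
* `cluttered_local` (default arena: ±10 m): flat zero-elevation
  skyline — no distal panorama at all — and 150 small objects (radius
  5–25 cm) everywhere. Views change rapidly with small displacements;
  the agent must walk with shorter steps to stay within the familiar
  catchment, which is exactly what the `cluttered_world` robustness
  condition does.

What the generator does **not** emulate: ground texture and
below-horizon content, object shapes other than cylinders, lighting,
occlusion of a far tall tree's crown above a nearer short object
(per column the nearest occluder wins outright), and the slow
luminance gradients of real skies. Passing tests therefore show that
the opponent principle works given smooth, two-scale panoramic
structure; they do not certify performance in any specific real
habitat.

## Memory banks

The learning walk is modelled as an Archimedean spiral around the
nest: 25 views, radius growing linearly to 2 m over 2 revolutions,
each view facing the nest exactly (attractive) or exactly away
(repulsive). Spiral turn count and starting radius are modelling
choices (real learning walks are loops of increasing span; two turns
give even areal coverage) and are configurable. The homing route is a
straight 10 m line from the nest with nest-ward-facing views every
0.5 m — 20 views, a spacing chosen to emulate dense route memorisation;
it too is configurable. Outbound (outward-facing) route views can be
appended to the repulsive bank with a flag but are off by default: the
baseline protocol does not require them.

Robustness manipulations mirror the learning-walk variations studied
behaviourally: uniform orientation noise up to ±90° on memorised
facings, decoupling the repulsive spiral from the attractive one
(independent random phase), halving the number of views to 10,
coarsening the eye to 10°/pixel, shrinking the walk to a 10 cm radius
(with the agent stepping 4× shorter and 4× as often), swapping in the
cluttered world, and releasing around a fictive nest in unvisited
terrain.

## The walker

Defaults: baseline 90°, gain 3000, step 0.2 m, Gaussian heading noise
(sd 10°), 320 steps (a 64 m path budget). The gain converts
familiarity units into degrees; because opponent-familiarity
differences in the default world are of order 10⁻²–10⁻¹, useful gains
are in the hundreds to thousands, and the sweep grid is log-spaced
(`0, 100, 300, 1000, 3000, ∞`). The default gain sits mid-range (on a
log scale) of the region in which the sweep shows opponent homing to
operate; the acceptance sweep recomputes that region rather than
assuming it. Infinite gain is a first-class value: turns are pinned to
0° (positive drive) or 180° (negative drive), with the baseline at
drive exactly zero for continuity with finite gain. Under infinite
gain the agent moves in straight lines and U-turns; uniform ±20°
heading noise is then the only source of new directions, and is
sufficient for homing.

Further conventions, stated once and used everywhere: positions in
metres, x east / y north; headings in degrees counter-clockwise from
+x; view column 0 is the heading direction and columns advance
clockwise in the visual field; eye height is 2 cm and enters only
through object angular heights. Noise is added to the heading *after*
the clipped oscillator turn and never flips the oscillator, whose
initial side is randomised per run (alternation makes it
asymptotically irrelevant). An agent that would leave the arena is
truncated in place with status `"out_of_world"`; its arrival distance
is measured at the truncation point, which keeps arrival statistics
honest rather than silently reflecting walkers off walls.

## Mapping and statistics

`sample_familiarity_map()` scores every lattice position × heading
against both banks. The full protocol is a 30 × 30 m square every
0.5 m (3600 positions) × 72 headings; because all headings on the
default grid are multiples of the azimuthal resolution, the map costs
one 360° render per position. Directional specificity is max − median
familiarity across headings, clipped into [0, 0.5] for reporting
(clipping, not rescaling — the raw value is kept alongside). Ties in
the best heading go to the lowest heading. The fixed "north" heading
used in the single-heading analyses is +y = 90°; any fixed heading off
the route axis behaves similarly.

The summary statistic relating map values to angular error and to
nest distance is the Spearman rank correlation: familiarity saturates
nonlinearly, and rank correlation is invariant to that. Degenerate
inputs (constant maps) are reported as correlation 0 with an explicit
`degenerate` flag rather than `NA`, so downstream comparisons never
silently propagate missingness.

## Sweeps, success, and protocol sizes

A sweep cell releases M = 10 agents at points spaced exactly 360/M =
36° around the nest (random ring phase, seeded), each with a random
initial heading, 320 steps. The cell score is the *median* arrival
distance — the median answers "did the majority home?", where a mean
would be dominated by the few lost agents. Homing success uses a
closed boundary, arrival ≤ 1 m (the boundary itself is measure-zero;
the choice is documented rather than consequential). Run-level seeds
derive deterministically from the sweep seed, so sweep matrices are
reproducible bit-for-bit and resumable per cell; a failed cell is
recorded, never fatal to the sweep.

The robustness protocol (`run_condition()`) is 3 nest placements × 100
releases at 5 m, each run given a 30 m *travel budget*. Fixing
travelled distance rather than step count is a deliberate reading of
the slow-walk conditions: with 4× shorter steps the agent takes 4× as
many, covering the same ground. The fictive nest of the
`unfamiliar_release` condition is drawn at least 12 m from the true
nest and the route, where both banks are equally uninformative and
the opponent drive hovers near zero.

Test problem sizes: the test suite exercises the mapping statistics on
a 20 × 20 × 36 map (30 m extent at 1.5 m spacing, 10° headings) and
the sweep comparison on the full 6 × 6 grid with M = 10 and 320 steps;
unit tests use miniature worlds and banks built in code. These sizes
were chosen so the whole suite completes in minutes while keeping every
protocol structurally identical to its full-scale counterpart — only
lattice spacing and replication shrink, never the algorithm.

## Numerical choices

* Mismatch between view sets is computed via the
  \(|a-b|^2 = |a|^2 + |b|^2 - 2ab\) expansion for speed; cancellation
  can leave O(10⁻¹³) residue in the squared distance of identical
  views, so squared distances below 10⁻¹⁰ (RMS ≈ 10⁻⁷ luminance
  units, far below any real view difference) snap to exact zero.
  Self-matches therefore score familiarity exactly 1.
* Object angular half-width uses `asin(r/d)` (exact for a cylinder);
  an agent standing inside an object's footprint sees it fill the
  panorama. Elevation bins fill when their centre lies below the
  occluding edge.
* The skyline profile is interpolated linearly and periodically in
  azimuth; worlds regenerate bit-identically from their seed, and all
  randomised operations take explicit seeds and restore the caller's
  RNG state.
* `turn_amplitude` handles ±∞ gain by the sign rule before any
  arithmetic that could produce `NaN` (`∞ × 0`).

## Known limitations

* The renderer's "nearest occluder wins" rule can hide a tall distant
  tree behind a short near object within a column; with the default
  two-scale worlds this situation is rare but it is a geometric
  simplification.
* Memory banks are constructed, not learned: no plasticity, no
  forgetting, no mushroom-body circuitry. The opponent integration is
  a literal subtraction standing in for antagonistic output-neuron
  valences.
* Familiarity landscapes and homing results depend on the procedural
  world's statistics. The generator's defaults were chosen once to
  give smoothly decorrelating, orientation-informative panoramas —
  the regime the opponent mechanism needs and that natural open
  habitats with distant trees provide — and the package makes no
  claim about habitats far outside that regime beyond the
  `cluttered_local` condition it explicitly tests.
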