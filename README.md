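# viewhoming

Opponent-process visual homing in an oscillatory insect agent.

## The problem

Solitary foraging ants home by visual familiarity: they memorise
low-resolution panoramic views while facing the nest (during learning
walks) and along habitual routes, and later move in directions that look
familiar. The classic difficulty is that the familiarity of a *single*
view says nothing about whether the animal should turn: a view can match
a stored snapshot well even when the animal faces the wrong way, so
familiarity-only models must stop and scan many directions at every
step.

`viewhoming` simulates an alternative: the agent keeps **two**
valence-tagged memory banks — *attractive* views memorised facing the
nest, and *repulsive* views memorised facing 180° away from it — and
integrates the two familiarity readouts by subtraction. The resulting
**opponent familiarity** is positive when the current view matches
goal-facing memories better than anti-goal-facing ones, and it tracks
the angular error of the current heading rather than the distance from
the goal. A single glance per step is then enough to steer.

## The model

For a current view `V` and a bank `M = {m1, …, mk}` of memorised views,
the familiarity is

    f(V, M) = 1 − clip( min_i RMS(V, m_i) / K , 0, 1 )

where `RMS` is the root-mean-square pixel difference at the facing
alignment (views are never rotated) and `K` normalises mismatch into
[0, 1]. The per-step drive is either

    opponent:        D = f(V, M_att) − f(V, M_rep)
    attractive-only: D = f(V, M_att) − f̄

with `f̄` the average familiarity between two random views in the world.
The walker turns every step, alternating left and right, with amplitude

    turn = clip( baseline − gain × D , 0°, 180° )
    θ(t+1) = θ(t) + turn × (−1)^t + noise

and then steps 20 cm forward. Familiar views inhibit turning; repulsive
or unfamiliar views amplify it.

Worlds are procedural: a distant skyline profile plus opaque vertical
cylinders ("trees" or clutter), rendered as 72 × 12 px single-channel
panoramas (5°/pixel, above-horizon only).

## A worked example

```r
library(viewhoming)

world <- generate_world(1, "open_distant")     # 25 eucalypts, 64 m arena
banks <- build_memory_banks(world,             # 25 spiral + 20 route views
                            learning_walk_spec(), route_spec())
path  <- run_agent(world, banks, familiarity_context(),
                   agent_params(max_steps = 320, seed = 4),
                   release = c(4, 0))
path
#> <homing_path> 320 steps, completed
#>   release ( 4, 0 ) -> arrival 1.018 m from nest
```

The agent released 4 m from the nest ends its 64 m run about 1 m from
it: the opponent drive steered it back and held it searching around the
goal. With the repulsive bank removed
(`memory_mode = "attractive_only"` plus a calibrated context), the same
protocol typically strands agents metres away — the core contrast the
package exists to demonstrate. `sample_familiarity_map()` +
`angular_error_stats()` quantify why: on this world the opponent value
of a north-facing view correlates with the angular error of that heading
(|Spearman rho| ≈ 0.4) and barely with nest distance, while the
attractive-only value does the reverse.

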