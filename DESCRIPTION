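Package: viewhoming
Title: Opponent-Process Visual Homing in an Oscillatory Insect Agent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of view-based homing in navigating
    insects. A procedural virtual-world module renders low-resolution
    panoramic luminance views; attractive (goal-facing) and repulsive
    (anti-goal-facing) memory banks are built from simulated learning
    walks and homing routes; per-step visual familiarity is the
    complement of the lowest normalised root-mean-square pixel
    difference against a bank, and the two valences are integrated by
    subtraction into an opponent drive that modulates the turn
    amplitude of a left/right alternating oscillatory walker. Includes
    exhaustive familiarity-landscape mapping, gain-by-baseline
    parameter sweeps, and the robustness manipulations used to probe
    the opponent-memory strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
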