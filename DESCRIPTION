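Package: transportscope
Title: Trajectory Analysis of Alternating-Access Transporter Gating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Metrics for detecting the outward-to-inward conformational
    transition of LeuT-fold secondary transporters in molecular dynamics
    trajectories: gate-distance traces with hysteresis event detection,
    Shrake-Rupley solvent-accessible surface area of residue sets,
    cavity and shell water bookkeeping, ion coordination, hydration and
    release detection, side-chain chi1 tracking, helix-axis tilt and
    hinge angles, HOLE-style pore radius profiles, and one-site
    Michaelis-Menten uptake kinetics.  Includes a synthetic
    toy-transporter generator with frame-exact ground truth so every
    analysis stage is testable without external simulation data, and a
    pipeline driver that runs the full analysis battery from one
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
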