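# transportscope

Trajectory analysis for alternating-access gating of LeuT-fold secondary
transporters (serotonin/neurotransmitter:sodium symporter family), for
people who run molecular dynamics on these proteins and need the standard
measurement battery as tested, scriptable R functions rather than ad-hoc
VMD scripts.

A transporter of this fold carries a "scaffold" (TM3–5, TM8–10) and a
mobile four-helix bundle (TM1, TM2, TM6, TM7). The transition from the
outward-facing to the inward-facing state shows up in a trajectory as a
chain of signatures, each of which this package measures per frame:

* **gate distances** — shortest heavy-atom distance between the charged
  groups of the extracellular (Arg–Glu) and intracellular (Arg–Asp) gates,
  with hysteresis-based break/reform event detection;
* **solvent exposure** — Shrake–Rupley SASA of configured residue sets
  (aromatic lid, cytoplasmic pathway), water counts near selections, and
  extracellular/intracellular cavity occupancy with the cavity defined by
  z bounds plus distance to a reference residue and to a set of TMs;
* **ion transport** — Na2-site coordination distances, first-shell
  hydration, χ1 of the coordinating aspartate, release detection (no
  protein contact + full hydration, persistent over a dwell), and a
  scaffold-aligned release pathway trace;
* **helix geometry** — helix/bundle axis fits, scaffold/bundle tilt
  angles, TM1a/TM1b and TM6a/TM6b hinge angles, and classification of a
  frame's bundle orientation against labelled reference structures;
* **pore radius** — a HOLE-style largest-inscribed-sphere profile along
  the membrane normal, with a deterministic grid+descent optimizer;
* **uptake kinetics** — one-site hyperbola
  v = V<sub>max</sub>·[S]/(K<sub>M</sub>+[S]) by nonlinear least squares
  with asymptotic SEs, t-based 95% CIs, saturation flagging and
  wild-type/mutant fold-change comparison;
* **a synthetic toy-transporter generator** with frame-exact ground truth
  (programmed hinge schedule, scripted ion release and gate rupture,
  opening-tracking cavity waters), so the whole measurement chain is
  testable without deposited trajectories;
* **a pipeline driver** that runs the battery from one YAML config and
  exports the most inward-facing snapshot (the pathway-SASA argmax frame).

File I/O (PDB single/multi-model, DCD) goes through `bio3d`; the
measurement algorithms are implemented here.

## Worked example

Generate a 100-frame toy transition (hinge ramps 0°→25° over frames
20–60, intracellular gate ruptures at frame 40, Na2-like ion released at
frame 70) and run the full battery:

```r
library(transportscope)

g   <- generate_toy_trajectory(toy_transporter_spec(seed = 1), dir = "toy")
out <- run_all(run_config(g$paths$pdb, g$paths$config, "toy_out",
                          site = g$site))

out$snapshot_frame                       # 60  (pathway-SASA argmax)
out$results$gates$IC_gate$events         # break at frame 40
out$results$ions$release_frame           # 70
cav <- out$results$solvation$cavity_waters
c(cav$IC[1], cav$IC[100])                # 0 20  (IC cavity hydrates)
out$results$pore$comparison$region_means
#       label  ec_mean  ic_mean
#     frame_1 2.628585 2.767465
#   frame_100 2.628585 2.901277
```

The exported snapshot is the first frame of the open plateau, the gate
event and release frame match the scripted schedule exactly, the
intracellular cavity gains ~20 waters, and the intracellular mean pore
radius grows while the extracellular side is unchanged — the signature
chain of an inward-facing state.

Kinetics, on simulated uptake data (true K_M = 5.9 mM):

```r
wt <- generate_uptake_data(5.9, 100, c(0.5, 1, 2, 5, 10, 20, 60, 150),
                           noise_cv = 0.03, n_replicates = 3, seed = 31)
fit_michaelis_menten(wt, conc_units = "mM")
# One-site hyperbola fit
#   KM   = 5.99 mM (SE 0.179, 95% CI [5.618 ; 6.362])
#   Vmax = 100.2 au (SE 0.792, 95% CI [98.54 ; 101.8])
```

A thin CLI over the same functions lives at
`inst/cli/transportscope.R` (`synth`, `run-all`, `kinetics` subcommands).

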