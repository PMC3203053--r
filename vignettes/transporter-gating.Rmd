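---
title: "Measuring alternating-access gating in transporter trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring alternating-access gating in transporter trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

`transportscope` quantifies the signatures by which an outward-to-inward
conformational transition of a LeuT-fold secondary transporter shows up in a
molecular dynamics trajectory. The package does not run or touch the
dynamics itself; it consumes a topology (PDB), frames (multi-model PDB or
DCD, assumed whole-molecule, no periodic imaging) and a selection
configuration, and emits per-frame metric series.

Two geometric conventions underlie everything:

* coordinates are in Angstrom, and the membrane normal is +z with the
  extracellular side up. Inputs are assumed pre-oriented; the synthetic
  generator writes them oriented.
* residue numbering is taken verbatim from the input file; no renumbering.
* frame indices are 1-based, as is idiomatic in R. All "scripted frame"
  bookkeeping in the synthetic generator and all event frames reported by
  the detectors share this convention.

The measured quantities are the field's standard battery for
alternating-access gating:

* **Stability** — C-alpha RMSD after Kabsch superposition, and per-residue
  RMSF about the mean structure after per-frame alignment.
* **Gates** — the shortest heavy-atom distance between two charged groups
  (carboxylate oxygens vs guanidinium nitrogens), with break/reform event
  detection.
* **Solvation** — Shrake-Rupley SASA of residue sets, water counts near
  selections, occupancy of extracellular/intracellular cavities, and the
  split of the substrate's hydration shell at the substrate's z plane.
* **Ion transport** — coordination distances, first-shell hydration, chi1
  of a coordinating side chain, release detection and a scaffold-aligned
  pathway trace.
* **Helix geometry** — axis fits, scaffold/bundle and hinge tilt angles,
  and classification of the bundle orientation against labelled reference
  structures.
* **Pore** — a HOLE-style largest-inscribed-sphere radius profile along
  the membrane normal.
* **Uptake kinetics** — a one-site binding hyperbola
  $v = V_\mathrm{max}\,[S]/(K_M + [S])$ fitted by nonlinear least squares.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| frame spacing | 0.1 | ns | 1000 snapshots per 100 ns trajectory, the conventional analysis stride |
| SASA probe radius | 1.4 | A | water probe |
| SASA sphere points | 960 | — | golden-spiral placement; <2% error on an isolated sphere, <1% drift vs 3840 points |
| gate formed / broken cutoffs | 4 / 6 | A | salt-bridge "formed" vs "lost" heavy-atom distances; hysteresis prevents chatter |
| event dwell | 5 | frames | a state must persist half a nanosecond to count |
| cavity cutoff | 10 | A | distance from the reference residue and from each listed TM |
| EC cavity z bounds | (2, 15) | A | measured from the substrate centre of mass (strict inequalities) |
| ion contact cutoff | 4 | A | "no protein interaction" for release |
| min hydration at release | 4 | waters | a freed monovalent cation carries 4-5 first-shell waters |
| release dwell | 10 | frames | release must be persistent, not a fluctuation |
| pore z step / grid step / search radius | 0.5 / 0.5 / 10 | A | profile resolution vs cost |

All are configurable per call or through the YAML selection config.

## Numerical choices

**Superposition.** Kabsch via SVD with the standard reflection guard: if
the optimal orthogonal matrix has determinant -1, the axis of smallest
singular value is flipped so a proper rotation is always returned. Inputs
with fewer than 3 points or collinear point sets are rejected as degenerate
rather than silently fitted. The RMSD reference frame defaults to the first
frame (configurable); the RMSF mean structure is computed in a single pass
after alignment, without iterative refinement — the difference is far below
the tolerances used anywhere in the package.

**Helix axes.** A plain principal-component fit of C-alpha positions is
biased for helices spanning a non-integer number of turns (several degrees
for an 11-residue half-helix). The package therefore first collapses the
C-alpha spiral onto the axis with a sliding 4-point weighted centroid whose
weights $(1, a, b, 0.75)$ solve $\sum_k w_k e^{ik\cdot100^\circ} = 0$ —
exact cancellation for the canonical 100 degrees-per-residue twist — and
takes the principal axis of the smoothed points. The filter is linear, so
axis fitting stays rigid-motion equivariant; for real helices that deviate
from the canonical twist the residual bias is small and smooth. Group axes
pool the smoothed C-alphas of all member helices (not the mean of per-helix
axes, which over-weights short members); orientation is fixed against the
polarity-weighted sum of member N-to-C vectors so antiparallel helices vote
consistently. Tilt angles are unsigned, in [0, 180] degrees, with the dot
product clamped before `acos`.

**SASA.** Shrake-Rupley with deterministic golden-spiral test points, so
results are exactly reproducible at fixed point count. Occlusion is
computed against protein and substrate heavy atoms only: the package uses
SASA increases to mean *solvent exposure*, and letting explicit waters
occlude would invert that signal. Coincident atoms of equal radius are
well-defined (points blocked symmetrically).

**Cavity occupancy.** A water belongs to a cavity when its oxygen satisfies
the z bounds (strict inequalities, relative to the substrate
centre-of-mass z — the one place the coordinate origin is defined, and so
reused for both the cavity bounds and the shell split), lies within the
cutoff of the reference residue, and within the cutoff of *every* listed TM.
The conjunctive reading is the default because it is the most literal one;
`tm_logic = "any"` switches to the union reading. Waters are represented by
their oxygen; a water exactly on the substrate plane counts as
extracellular.

**Pore profile.** The objective is HOLE's — the largest sphere centred in
each slice that overlaps no van der Waals sphere — but the optimizer is a
deterministic coarse grid plus a shrinking-grid descent refined to
grid_step/16, replacing Monte Carlo annealing so profiles are bit-for-bit
reproducible. Slices with no atom within search_radius + 20 A are reported
capped at the search radius and flagged `unbounded`, not as errors. Only
protein and substrate heavy atoms block the pore. Van der Waals radii come
from a bundled per-element table (Bondi-style; unknown elements get 1.70 A),
since pore radii are only meaningful against a fixed, documented radius set.

**Gate events.** A two-threshold hysteresis state machine: broken only
after the distance exceeds the broken cutoff for a full dwell, re-formed
only after it drops below the formed cutoff for a full dwell. Events are
reported at the first frame of the qualifying run and necessarily
alternate. Gates are assumed formed at the start, so the first reportable
event is a break.

**Kinetics.** The hyperbola is fitted by Levenberg-Marquardt started from
$V_{\max,0} = \max v$ and $K_{M,0}$ = the concentration nearest half-max,
followed by a Gauss-Newton polish with the analytic Jacobian so the
optimum is converged to machine precision; rates are internally scaled to
unit magnitude, which makes the fit exactly scale-equivariant. Standard
errors are asymptotic (from the Jacobian at the optimum) and 95% limits use
the t distribution with $n-2$ degrees of freedom. When the fitted $K_M$
exceeds the largest tested concentration the fit is flagged unsaturated:
the data bound $K_M$ only from below, and `compare_fits()` then reports the
fold change as a ">=" bound — mirroring the convention of quoting "at
least n-fold" when one arm never saturates. The construction of a
conservative point estimate under saturation is deliberately left to the
caller. Replicates are pooled by default; per-replicate fits feed the
unpaired t-test in `compare_fits()`.

## What the synthetic generator emulates — and what it does not

`generate_toy_trajectory()` builds a 10-helix toy transporter: a static
6-helix scaffold and a 4-helix bundle on an 8 A ring, 22 residues per
helix, with the intracellular halves of TM1 and TM6 hinging outward
following a programmed angle schedule (default: 0 to 25 degrees ramped
over frames 20-60 of 100, i.e. over ~4 ns of a 10 ns trajectory — a
deliberately compressed version of a transition that takes tens of
nanoseconds in real simulations). Around it:

* cavity waters drawn per frame from Poisson distributions — intracellular
  occupancy proportional to the current opening angle (0.6 waters per
  degree, giving ~15 at the open plateau), extracellular occupancy at a
  constant low rate of 3;
* a substrate pseudo-residue whose centre of mass defines z = 0;
* a bound ion with two coordination partners that unbinds at a scripted
  frame and leaves along -z in fixed steps, carrying a 6-water first
  shell;
* two salt-bridge gates built from real residue/atom names (GLU OE1/OE2 vs
  ARG NH1/NH2, ASP OD1/OD2 vs ARG NH1/NH2) so selection strings exercise
  the same code paths as real files; the intracellular gate steps from
  3 A to 8 A at a scripted frame.

Every scripted quantity is recorded frame-exactly as ground truth, which is
what makes the package testable without deposited trajectories: each
analysis module must recover the generator's schedule within its stated
tolerance.

The toy is geometry and bookkeeping only. It has no force field, no
thermal noise on protein atoms, no solvent dynamics, no membrane, and its
water counts are independent across frames. Passing the recovery tests
therefore demonstrates that the *measurement* chain is correct — not that
the measurements are robust to every pathology of real simulation data
(force-field artifacts, imaging errors, protonation changes). Tests that
need noise add it explicitly on top of the clean traces.

Problem sizes throughout the tests and the acceptance script are the
generator defaults: 100 frames, ~1200 atoms, an 80-water pool, 960 SASA
sphere points, 100-seed kinetics simulations. These run the full battery in
about a minute on one core while leaving every tolerance comfortably
non-trivial.

## Design decisions where the field leaves a choice

* **Per-monomer analysis of oligomers** is handled by chain-scoped
  selections; the package never guesses how to split a dimer.
* **"Within 10 A of TM_n"** means within 10 A of any atom of any residue of
  that TM range — the most literal reading.
* **TM1a/TM1b (TM6a/TM6b) split residues** are configuration entries; the
  boundaries of centrally unwound helices are structure-specific and not
  inferred.
* **The scaffold axis** for bundle-state classification is the pooled
  principal axis described above; published comparisons of this kind render
  the scaffold as a surface without defining its axis, so the convention is
  declared rather than inherited.
* **Snapshot export** ranks frames by cytoplasmic-pathway SASA and breaks
  ties toward the earliest frame, making the "most inward-facing snapshot"
  reproducible.
* The intracellular gate site is configured under one name with aspartate
  atom names (OD1/OD2); glutamate naming for the same site in some
  descriptions maps to the same selection mechanism (OE1/OE2) and is a
  config edit, not a code change.

## Known limitations

* The pore axis is a straight line along the membrane normal; curved
  channel paths are out of scope.
* No hydrogen-bond angle criteria: gate traces are heavy-atom distances.
* No mass-weighting in RMSD/RMSF (C-alpha metrics only) and no iterative
  mean-structure refinement in RMSF.
* DCD support covers the common CHARMM/NAMD single-precision layout
  without unit-cell records or fixed atoms.
* The helix-axis smoothing assumes the canonical twist; strongly distorted
  or pi-bulged helices will see a small residual axis bias.
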