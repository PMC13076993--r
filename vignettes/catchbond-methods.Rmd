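---
title: "Two-state catch-bond analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state catch-bond analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchbond)
```

## The problem

Several receptor–ligand pairs of the immune synapse — prominently PD-1
with its ligands PD-L1 and PD-L2 — behave as *catch bonds*: under a
force clamp their mean lifetime first rises with tensile force, peaks in
the 5–10 pN range, and only then decays. The structural picture behind
this is a bond with **two bound conformations**: a compact state I that
closely resembles the crystal structure of the complex, and a
force-extended state II reached by reorientation of the two IgV domains.
Force tilts the balance toward state II; if state II dissociates more
slowly, the bond lives longer under moderate load.

`catchbond` implements the three computational stages this picture
requires: (i) geometric observables that distinguish the states in
simulation trajectories, (ii) classification of frames into states and
per-state statistics, and (iii) a two-state kinetic model of force-clamp
lifetime data of the kind produced by biomembrane force probe (BFP)
experiments. Synthetic generators with complete ground truth tie the
stages together into testable round trips.

## Geometric observables

**Inter-domain angle.** Each molecule's orientation is summarised by a
vector joining the centroids of two groups of backbone atoms; the
inter-domain angle is the angle between the two molecules' vectors,
reported in [0°, 180°]. The shipped presets (`vector_preset()`) use
residue ranges on the ectodomain β-sandwich of PD-1, PD-L1 and PD-L2
(author numbering). Conventions we fixed where the underlying definition
is silent:

* *backbone atoms* are N, CA, C, O (configurable via `atom_subset`);
* the vector points from the centroid of the first residue-range group to
  the centroid of the second, in the order the groups are listed; because
  the angle is folded into [0°, 180°], no global sign convention is
  needed;
* the angle is invariant under rigid motion of the whole complex (tested
  to 10⁻⁶ degrees).

**CT–CT extension.** The distance between the C-terminal Cα atoms of the
two chains is the standard proxy for complex extension under load. The
terminal residue of an expressed construct is a property of the construct
rather than of the fold, so by default the *last residue with a Cα* in
each chain is used, overridable per call.

**Salt bridges.** A bridge is present when the minimum distance between
the donor's charged-group side-chain nitrogens (Arg NE/NH1/NH2, Lys NZ,
His ND1/NE2) and the acceptor's carboxylate oxygens (Asp OD1/OD2, Glu
OE1/OE2) is *strictly* below the cutoff (default 3.5 Å). The strictness
matters only on a measure-zero boundary but is contractual: a pair at
exactly 3.5 Å is not bridged. We read "heavy atoms of the donor and
acceptor" as the charged-group atoms, not whole residues, which keeps the
criterion specific to the ionic interaction.

**Hydrogen-bond chains.** Relay networks (e.g. a Lys side chain
stabilising an interface indirectly through Asp and Gln) are evaluated
link by link as the minimum polar (N/O) heavy-atom distance between
consecutive residues. No community-standard geometric criterion was fixed
for this context, so the default is distance-only at 3.5 Å; an optional
donor–H–acceptor angle term exists but requires explicit hydrogens, which
simulation-derived PDB frames often lack — links that cannot be evaluated
return `NA` rather than a guess.

**Buried contact area.** Computed as
`(SASA(A) + SASA(B) − SASA(A∪B)) / 2` over the selected residues, with a
Shrake–Rupley accessible-surface routine written in the package: probe
radius 1.4 Å, 960 deterministic golden-spiral sample points per atom,
Bondi-style van der Waals radii. Two numerical choices are worth noting.
First, only the *selected* residues enter the calculation, so the number
measures the pairwise packing of the selections themselves. Second, a
sample point lying exactly on a neighbour's expanded sphere counts as
buried (with a 10⁻¹² relative tolerance); this makes two fully superposed
identical atoms bury exactly one atomic surface, the natural continuum
limit. Absolute areas from any SASA method depend on the sampling density
and radii table; cross-method comparisons should expect a few-percent
method offset, while differences and trends (state I vs state II) are
robust.

**Alternate locations.** PDB altloc records resolve to the
highest-occupancy copy; ties keep the first listed.

## State classification

Frames are classified from the angle series by dual-threshold hysteresis:
with state centres `low_center` and `high_center` (defaults 87° and 157°;
use 135° for the more compact extended state of PD-1/PD-L2), a frame
above `midpoint + hysteresis` is II, below `midpoint − hysteresis` is I,
and frames inside the dead band inherit the previous label. Leading
dead-band frames stay unassigned, as do frames masked as dissociated
(masking also breaks inheritance: the bound state after rupture is
undefined). The hysteresis half-width defaults to 10°, roughly one noise
SD of a realistic angle series, which suppresses chatter without delaying
genuine transitions by more than a frame.

The mechanism is deliberately simple. Trajectory segmentations of this
kind are usually done by inspection; a threshold rule makes the procedure
explicit and testable. We chose hysteresis thresholding over a hidden
Markov model because the two state centres are far apart relative to
frame noise (≈ 70° vs ≈ 10°), where an HMM's extra machinery buys little
and costs reproducibility across implementations; a two-component
Gaussian-mixture alternative was considered and rejected for the same
reason.

Per-state statistics follow the per-trajectory-mean convention: each
trajectory contributes one mean per state (only when the state holds at
least `min_frames = 10` frames, guarding against single-frame "states"),
and the cross-trajectory summary is mean ± SD with n equal to the number
of contributing trajectories.

## The two-state kinetic model

Force-clamp lifetime data are modelled by a continuous-time Markov chain
on the two bound states with an absorbing dissociated state. All four
transitions carry Bell rates `k(F) = k0 exp(F x / kBT)`, with `kBT`
fixed at 4.28 pN·nm (310 K, the physiological temperature of both the
experiments and simulations this emulates). The two-bound-state picture
itself comes with no published rate equations, so the model *form* is this
package's design choice: the standard two-state, two-pathway Bell-rate
Markov model, the minimal literature-convention model that generates
catch–slip behaviour. Its parameters are illustrative, not measured
constants: `example_catch_model()` was parameterised once so that its
lifetime peaks near 7 pN at about 1.2 s — the qualitative regime of human
checkpoint catch bonds — and is used as the planted truth of all
round-trip tests.

Key conveniences and caveats:

* `p0 = (1, 0)` by default: bonds form in the crystal-like compact state.
* Mean lifetime and survival are closed-form (`τ = 1ᵀ(−M)⁻¹p0`,
  `S(t) = 1ᵀe^{Mt}p0` via the 2×2 eigen-decomposition, with a limit
  formula when the eigenvalue gap falls below 10⁻¹⁰ relative). Both are
  validated against quadrature and matrix-exponential oracles.
* `simulate_lifetimes()` is exact Gillespie simulation, vectorised over
  draws; with a fixed seed its output is bit-reproducible.
* `bin_lifetimes()` uses half-open bins `[lo, hi)` and reports SEM as
  SD/√n, `NA` at n = 1; the default 2.5-pN bins on 0–30 pN match common
  force-clamp practice.
* `fit_two_state()` minimises `Σ((τ(F) − mean)/SEM)²` by
  Levenberg–Marquardt on `(log k0, x)` of all four rates, with the SEM
  floored at 5% of the bin mean so single-event bins cannot dominate.
  Eight parameters against one 1-D curve are only weakly identifiable —
  different rate combinations produce near-identical curves (e.g. a very
  fast pre-equilibrium mimics a slower one). The fitted *curve*, its peak
  force and peak lifetime are the meaningful outputs, and these are what
  the recovery tests score (peak force to 1 pN, peak lifetime to 15%, at
  10 bins × 200 lifetimes). Parameters pinned at bounds are flagged via
  `at_bounds`; a flat (force-independent) target characteristically drives
  switching rates to bounds.
* `peak_force()` certifies a catch bond only when the interior maximum
  exceeds the lifetime at *both* ends of the searched range by a relative
  margin (default 2%), so numerically flat curves are not misclassified.

**Adhesion statistics.** The adhesion-frequency layer assumes Poisson
bond formation saturating at λ expected bonds per touch and first-order
dissociation during contact, giving
`P_a = 1 − exp(−λ(1 − exp(−k_off t_c)))`. Under the same Poisson
assumption, `single_bond_fraction()` converts an observed `P_a` into
`P(n = 1 | n ≥ 1)`; at the conventional `P_a < 25%` working point this
exceeds 0.86, the quantitative basis for calling such measurements
predominantly single-bond.

## Synthetic data: what it emulates, and what it does not

The trajectory generator draws the hidden bound-state path from the
kinetic model (exact jump-chain simulation; frame-stepped when a force
ramp is active) and emits observables as the state mean plus Gaussian
frame noise. Defaults encode the study conditions this package emulates:
angle centres 87°/157°, CT–CT centres 49/77 Å, frames every 20 ps, clamp
force 100 pN (constant-force pulling used 100 or 50 pN), and ten-
trajectory ensembles in the round-trip tests. Where no value was stated
we chose once: angle noise SD 8° and CT–CT noise SD 3 Å, plausible frame-
to-frame fluctuation scales for domain-orientation observables;
`max_frames = 5000` (100 ns) keeps generated ensembles comfortably inside
test budgets. Two deliberate simplifications matter when transferring
conclusions to real trajectories:

* **Timescales are split.** The same model class is used on two clocks:
  rates are per *second* when emulating BFP lifetimes and per
  *nanosecond* when driving SMD-style trajectories
  (`example_smd_model()`). Conformational switching observable within a
  100-ns simulation is orders of magnitude faster than the second-scale
  kinetics of the real bond at low force; generated trajectories emulate
  the *phenomenology* (two states, force-dependent occupancy,
  dissociation as an absorbing event), not a single consistent physical
  timescale.
* **Noise is independent and Gaussian.** Real angle series show
  correlated fluctuations; white noise makes classification slightly
  easier than reality. Passing the 95%-accuracy test therefore
  demonstrates correctness of the classifier contract, not a performance
  guarantee on correlated data.

The constant-velocity pulling schedule is emulated only as a linear force
ramp on the hidden-state process (`force_ramp`, pN/ns, piecewise-constant
per frame with at most one transition per frame); no spring–bead dynamics
are modelled.

Toy complexes plant each interaction at exactly its target distance in
isolated 60-Å-spaced blocks, with every residue's backbone cluster offset
so the planted atom pair is always the nearest one — detection results on
toys are therefore exact, by construction, and serialising to PDB and
re-reading preserves planted distances to the format's 10⁻³ Å precision.

## Degenerate inputs and numerical edges

* All-zero switching reduces every kinetic quantity exactly to the
  single-exponential bond (tested).
* A generator with all rates zero at some force is singular; the mean
  lifetime raises an error rather than returning infinity.
* Bell exponents are capped (default 500) with a warning, guarding
  overflow for aggressive `x` at high force.
* Empty selections, unresolvable residue ranges, zero-length
  inter-domain vectors, and missing Cα atoms are errors naming the
  offending range, chain or frame.

## Known limitations

* The crystal-structure geometry check (compact-state angle ≈ 87°, CT–CT
  ≈ 49 Å on the deposited PD-1/PD-L1 complex) requires the PDB entry
  4ZQK, which cannot be redistributed with the package; without it that
  check reports as unavailable.
* Absolute buried-area values are method-dependent (sampling density,
  radii table); compare trends, not absolute Å², across software.
* The kinetic parameters shipped in the example models are illustrative.
  Fitting real binned curves recovers peak position and height reliably,
  individual rate constants only up to the identifiability caveats above.
* Binary MD trajectory formats are out of scope; convert to multi-model
  PDB or the plain coordinate table first.

## Problem sizes used in the validation suite

Round-trip and oracle tests run at sizes chosen to make their statistical
tolerances sharp: 10 random models × 5 forces × 10,000 Gillespie draws
for the mean-lifetime agreement (3·SEM criterion, with one independent
4× escalation for the rare heavy-tail excursion), 10 bins × 200 lifetimes
for peak recovery, 5 × 3,000 frames for label accuracy, and 10 × 2,500
frames for the state-statistics round trip.
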