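# catchbond

Tools for analysing **force-dependent receptor–ligand bonds that switch
between two bound conformations** — the mechanism behind catch bonds of
immune checkpoint complexes such as PD-1/PD-L1 and PD-1/PD-L2.

Single-molecule force-clamp experiments (biomembrane force probe, BFP) show
that the mean lifetime of these bonds first *rises* with tensile force,
peaks in the single-digit piconewton range, and then falls (catch–slip
behaviour). Steered-MD trajectories of the same complexes show two bound
conformations: a compact, crystal-like **state I** (inter-domain angle
≈ 87°, C-terminus-to-C-terminus extension ≈ 49 Å for PD-1/PD-L1) and a
force-extended **state II** (≈ 157°, ≈ 77 Å), with force-driven, reversible
switching between them. `catchbond` packages the computational core of that
analysis for anyone who wants to quantify trajectory geometry, classify
bound states, or model and fit catch–slip lifetime curves.

## What it computes

**Geometry layer** (from multi-model PDB files or plain coordinate tables):

- *inter-domain angle* between backbone-centroid vectors
  (`interdomain_angle()`, with shipped residue-range presets `"pd1"`,
  `"pdl1"`, `"pdl2"`),
- *CT–CT extension* between terminal Cα atoms (`ctct_distance()`),
- *salt bridges* (strict `< 3.5 Å` charged-group heavy-atom criterion),
  *hydrogen-bond chains*, and *buried contact area* (Shrake–Rupley SASA
  difference), per structure or per frame (`extract_observables()`).

**State layer**: hysteresis thresholding of the angle series into states
I/II (`classify_frames()`) and cross-trajectory per-state statistics
reported as per-trajectory means with mean ± SD (`state_statistics()`).

**Kinetics layer**: the two-state Bell-rate Markov model. Each transition
has a rate

```
k(F) = k0 · exp(F · x / kBT),        kBT = 4.28 pN·nm (310 K)
```

with four transitions: dissociation from state I (`k1`) and state II
(`k2`), and the conformational switches I→II (`k12`) and II→I (`k21`).
With occupancy vector `p = (pI, pII)` the bound-state generator is

```
M(F) = [ −(k1+k12)   k21      ]
       [  k12       −(k2+k21) ]
```

giving the closed-form mean lifetime `τ(F) = 1ᵀ(−M)⁻¹ p0` and survival
`S(t) = 1ᵀ exp(Mt) p0`. A catch bond arises when force promotes the switch
into the long-lived state II (`x12 > 0`, `x21 < 0`) faster than it
accelerates dissociation. The layer provides exact Gillespie force-clamp
simulation (`simulate_lifetimes()`), force-binned mean ± SEM curves
(`bin_lifetimes()`), weighted Levenberg–Marquardt fitting
(`fit_two_state()`), peak detection with a catch-bond certificate
(`peak_force()`), and Poisson adhesion-frequency statistics
(`adhesion_frequency()`, `single_bond_fraction()`).

**Synthetic generators** (`generate_state_trajectory()`,
`generate_toy_complex()`, `generate_toy_trajectory()`,
`generate_bfp_dataset()`) produce every input with known ground truth, so
each stage is testable end to end.

## Worked example

```r
library(catchbond)

model <- example_catch_model()
peak_force(model)
#> $peak_force_pN   6.716655
#> $peak_lifetime_s 1.230885
#> $is_catch_bond   TRUE

mean_lifetime_analytic(model, c(0, 7, 20))
#> 0.568 1.227 0.190     # rises from 0.57 s to 1.23 s, then slips
```

The lifetime peaks at **6.7 pN**, in the single-digit-pN regime where human
checkpoint catch bonds peak, with a ~2-fold lifetime enhancement over the
zero-force value. Emulate a BFP campaign and recover the peak from data
alone:

```r
edges <- seq(0, 30, by = 3)
bfp   <- generate_bfp_dataset(model, edges[-11] + 1.5, 200, seed = 42)
curve <- bin_lifetimes(bfp$records, edges)
head(curve, 3)
#>   bin_lo bin_hi bin_mid mean_s  sem_s   n
#> 1      0      3     1.5  0.633 0.0485 200
#> 2      3      6     4.5  0.968 0.0758 200
#> 3      6      9     7.5  1.290 0.1071 200

init <- two_state_model(bell_rate(1, 0.2),  bell_rate(0.1, 0.5),
                        bell_rate(0.5, 1.0), bell_rate(2, -0.5))
fit <- fit_two_state(curve, init, n_starts = 5)
peak_force(fit$model)
#> peak 6.41 pN, lifetime 1.23 s   # planted peak recovered within 0.3 pN
```

Geometry on a planted complex:

```r
tc <- generate_toy_complex(salt_bridges = list(
        list(donor = "ARG", acceptor = "GLU", distance = 3.4)))
detect_salt_bridges(tc$structure)
#>   chain1 resno1 resname1 chain2 resno2 resname2 min_distance bridged evaluable
#> 1      B      1      ARG      A      1      GLU          3.4    TRUE      TRUE
```

A thin command-line front-end over the same functions ships at
`inst/cli/catchbond.R` (subcommands `observables`, `classify`, `stats`,
`simulate`, `bin`, `fit`, `peak`, `generate`, `run`).

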