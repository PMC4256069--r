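---
title: "Mapping gas-migration channels with implicit ligand sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gas-migration channels with implicit ligand sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasmap)
```

## The problem

Small apolar gases (O2, CO, NO, Xe) reach buried active sites of proteins
through transient internal channels: chains of cavities connected by
constrictions whose opening and closing is governed by thermal side-chain
fluctuation. Such channels are largely invisible in a single static
structure; they emerge only when many conformations are examined at once.
`gasmap` implements the standard computational route to them:

1. **Implicit ligand sampling (ILS)** — Widom-style test-particle
   insertion of the gas probe into every voxel of a 3D grid, over an
   ensemble of ligand-free conformations, yielding a potential-of-mean-force
   map of the probe.
2. **Explicit-ligand density maps** — 3D probability densities from
   trajectories that contain the gas explicitly, the empirical
   counterpart used to cross-validate the ILS map.
3. **Free-energy landscape analysis** — watershed tessellation of the map
   into basins, saddle points between adjacent basins, a pathway network
   of minima and saddles, channel profiles with barriers, and block-based
   error estimates.

Because production membrane-protein trajectories are far beyond desk
scale, the package ships a first-class synthetic-systems module: assemblies
of Lennard-Jones (LJ) sites forming cavities and gated channels with
analytically known statistics, so every stage can be validated against
ground truth.

## The insertion free-energy map

For a probe at grid position $r$ the map stores

$$\Delta G(r) = -k_B T \,\ln\Big\langle e^{-\beta E_{int}(r,\Omega)}\Big\rangle_{\text{frames},\,\Omega,\,\delta r}$$

the free energy of moving the probe from vacuum to $r$, with the average
taken over ensemble frames (weighted by their frame weights), uniformly
random orientations $\Omega$, and uniformly random displacements
$\delta r$ within the voxel cube (the cube is centered on the insertion
point with edge equal to the grid spacing; an inscribed-sphere variant is
retained as an option for comparison with the older convention).
$E_{int}$ is the LJ 12-6 interaction of the two probe sites with every
matrix site within the cutoff. Subtracting the probe's bulk-water
solvation free energy (`convert_reference()`, with the offset measured by
`estimate_bulk_offset()` on a homogeneous reference ensemble) re-expresses
the map relative to water, so that bulk-like regions sit near zero.

Key parameters, defaults, and rationale:

* **Probe** (`probe_spec()`): two identical LJ sites,
  $\sigma = 3.0$ Å, $\varepsilon = 0.43$ kJ/mol, bond 1.21 Å — a typical
  united-parameter O2 model; charges are fixed at zero because the probe
  is treated as apolar. Force-field-specific values should be supplied
  through the constructor rather than edited in code.
* **Temperature**: 310 K, the usual physiological simulation temperature.
* **LJ cutoff**: 14 Å, a common long-range truncation; plain truncation,
  no switching.
* **Combining rule**: Lorentz–Berthelot (arithmetic $\sigma$, geometric
  $\varepsilon$) by default, with a `geometric` option since united-atom
  force fields of the GROMOS family combine geometrically.
* **Insertions per voxel** (`n_insertions_per_voxel`): 400 per frame by
  default, matching common production practice; the tests and the
  bundled acceptance study use 25–10⁴ depending on the question.
* **Periodicity**: off by default — after frames are superposed onto a
  common reference the periodic lattice is no longer meaningful; the
  periodic mode exists for bulk-offset estimation on unfitted ensembles.

### Numerical choices

The per-voxel average of Boltzmann factors is accumulated through a
shifted log-sum (log-mean-exp) scheme, so maps stay finite and exact in
the two edge cases that the tests pin down: a zero-$\varepsilon$ probe
gives *exactly* zero everywhere, and voxels farther than cutoff + bond
length from every site give exactly zero. Voxels whose average factor
underflows are set to the grid's `value_cap` (default 100 kJ/mol, far
above the 20 kJ/mol network cutoff so capping can never alter network
topology) and flagged in the map's `capped` mask. Overlapping insertions
produce large positive but finite energies (the squared distance is
floored at $10^{-6}$ Å²), so no special-casing of singularities is
needed downstream.

Each (voxel, frame) pair draws its insertions from an independent RNG
stream seeded by a hash of (seed, voxel index, frame label). This makes
maps independent of evaluation order, bit-reproducible, and gives the
exact *frame-pooling identity*: the map of a pooled ensemble equals the
Boltzmann-factor-weighted combination of sub-ensemble maps computed with
the original frame labels (`frame_ids`), which the test suite asserts to
machine precision.

### Monte Carlo error near steric walls

The insertion estimate has a position-dependent variance with a sharp
structure: in open or uniformly attractive regions the relative standard
error of the average factor is $\mathcal{O}(n^{-1/2})$ with a small
constant, but in voxels straddling a repulsive LJ wall the average is
dominated by a thin low-energy sliver (the $r^{-12}$ wall has an
e-folding length of only a few hundredths of an Å at energies of
10–25 kJ/mol), so the standard error of $\Delta G$ at such voxels is
approximately $k_BT\sqrt{e^{\beta\Delta G_{\rm eff}}/n}$ — a few tenths
of a kJ/mol at $n = 10^4$ and $\Delta G \approx 15$–20 kJ/mol, shrinking
only as $n^{-1/2}$. Deep-channel topology is unaffected (wall voxels are
either excluded by the network cutoff or dominate nothing), but
voxel-level agreement with a deterministic quadrature at the 0.1 kJ/mol
level across an entire wall region requires $n \gtrsim 10^6$, not
$10^4$. The test suite documents this honestly: it measures the error
distribution against an independent radial quadrature and verifies the
$n^{-1/2}$ scaling.

## Explicit-ligand sampling and density maps

`sample_explicit_ligand()` runs a Metropolis random walk of the rigid
diatomic (translation plus axis rotation through a random-axis Rodrigues
move, both symmetric proposals) in the field of an ensemble frame that
is re-drawn uniformly at a fixed stride. Only the stationary
distribution matters for validating density maps, which is why Monte
Carlo was chosen over Langevin dynamics: the recorded positions are
asymptotically Boltzmann-distributed in the frame-averaged sense, with
no time-step or friction parameters to justify. A full window of
rejected moves (1000 steps) aborts with a diagnostic, since it means the
step sizes or the system are pathological.

`compute_density_map()` histograms ligand centers (nearest-voxel
assignment) and normalizes by frames × voxel volume, so that the sum of
voxel values times voxel volume is *exactly* the mean number of in-grid
ligands per frame; positions outside the grid are tallied separately,
never silently dropped. The conventional display iso-level for dioxygen
densities, 0.00015 Å⁻³, is the default in `isosurface_report()`, which
counts voxels above level and their 26-connected components. No kernel
smoothing is applied by default; smoothing would break the exact
normalization identity the tests rely on.

Consistency between the two routes is itself a property under test: for
a frozen system, voxel occupancies of the sampler are proportional to
$V_{\rm vox}\,e^{-\beta\Delta G(r)}$ with the *cube-averaged* $\Delta G$
that ILS computes, so cavity occupancy ratios from both routes must
agree within sampling error — the package's small-scale analogue of
comparing an ILS landscape against explicit-gas simulations.

## Landscape analysis

`tessellate()` performs a steepest-descent (watershed) classification:
every voxel at or below the cutoff repeatedly moves to its
lowest-valued neighbor until no neighbor improves on it. Two
conventions the underlying idea leaves open are fixed here as explicit,
testable rules:

* **Connectivity** defaults to 26 neighbors (diagonal moves allowed),
  which gives smoother descent on 1 Å grids; 6 and 18 are available for
  sensitivity checks.
* **Ties and plateaus** break toward the smallest linearized voxel
  index; a move on equal values happens only toward a smaller index, so
  a flat grid drains deterministically to its first voxel.

`find_saddles()` defines the boundary between basins as the set of
neighboring voxel pairs with different labels, the saddle energy as the
minimum over the boundary of the pair maximum, and the saddle voxel as
the higher-valued voxel of the achieving pair (ties again toward the
smallest index). This convention is not arbitrary: it makes the saddle
energy provably equal to the minimax path energy — the lowest achievable
maximum voxel energy over all paths connecting the two minima *within
the union of the two basins*. (Unrestricted minimax between two minima
can be lower when a detour through a third basin exists; the network as
a whole captures those detours, and `route_between()` finds the global
bottleneck route by thresholded search over the network.) The test
suite checks the identity against an exhaustive threshold/flood-fill
oracle.

`build_network()` turns minima into nodes and admissible saddles into
edges carrying both directional barriers (saddle minus source minimum);
basins containing a voxel on a grid face are flagged exterior, marking
entry points from the surroundings. The published convention this
follows uses a 20 kJ/mol cutoff for network construction but does not
state whether it bounds voxel energies, saddle energies, or barriers;
both defensible readings are implemented behind
`cutoff_mode = "voxel"` (default: only voxels up to the cutoff
participate at all) and `"saddle"` (everything up to the value cap is
tessellated, edges are filtered on saddle energy), without asserting
either as the original intent.

`extract_profile()` produces the alternating minimum/saddle sequence
along a route with forward barriers defined as saddle minus the
*preceding* minimum — the barrier felt travelling the route — and
reverse barriers against the following minimum, so forward minus
reverse equals the free-energy difference between consecutive minima.
`block_errors()` runs the whole analysis independently on maps from two
disjoint data blocks, matches features greedily by nearest position
within a radius (default two voxels; the convention is ours, stated
because no standard exists), and reports half the absolute energy
difference as each feature's error; features present in only one block
are flagged *uncomputable* rather than given an error of zero.

## What the synthetic systems emulate — and what they do not

`toy_system_spec()`/`make_fluctuating_ensemble()` model the matrix as LJ
sites with independent isotropic Gaussian displacements about fixed
means. This is the simplest model with a tunable analogue of thermal
side-chain fluctuation, chosen deliberately so that ground truth stays
analytically tractable (the zero-noise limit is exact, displacement
statistics are known, and frozen systems admit quadrature oracles).
It does **not** reproduce correlated collective motion, anisotropic
fluctuation, bonded topology, electrostatics, or solvent — so passing
tests demonstrate the correctness of the *method implementation*, not
fidelity to any particular protein.

`make_channel_system(open_fraction)` builds a cylindrical channel along
x in a 20×14×14 Å box: an open mouth, a wall of rings (radius 6 Å,
10 carbon-like sites per ring, 1.5 Å ring spacing — close enough that
the wall is sterically tight), an 8-site gate at x = 8.25
built from two angularly staggered 4-site sub-rings whose radii grow
linearly with `open_fraction` (1.2 → 6.0 Å and 3.4 → 5.8 Å): closed,
the sub-rings tile the entire lumen cross-section — a gate that blocks
only the axis would leave a soft annular leak between gate and wall —
and open, they retract into the wall so the aperture clears twice the
probe diameter. There is also an attractive double-ring cavity at
x = 12.75 and a 25-site end cap. Gate sites fluctuate more (0.4 Å vs
0.25 Å) so a nominally closed gate opens transiently — the mechanism by
which a time-averaged map shows a finite rather than infinite
constriction barrier. The exterior-to-cavity bottleneck saddle
decreases monotonically with `open_fraction` by construction, which the
acceptance study measures from the maps (representative run: ≈ 65, −7.6
and −14.0 kJ/mol at open fractions 0.2, 0.6, 1.0 with 20 frames and
150 insertions/voxel).

## Problem sizes used in the bundled studies

The shipped tests and the acceptance script work at deliberately small
scale, chosen so each study answers its question with comfortable
statistical margins: 11³–19×11×11 voxel grids at 1 Å spacing, 1–20
frames, 25–10⁴ insertions per voxel, Metropolis trajectories of
2–6×10⁵ steps, and 100 random 8³ grids per connectivity for the
watershed oracle comparisons. All randomness flows from explicit seeds;
every study is reproducible bit for bit.

## Known limitations

* LJ-only energetics: no electrostatics, polarizability, or flexible
  probe; the probe is a rigid two-site diatomic.
* The ILS estimator's variance grows exponentially with the wall energy
  of a voxel (see above); wall-voxel values at default sampling are
  qualitative.
* Basin/saddle conventions (connectivity, tie-breaking, feature-matching
  radius) are stated choices; results near degenerate plateaus depend on
  them, which is why they are deterministic and documented rather than
  left to floating-point accident.
* The explicit-ligand sampler re-draws a frame per stride, which samples
  the *frame-averaged* Boltzmann density — appropriate for validating
  density maps, not for kinetics; no rates or committors are computed
  anywhere in the package.
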