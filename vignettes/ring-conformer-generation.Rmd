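---
title: "Ring-driven conformer generation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-driven conformer generation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ringconf)
```

`ringconf` generates conformational ensembles for small molecules and
macrocycles by deterministic physical ring movements over a molecular
mechanics energy, rather than by torsion templates, distance geometry or
stochastic sampling. This vignette is the package's own account of the
model: what is computed, which parameters matter, which choices were open
and how they were made, and what the synthetic fixtures do and do not
emulate.

## The search model

A molecule enters as a topological graph (SMILES, SDF or mol2; hydrogens
added by standard-valence protonation when absent). Stereochemistry is
*noted* — tetrahedral centers with four topologically distinct substituents
by signed volume, exocyclic double bonds by torsion sign — before any
coordinates are discarded. Conformational search always begins from a
memory-free start: coordinates are regenerated from topology alone (main
macrocycle on a circle, other ring systems from a seeded 2-D spring layout,
substituents attached breadth-first), relaxed in stages, repaired to the
noted configurations and re-minimized. The lowest-energy of up to ten valid
embeddings becomes the start, which discards pathological high-energy folds.

Ring perception assigns each bond the size of its smallest enclosing ring
(shortest path between its ends with the bond deleted, plus the bond). A
bond is *macrocyclic* when that size is nine or more — the threshold is
sharp: cyclononane is a macrocycle, cyclooctane is not. Small-ring systems
are components over bonds with ring size three to eight; macrocyclic systems
are components containing a macrocyclic bond, decomposed into a main cycle
and bridges. Among candidate cycles, the main cycle maximizes the number of
macrocyclic bonds and then minimizes atom count, so a fused proline ring
does not divert it while a disulfide shortcut is classified as a bridge; for
the 14-residue disulfide-bridged peptide fixture this yields the 42-atom
backbone cycle with a Cβ–S–S–Cβ bridge.

The search itself is a fixed-point iteration: every pool member is expanded
exactly once by all eligible moves, candidates are minimized (pinned phase,
then free), and survive only if they preserve the noted configurations, fall
inside the energy window, and are non-redundant by ring-atom RMSD against
the pool. Iteration stops when no new ring conformers appear, a round cap is
reached, or the pool hits the mode cap. Exocyclic torsions are then
elaborated over staggered (sp3: ±60°, 180°) or planar (conjugated: 0°, 180°)
values with greedy combination, and the final ensemble is energy-sorted,
windowed, redundancy-pruned on heavy atoms and truncated to the mode cap.

Two points deserve emphasis. First, redundancy during search is
**label-fixed** ring-atom RMSD: symmetry-equivalent relabelings (e.g. the
twenty automorphic images of a cyclodecane conformation) count as distinct
conformers, which matches how the conformer pools are assembled; graph
automorphisms enter only in *evaluation*, where RMSD to a reference is
minimized over all symmetry self-maps. Second, noted configurations are
*enforced* (improper-volume penalty terms active in every minimization)
rather than merely checked. The enforcement term `k·max(0, m₀ − s·v)²` on
the normalized tetrahedral volume v is exactly zero once the configuration
is safely formed, so it does not bias relative energies; pure checking
proved fragile with this package's embedder, either wandering across
diastereomers (for inputs without stereo descriptors) or discarding nearly
every candidate.

## The energy model

Minimization uses a compact valence force field implemented in C++:

| term | form | parameters |
|---|---|---|
| bond | `k(r − r₀)²` | r₀ from covalent radii (× 0.87 double, × 0.78 triple); k = 350/550/750 kcal/mol/Å² |
| angle | `k(θ − θ₀)²` | θ₀ = 109.47°/120°/180° by hybridization; small-ring interior angles for 3–5 rings; k = 60 (35 with H) kcal/mol/rad² |
| torsion | `V/2 (1 + cos(nφ − φ₀))` | sp3–sp3: n = 3, V = 2.9 kcal/mol per bond (the ethane barrier), split over paths; conjugated single: n = 2, V = 4; double bond: V = 30; amide C–N: V = 14 (planar, trans/cis minima) |
| out-of-plane | `k·h²` | trigonal sp2 centers, k = 40 kcal/mol/Å² |
| nonbonded | 12-6 LJ (Rmin form) + `332·qᵢqⱼ/(2r²)` | radii/ε by element; electronegativity-increment charges; 1-2/1-3 excluded, 1-4 scaled 0.5; distance-dependent dielectric |

The torsional amplitude matters most for conformer counting: with a
noticeably softer barrier, distinct ring minima of fused systems collapse
into one another. The cyclohexane chair/twist-boat gap under these
parameters is ≈ 5.4 kcal/mol, close to the textbook value.

This force field is the package's own; it is a deliberately small model in
the spirit of general-purpose MM parameterizations, not a re-implementation
of any published parameter set. Absolute energies and the relative spacing
of ring conformers therefore differ from richer force fields, which shifts
converged conformer counts (see "Worked-example counts" below).

Minimization is L-BFGS (history 7, Armijo backtracking, per-coordinate step
cap 0.5 Å) with gradient RMS tolerance 1e-4 kcal/mol/Å (5e-4 inside move
loops) and a 2000-iteration cap; a plateau exit fires when energy progress
stalls near a flat minimum. All of it is deterministic: identical inputs and
seeds give byte-identical ensembles, independent of the `threads` knob
(parallelism is a contract of the expansion loop, whose merge order is
deterministic; the implementation is serial).

## Restraints

Positional pins (`k|x − x₀|²`), square-well distance restraints
(`penalty · max(0, |d − dist| − wiggle)²`, measured between group centroids
for symmetry-degenerate `qnmr` protons), square-well torsion restraints
(quadratic in degrees beyond `[lo, hi]`, periodic) and chirality impropers
share one implementation between the minimizer and the profiler, so the
violation energy a profile reports is exactly the penalty the search felt.
NMR restraints stay active from initial structure generation through every
minimization of the search. Distance restraints default to the conventional
± 0.5 Å wiggle; discrete violation counting uses 0.2/0.5 Å and 5°/15°
thresholds (configurable).

## Search modes and knobs

Seven modes trade accuracy for time; the per-mode caps are fixed
(50 for `pfastf`/`pfast`; `pscreen` 50 or 120 when the rotatable-bond count
exceeds 8; 250 for `pgeomf`/`pgeom`; 1000 for `pquantf`/`pquant`). Deeper
modes enable sub-cycle flips (`pgeom`, `pquantf`, `pquant`) and, on
macrocycles, hydrogen-bond network exploration (`pgeom`, `pquant`). Round
caps and twist angle schedules (±60°/180° shallow; ±60°, ±120°, 180° deep)
are package defaults chosen for coverage at modest cost — the reference
tool's internal budgets are unpublished. Other defaults: search window 10
kcal/mol, final macrocycle window 20, ring-RMSD duplicate gate 0.3 Å,
heavy-atom assembly gate 0.5 Å, triplet starts capped at 8, pin constant
100 kcal/mol/Å².

Open choices and how they were fixed:

- *Bend eligibility.* "The pair must not cross a bridged ring atom or a ring
  fusion" is implemented as: removing the axis pair must split the system
  into exactly two sides. Pairs spanning a fusion leave the system connected
  and are excluded (decalin), while the fusion-atom pair itself is a valid
  axis — the butterfly bend of fused bicyclics, without which fused drugs
  like tetracycline barely move.
- *Flip arcs.* "All atoms between the ends of the two bonds" is
  side-ambiguous; both arcs are emitted as independent candidates and the
  energy/window checks filter.
- *Triplet topology.* Pair anchors are the main-cycle atoms bearing (or
  nearest to) the donor/acceptor; positions are numbered along the main
  cycle and index deltas compared modulo ring size, requiring exact
  negation between donor and acceptor sides, three distinct donors and
  three distinct acceptors. Enumeration is a literal scan of all
  three-subsets.
- *Amides.* "Non-amide" single bonds (flexibility count, twist eligibility)
  exclude any C–N single bond whose carbon bears a double-bonded O/S;
  amide nitrogens are planar and are not acceptors.
- *Percentiles.* RMSD95 uses linear interpolation (R quantile type 7).
- *KS coefficients.* The asymptotic form `c(α)·sqrt((n+m)/nm)` with
  `c(α) = sqrt(−ln(α/2)/2)`; exact small-sample inversion is out of scope.

## Worked-example counts and problem sizes

The package's two headline numbers, recomputed by `scripts/acceptance.R`,
are the converged ring-conformer counts for cyclodecane
(twist-and-bend search of the 10-ring; the pool saturates the 250-conformer
cap of the standard geometric mode) and tetracycline (bend search of the
fused four-ring system with stereochemistry from its isomeric SMILES;
converges at ≈ 46 conformers, seed-stable within a few counts). Under the
package's force field the tetracycline pool's energy spread reaches the
10 kcal/mol search window, so this count is sensitive to the force field's
relative-energy scale; richer parameterizations report roughly twice as
many. Test-suite simulations use deliberately small problem sizes — ring
searches on 30–60-atom molecules, shallow searches (25-conformer caps, two
rounds) on 5–6-residue cyclic peptides — so the full suite completes in
minutes on one core.

## What the fixtures emulate

`make_cycloalkane` provides the bend/twist workhorses. `make_cyclic_peptide`
builds head-to-tail backbones (three main-ring atoms per residue) with
controllable N-methylation (removes amide donors), prolines (fused
five-ring, no donor), ester linkages (depsipeptides) and a disulfide bridge
— enough to exercise donor/acceptor perception, bridge handling and triplet
topology: the 9-residue, 4×N-methyl, one-proline, one-ester analog has a
27-atom ring and exactly three ring N–H donors and one compatible
hydrogen-bond triplet; the 14-residue disulfide analog has a 42-atom main
cycle with the disulfide classified as a bridge. These are *toy* topologies
with a minimal sidechain alphabet: they do not reproduce real side-chain
sterics, solvent effects, or the conformational preferences of particular
natural sequences, so passing tests demonstrate the machinery, not
biological accuracy.

`make_synthetic_constraints` samples polar-H/acceptor distances from a known
reference conformer (± 0.5 Å wiggle), enabling parameter-recovery
experiments: across five 5–6-residue fixture peptides with sixteen
noise-free restraints each, the constrained shallow search concentrates
ensembles toward the generating reference (paired mean-RMSD reduction
≈ 0.2–0.5 Å); conditions chosen to mirror the restraint density of
published sparse-NMR studies of comparable rings. `make_synthetic_rdcs`
forward-calculates couplings from a chosen Saupe tensor, making the
alignment-tensor fit an exact inverse problem at zero noise (Q = 0) and a
calibrated one under multiplicative noise (Q on the scale of the noise).

## Known limitations

- The valence force field has no explicit hydrogen-bond term beyond
  electrostatics and no solvent model; hydrogen-bond wells during triplet
  exploration come from restraints, not the force field.
- Stereocenters are detected by iterative neighborhood refinement; centers
  distinguishable only by remote ring features may be missed (and are then
  neither noted nor enforced).
- The embedder is a layout-plus-minimization scheme; for heavily fused or
  bridged topologies it relies on the repair-and-retry loop, and a
  persistent chirality failure is surfaced as an error rather than silently
  accepted.
- Automorphism enumeration is capped at 10,000 maps; beyond that a warning
  is raised and the enumerated subset is used.
- Kekulization of aromatic mol2 input is not attempted (aromatic bonds read
  as order 1 with planarity flags); prefer SDF or SMILES for aromatic
  systems.
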