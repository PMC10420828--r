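---
title: "Methods: geometric trajectory analysis and cluster-model energy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric trajectory analysis and cluster-model energy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechprof)
```

`mechprof` implements the desk-side halves of the combined MD +
quantum-cluster workflow used to characterize enzyme reaction
mechanisms: geometric post-processing of active-site trajectories,
selection of catalytically competent conformations, bookkeeping of
truncated quantum-cluster models, and assembly of composite reaction
energy profiles with transition-state-theory rate interconversion.
It does not run MD or DFT; it consumes their outputs as structures,
trajectories and energy-component records.

## Hydrogen bonds and water bridges

A hydrogen bond is scored purely geometrically.  For an annotated
donor heavy atom D with attached hydrogen H and an acceptor A, the
triple qualifies when

* the donor–acceptor distance d(D,A) is at most the cutoff
  (default **3.2 Å**), and
* the D–H–A angle deviates from linearity by at most the cutoff
  (default **50°**, i.e. ∠DHA ≥ 130°).

Both defaults are the conventional strong/medium-strength bond
criteria of trajectory-analysis tools.  The angular criterion is
implemented as deviation from 180°; the literal reading "angle
between donor, hydrogen and acceptor ≤ 50°" is geometrically
impossible for a bonded triple (H sits ~1 Å from D, so ∠DHA is
always large), so the deviation convention is the only sensible one;
both cutoffs are configurable via `hbond_criterion()`.  Comparisons
are inclusive (`<=`) so boundary behavior is deterministic.  Donor
and acceptor in the same residue are never paired.

Donor/acceptor chemistry is supplied explicitly by a
`topology_annotation()`, not inferred from element tables: mechanism
studies analyze specific named contacts, and inference heuristics add
silent variability between runs.

**Occupancy** of a contact is the percentage of analyzed frames with
at least one qualifying geometry for that (residue, atom-name) pair;
the denominator is always the full frame count.  Pair identity is per
atom name, so a side chain offering two equivalent hydrogens counts
once per frame.  Pairs are reported above a 5% threshold by default
(mirroring the usual "present more than 5% of the time" convention);
a threshold of 0 enumerates every candidate pair including
never-formed ones.

A **water bridge** is reported when one water simultaneously forms
qualifying bonds — in either polarity — to atoms of two endpoint
sets.  Tightening either cutoff can only shrink the set of qualifying
triples, so occupancies are monotone in both cutoffs; the test suite
checks this property over randomized cutoff pairs, and checks both
detectors against exhaustive brute-force enumeration on random small
frames.

## RMSD and superposition

`kabsch_superpose()` computes the least-squares proper rotation via
SVD of the 3×3 covariance matrix (determinant-corrected), and
`rmsd_series()` applies it per frame against a reference frame
(default: the first frame, unweighted Cα selection), so the series
starts at zero.  Degenerate (collinear) selections are rejected
rather than silently fit.  The implementation is cross-checked
against an independent quaternion characteristic-polynomial RMSD
oracle to 1e-6.

## Frame selection and classification

The reactive coordinate is the per-frame minimum distance from the
cofactor methyl carbon to the candidate acceptor oxygens of the
substrate carboxylate.  Frames are **catalytically competent** when
this distance is strictly below 2.8 Å ("below" is read as strict; the
boundary case 2.8 is excluded).  Each frame's key contact is labelled
`DIRECT` (the named direct bond qualifies, no bridge),
`WATER_MEDIATED` (bridge only), `BOTH` or `NEITHER`; all four labels
are retained rather than forced into two classes, so the two
mechanistically distinct patterns emerge as the dominant classes
instead of being imposed.

**Representatives** are per-pattern medoids: the catalytic frame
minimizing mean pairwise superposed heavy-atom RMSD to the other
catalytic frames of its pattern, ties broken toward the lower frame
index.  Source studies rarely state their representative-picking
procedure; the medoid rule is chosen here because it is deterministic
and reproducible, and it is the one point of this module most likely
to differ from any particular study's hand selection.

## Cluster models

`build_cluster_model()` extracts a residue subset (whole residue,
side chain only, or backbone fragment), plus listed waters, in
deterministic spec-then-file order.  The truncation scheme follows
the frozen-boundary convention: atoms at the cut points are fixed to
emulate the scaffold, so capping with link hydrogens defaults off
(when enabled, a hydrogen is placed at 1.09 Å along each cut-bond
vector).  Bond connectivity — used only for validation — is inferred
from single-bond covalent radii scaled by 1.2, so validation operates
on bare coordinates without topology files.  `validate_model()`
flags unfrozen uncapped boundary atoms, frozen fractions outside
1–50%, and electron-count/multiplicity parity mismatches.  Atom
counts are pure functions of the spec: adding one whole water changes
the count by exactly 3 (the 192- vs 189-atom pairing typical of
water-in/water-out model pairs).  Published models' exact residue
lists are usually not printed, so truncation specs are user-supplied
configuration, not something the package guesses.

## Composite energy profiles

For each stationary point (initial, TS, final) the composite relative
energy is

E = ΔE_LB + ΔE_solv(ε) + ΔZPE

with ΔE_LB the large-basis relative electronic energy, ΔE_solv the
continuum-solvation difference at dielectric ε (4 or 80), and ΔZPE
the zero-point correction, all in kcal/mol.  Absolute-mode solvation
columns are relativized against the same model's initial state.  The
default dielectric is ε = 4, the standard protein-interior choice
for cluster calculations; ε is always recorded in outputs.  The
barrier is E(TS) − E(initial); the reaction is exoenergetic when
E(final) − E(initial) < 0.  Because the assembly is exactly linear in
each component, the ε = 80 and ε = 4 barriers differ by exactly the
solvation-difference delta — a property the tests exploit.

Component tables are read from a CSV with a one-line mode header (or
a JSON mirror); displayed energies are rounded to one decimal as in
standard published tables, with full precision retained internally.
Hartree inputs convert at 627.509474 kcal/mol.  One consequence of
one-decimal tables: components that sum to 17.5 may accompany a
printed barrier of 17.6, a rounding artifact the package reports
as-is rather than "correcting".

## Eyring conversions

`eyring_barrier_from_rate()` / `eyring_rate_from_barrier()` use
ΔG‡ = RT·ln(k_B·T/(h·k)) with transmission coefficient 1 and pinned
constants R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹ and k_B/h =
2.083661×10¹⁰ s⁻¹ K⁻¹ (`mechprof_constants()`, versioned in every
profile output so results are bit-stable across platforms).  The
default temperature is 303 K — the activity/simulation temperature of
the reference enzyme; with it, a 0.31 s⁻¹ turnover number converts to
18.45 ≈ 18.5 kcal/mol.  The two functions are strict inverses.

## The synthetic generator

`generate_trajectory()` emulates the statistical structure of an
active-site trajectory: two persistent donor contacts (defaults 95%
and 75% occupancy, the His/Gln-like anchors), one intermittent
contact that alternates per frame between a direct bond (20%), a
water-mediated bridge (20%) and neither, and a reactive distance
fluctuating around 3.1 ± 0.15 Å so that the sub-2.8 Å catalytic tail
is a few percent of frames and the series rarely exceeds 3.4 Å.
These defaults are the study conditions the tests run under; 2000
frames at 10 ps spacing mirrors a 20 ns production run, while tests
use 100–400 frames for speed (the generator is O(n_frames) and the
statistics scale as stated).

Planting is exact by construction: bonded frames draw the
donor–acceptor distance uniformly from [2.6, 3.1] Å and unbonded
frames from [3.6, 4.5] Å, with off-axis jitter truncated at 0.3 Å,
so every planted geometry clears the 3.2 Å / 50° criterion with a
margin and the ground-truth ledger can never disagree with the
detector by rounding.  Global positional noise (default σ = 0.5 Å)
is applied to the scaffold Cα atoms only — it drives the RMSD
stability checks without perturbing the planted contact geometry.
The generator is a 19-atom caricature of an active site, not a
protein rebuild: passing tests demonstrate the correctness of the
geometry and bookkeeping code under known ground truth, not the
realism of force-field dynamics, solvent structure, or the
occupancies of any real system.  RNG is Mersenne-Twister with
inversion normals, fully determined by the recipe seed.

`generate_energy_table()` mirrors the component-table structure with
recipe-implied barriers, exact at zero perturbation, for
property-testing the profile assembly.

## Numerical and design notes

* Coordinates are Å and energies kcal/mol everywhere; frame indices
  are 1-based.
* PDB dialect: ATOM and HETATM are treated uniformly; alternate
  locations resolve to the highest-occupancy conformer (ties to file
  order); insertion codes are part of residue identity; malformed
  numeric fields fail with the offending line number.  The writer is
  lossy by contract (coordinates at the format's 3-decimal
  precision, no headers/connectivity).
* Binary trajectory formats are out of scope; multi-model PDB and
  multi-frame XYZ keep the core bit-stable and dependency-light.
* Scan maxima break ties toward the smaller constrained distance;
  the catalytic filter is strict; H-bond cutoffs are inclusive.
* The crystal-contact measurement (`measure_min_distance`, CLI
  `crystal-distance`) reports the shortest cofactor-S to
  carboxylate-O separation; the packaged example PDB is a small
  synthetic stand-in site with a 3.3 Å planted contact, not a
  deposited structure.

## Limitations

Hydrogen-bond scoring is geometric only (no energetic or
directionality weighting beyond the linearity cutoff); π-stacking and
hydrophobic contacts are not detected.  Profiles include ZPE but no
thermal enthalpy/entropy corrections or tunneling.  Cluster-model
validation infers bonds from covalent radii and can mislabel unusual
coordination.  The synthetic generator tests code paths, not physics.
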