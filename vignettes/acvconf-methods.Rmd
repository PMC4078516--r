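---
title: "Conformational analysis of acyclic nucleoside analogues with acvconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational analysis of acyclic nucleoside analogues with acvconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acvconf)
```

## The problem

Acyclovir is a guanine derivative in which the deoxyribose of
2'-deoxyguanosine is replaced by an acyclic 2-hydroxyethoxymethyl chain.
Because the chain has no ring constraint, the molecule's conformational
space is governed by five exocyclic torsions,

* phi1 (C4-N9-C1'-O2'), the glycosidic-like orientation of the base
  (the chi analogue of nucleosides),
* phi2 (N9-C1'-O2'-C3') and phi3 (C1'-O2'-C3'-C4'), the chain folds,
* phi4 (O2'-C3'-C4'-O5'), the hydroxymethyl orientation,
* phi5 (C3'-C4'-O5'-H5'), the hydroxyl proton orientation,

together with three pseudo-bond observables fixing the hydroxyl end of the
chain relative to the base plane: the distance R = N9...O5' and the angles
beta (C4-N9...O5') and Phi (C1'-N9...O5'), both with vertex at N9. The
guanine moiety itself can exist in five tautomers: the keto forms with the
labile proton on N1, N3 or N7, and the cis/trans enol forms OHC/OHT.

`acvconf` implements the complete desk-scale analysis around these
observables: descriptor computation and torsion driving on labeled 3D
structures, syn/anti classification, circular torsion-range binning,
Boltzmann populations from tabulated relative energies, purine-ring
nonplanarity, hydrogen-bond detection and typing in monomers and multimer
assemblies, and a five-torsion grid conformational search under a pluggable
energy model. All quantum-chemical quantities -- relative electronic
energies with zero-point correction (dE), Gibbs energies (dG), dipole
moments, partial charges -- are *inputs*, never computed.

## Sign conventions and numerics

Torsions follow the IUPAC convention (cis = 0, positive clockwise looking
down the central bond) and are reported in (-180, 180]. Grid phases stated
on [0, 360) are normalized through `wrap_angle()`. `dihedral_angle()`
refuses geometry whose flanking angles are within 1e-8 of colinear;
`zmatrix_to_cartesian()` (a natural-extension / NeRF builder) reproduces
every supplied internal coordinate to 1e-6 Angstrom and 1e-4 degrees, and
`set_torsion()` drives a torsion exactly by rigidly rotating the distal
fragment, refusing axes that lie on a ring. No mirror-image
canonicalization is performed; signs are reported as measured.

A subtlety worth recording: on the circle, a printed interval bound of
-180 is kept distinct from +180, so a bin written `[-180, -66]` behaves
exactly as written; values that *round* to -180 stay on the negative side.

## Boltzmann populations

For records with relative energies `E_i` the population is
`p_i = exp(-E_i/RT) / sum_j exp(-E_j/RT)`, in percent, with
R = 1.98720425e-3 kcal/(mol K) ("kT" is interpreted per mole). The
implementation subtracts the minimum energy first, which makes the result
reference-shift invariant by construction; the T -> 0 and T -> Inf limits
are asserted numerically in the tests.

Although the Boltzmann formula is conventionally stated with the Gibbs
energy, the packaged reference tables reproduce their printed populations
(48.1 / 37.7 / 14.3 for the tautomers; 41.5 / 36.1 / 9.6 / 8.7 for the
conformers) from the **dE (electronic + ZPE) column, not the dG column**.
We verified this numerically, so `population_config()` defaults to
`energy_column = "dE"` while keeping `"dG"` selectable.

```{r populations}
p <- boltzmann_populations(tautomer_table(), population_config(298.15, "dE"))
round(setNames(p$population, p$name), 1)
```

## Classification, binning and energy bands

Class A (anti) is phi1 < 0, class B (syn) is phi1 > 0; phi1 = 0 exactly is
refused rather than guessed. Torsion bins are closed circular intervals; a
bin `c(175, -173)` wraps through 180 (the trans mode of phi4). The default
bins encode the reference modal structure: phi1-phi3 bimodal, phi4/phi5
trimodal.

The published interval endpoints are the *rounded observed extremes* of
each mode. Taken literally they exclude the very conformers that define
them (for instance the phi3 bound 58 degrees against an observed 57.8), so
`bin_torsions(..., round_to = 0)` evaluates membership on values rounded to
the printed precision; with that, the phi3 split is reproduced exactly
(32/46 with the 22/10 and 25/21 class splits). The phi2 split computes to
48/30 against a published 49/29: the source text counts one more
positive-phi2 A conformer than its own printed table contains. We keep the
printed table; the corresponding acceptance test is intentionally red and
the discrepancy is documented rather than tuned away.

Energy bands are half-open `[lo, hi)` with a closed final bound (so the
printed band counts partition the 78 records); the anti/syn ratio is
count(A)/count(B), reported raw and rounded to one decimal as printed.

## Hydrogen bonds

The monomer site inventory has four donors -- H1(N1), H2(N2), H2'(N2),
H5'(O5') -- and five acceptors: O6, N3, N7, O2', O5'. Distances are
measured H...acceptor, matching the 1.7-2.4 Angstrom magnitudes reported
for these contacts. Defaults: `max_HA_distance = 2.6` (covers the weakest
reference contact, 2.350 Angstrom, with margin) and `min_DHA_angle = 110`,
an added angular guard -- the reference states distances only -- and both
are configurable. On the idealized template the type (ii) H5'...O2'
contact occurs at a donor angle near 109 degrees, slightly under the
default guard; tests that pose that motif relax the angle, which is the
intended use of the configurable spec. Intramolecular typing is scoped to
the H5' donor: type (i) is H5'...N3 (the strong, stabilizing contact of
the lowest-energy conformers), type (ii) is H5'...O2'.

## The grid search

The search protocol enumerates all combinations of the driven torsions
(default: all five at 60-degree steps, 6^5 = 7776 starts, phases 0
inclusive to 360 exclusive) and relaxes each start by cyclic coordinate
descent restricted to the driven torsions: a coarse 15-degree circular scan
plus golden-section refinement per torsion, swept until the energy
improvement falls below `tol_energy` and no torsion moves more than
`tol_angle`. Bond lengths and angles stay fixed by design -- full
Cartesian relaxation belongs to the quantum-chemistry stage this package
deliberately treats as an input -- so the engine is exact, fast and
testable. Minima are merged when all driven torsions agree within a
circular `dedup_tol` (default 20 degrees, half the smallest spacing between
neighbouring reference minima); survivors are split by the sign of phi1 and
numbered A1..An / B1..Bm by ascending energy, ties broken lexicographically
on torsions rounded to 0.1 degree, which also makes the result independent
of input order.

The packaged surrogate energy (`toy_energy_model()`) is a sum of per-torsion
cosine preferences centred on the global-minimum torsions, a soft-sphere
repulsion over nonbonded pairs, and bounded attractive wells on H5'...N3
and H5'...O2' so the two intramolecular H-bond motifs are favored. It is
labeled a surrogate everywhere; no claim is made that its minima correspond
to the 78 quantum-chemistry minima, and the tests instead check the engine
against brute-force basin enumeration on two-torsion landscapes. Tests and
examples run reduced grids (two torsions and/or 120-degree steps) to stay
inside desk-scale budgets; the full 7776-start enumeration is validated by
counting, not by running, the start list.

## The synthetic-data module

`build_template()` constructs an idealized full-atom acyclovir geometry:
the purine bicycle as two fused regular polygons (exactly planar, bond
length 1.39 Angstrom), in-plane substituents along external bisectors, and
the chain grown by NeRF from a documented table of standard small-molecule
bond lengths and angles, so that requested torsions are realized exactly.
The reference work prints no usable coordinate set, so *no coordinate-level
agreement* (bond lengths, R, beta, Phi values) with published geometries is
claimed anywhere -- only torsion-level observables are exact by
construction. Tautomers differ only in proton placement (N1/N3/N7 keto;
enol H6 on O6 at a N1-C6-O6-H6 torsion of 0 or 180 for OHC/OHT), our
reading of the tautomer scheme, since the original figure is an image.

`generate_ensemble_table()` draws torsions from wrapped-normal mixtures
whose weights are the observed modal fractions of the 78-conformer
reference set (e.g. 47/78 anti), whose centers sit near the modal midpoints
and whose spreads put roughly three standard deviations across each printed
modal range; energies follow a truncated exponential (mean 2.5 kcal/mol,
cut at 8.5, re-anchored at zero) -- a realistic shape for a conformer
ladder that is dense at the bottom. The generator emulates the *marginal*
modal structure only: torsions are drawn independently, so correlations
between chain torsions present in real conformer sets are not reproduced,
and a green recovery test establishes sampling correctness, not physics.
Seeds are explicit and never touch the caller's RNG stream.

Posed assemblies are synthetic by construction and say so in their
provenance: `build_hbond_dimer()` relates two monomers by point inversion so
the reciprocal N1-H...O6 contacts both take the requested distance exactly,
and `pose_h5p_contact()` drives one torsion to realize an H5' contact
distance as closely as the idealized chain allows.

## Known limitations

* Quantum-chemical quantities are inputs; nothing here validates them.
* The template is idealized; descriptor values that depend on bond lengths
  and angles (R, beta, Phi) differ from relaxed geometries by construction.
* The phi2 bin criterion is red against the published counts, for the
  documented source-internal reason.
* PDB support is a minimal read-only ATOM/HETATM subset with prime
  normalization, sufficient for small-molecule crystal files only.
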