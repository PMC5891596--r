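---
title: "Additive and subtractive QM/MM coupling with hydrogen link atoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive and subtractive QM/MM coupling with hydrogen link atoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmlink)
```

## The problem

Hybrid QM/MM calculations treat a chemically interesting region (system 1)
with a quantum-mechanical method and the surrounding macromolecule and
solvent (system 2) with a classical force field.  Two assembly styles exist
for the total energy.  The *subtractive* scheme runs one QM calculation and
two MM calculations,

$$E^{\mathrm{sub}} = E_{\mathrm{QM1}} + E_{\mathrm{MM12}} - E_{\mathrm{MM1}},$$

so that every MM term inside the QM region appears once in
$E_{\mathrm{MM12}}$ and once, with opposite sign, in $E_{\mathrm{MM1}}$.
The *additive* scheme runs the same QM calculation and a single,
cherry-picked MM term,

$$E^{\mathrm{add}} = E_{\mathrm{QM1}} + E_{\mathrm{MM2-1}},$$

whose content is chosen so that nothing is double-counted.  When a covalent
bond crosses the boundary, the QM fragment is capped by a hydrogen link atom
(HL) standing in for the real boundary atom (CL, typically carbon); HL and
CL are two representations of the same atom and never appear in the same
calculation.  The interesting questions are (i) under what bookkeeping the
two assemblies are *identical*, and (ii) how the duplicated MM terms of the
subtractive scheme can be made deliberately different so that they *correct*
the truncation error of the link atoms — the van der Waals (VLAC),
electrostatic (ELAC) and bonded (BLAC) link-atom corrections.

`qmmlink` implements all of these side by side over one MM engine, so the
claimed identities and differences are machine-checkable, and ships an
MM-surrogate QM backend so no electronic-structure program is needed to
exercise any code path.

## Link-atom geometry and forces

The HL atom is placed on the Q1→CL ray at a scaled distance,

$$r_{\mathrm{Q1-HL}} = r_{\mathrm{Q1-CL}}\,
  \frac{r^0_{\mathrm{Q1-HL}}}{r^0_{\mathrm{Q1-CL}}},$$

where $r^0_{\mathrm{Q1-CL}}$ is the force-field equilibrium bond length and
$r^0_{\mathrm{Q1-HL}}$ is a user input, obtained once from a QM optimization
of the isolated truncated fragment.  The ratio
$g = r^0_{\mathrm{HL}}/r^0_{\mathrm{CL}}$ is treated as a
geometry-independent constant, so the HL introduces no degrees of freedom
and forces on it map back by a fixed linear chain rule:
$\partial E/\partial\mathrm{CL} \mathrel{+}= g\,\partial E/\partial\mathrm{HL}$,
$\partial E/\partial\mathrm{Q1} \mathrel{+}= (1-g)\,\partial E/\partial\mathrm{HL}$.

With the harmonic bond form $E = k\,(r - r^0)^2$, the Q1–HL force constant is
not free.  Requiring the HL-side bond energy at the mapped HL position to
equal the CL-side bond energy for *every* Q1–CL distance forces

$$k_{\mathrm{Q1-HL}} = k_{\mathrm{Q1-CL}}
  \left(\frac{r^0_{\mathrm{Q1-CL}}}{r^0_{\mathrm{Q1-HL}}}\right)^{2},$$

i.e. the force constant *increases* when the bond shortens.  The ratio is
sometimes printed the other way around in the literature; the orientation
used here is the one the energy identity itself forces, and the test suite
contains a grid oracle (50 Q1–CL distances) plus a negative control showing
that the inverted ratio breaks the identity off-equilibrium.

Because the HL sits exactly on the Q1–CL ray, any angle Q2–Q1–HL equals the
angle Q2–Q1–CL, and any torsion ending in HL equals the one ending in CL.
Copying the CL-side angle/dihedral parameters onto the HL-side terms of the
truncated topology therefore makes those terms cancel *exactly* between
$E_{\mathrm{MM12}}$ and $E_{\mathrm{MM1}}$ — this is what lets the
subtractive scheme run with dummy parameters for the QM region.

## Term selection and the scheme family

`mm_energy()` evaluates the AMBER-form potential (harmonic bonds and angles
without the 1/2 factor, Fourier dihedrals, 12-6 Lennard-Jones in the
Rmin/epsilon parametrization with Lorentz–Berthelot combination, Coulomb
with $332.0522$ kcal·Å/(mol·e²), no nonbonded cutoff, 1-2/1-3 exclusions and
1-4 divisors 1.2/2.0 by default) under a per-term *filter* over the QM/MM
region labels of the term's atoms, CL counting as QM.  The additive MM term
is the filter: bonded terms with at least one MM atom; MM–MM
electrostatics; van der Waals unless both atoms are QM.  All additive MM
terms use CL atoms, coordinates and parameters — never HL.

The assemblies provided by `qmmm_energy()`:

| scheme | embedding | content |
|---|---|---|
| `add` | electrostatic | $E_{\mathrm{QM1+ptch2}}^{HL} + E_{\mathrm{MM2-1}}^{CL}$ |
| `sub` | electrostatic | $E_{\mathrm{QM1+ptch2}}^{HL} + E_{\mathrm{MM12},q_1=0}^{CL} - E_{\mathrm{MM1},q_1=0}^{HL}$ (VLAC) |
| `sub-strict` | electrostatic | as `sub` but the small term on CL coordinates/parameters: identical to `add` |
| `me` | mechanical | $E_{\mathrm{QM1}}^{HL} + E_{\mathrm{MM12}}^{CL} - E_{\mathrm{MM1}}^{HL}$ with merged charges |
| `elac` | electrostatic | QM charges in both MM terms, the same point-charge model inside $E_{\mathrm{MM1}}$ |
| `blac` | electrostatic | `sub` with substituted HL-side (and optionally CL-side) bonded parameters |

In the electrostatic-embedding family the QM calculation is polarized by a
point-charge model containing *every* MM atom (never CL, which belongs to
the QM region) with unmodified charges — no deletion or redistribution near
the junction; the QM-region charges are zeroed in the MM terms to avoid
double counting.  QM–point-charge interactions are never 1-4 scaled or
excluded, even for charges bonded (in the full system) to CL: a real QM
program cannot scale them, and this reproduces the known embedding
asymmetry across the junction.  The point-charge self-energy is excluded
from the QM term by contract.

The van der Waals link-atom correction is the only difference between `sub`
and `add`: intra-QM van der Waals pairs involving a link atom are evaluated
once with CL parameters and coordinates (in $E_{\mathrm{MM12}}$) and once
with HL parameters and coordinates (in $E_{\mathrm{MM1}}$), and the two do
not cancel.  On a system whose only CL-involving intra-QM pair partner has
zero Lennard-Jones depth (the ethanol fixture's hydroxyl hydrogen), the
correction vanishes identically and `sub` equals `add` to machine
precision.

## Mechanical embedding and the charge merge

For mechanical embedding the QM-derived charges of the truncated fragment
(including one HL charge per junction) must be reconciled with the MM
charges of the full system.  `merge_charges_me()` implements the per-unit
procedure: QM atoms (except HL) take QM charges; MM atoms keep MM charges;
and in each biochemical unit containing CL atoms, a constant offset is
added to each CL atom's original MM charge so the unit total returns to its
original integer value (plus any declared integer external to the QM
system).  When a unit holds several CL atoms the residual is split equally
among them — the procedure's description does not resolve the multiplicity,
so the equal split is this package's documented choice (an alternative
global division over all link atoms is *not* implemented).  Charge transfer
across the QM region is allowed: individual QM residues need not end at
integer charge, only units with CL atoms are re-closed, and the full-system
total is conserved to better than $10^{-10}$ e by construction.

On the ethanol fixture this reproduces the published worked example: with
methanol QM charges (C1 0.2120, H1 −0.0043, O −0.5903, HO 0.3977) and the
ethanol MM set, the merged CL charge is −0.1935 e:

```{r merge}
fx <- build_fixture("ethanol_methanol")
round(merge_charges_me(fx$mm_charges, fx$qm_charges,
                       fx$region_map, fx$units)$charges, 4)
```

## Truncated-topology generation

`build_truncated_topology()` regenerates, from the full topology alone, the
small-system topology: system-1 atoms with CL converted in place to HL
(mass 1.008, a hydrogen van der Waals type, per-mode charges); all bonded
terms wholly inside system 1 with the Q1–HL bond rescaled as above and
…–CL angle/dihedral parameters copied; exclusions and 1-4 lists rebuilt
from the truncated connectivity.  For covalently bonded CL pairs, the CL–CL
bond and every angle/dihedral whose bond path runs through it are removed —
otherwise spurious forces distort the optimization.  Such junctions are
flagged with a warning and are discouraged; note two consequences that the
test suite makes explicit:

* the removed cross-junction bonded terms survive once in
  $E_{\mathrm{MM12}}$, so on a bonded-CL system the subtractive-additive
  difference is the VLAC *plus* this bonded remainder (the enumeration
  oracle in the tests computes both pieces independently);
* after the removal the two capped fragments see each other as plain
  nonbonded neighbors in the small system, which is part of the same
  correction.

## The MM-surrogate QM backend

Every scheme talks to a backend object with one method: energy and gradient
of system 1 with HL atoms, optionally embedded in point charges, never
including the point-charge self-energy.  The default backend
(`surrogate_backend()`) is a stand-in theory whose physics is exactly the
MM force field of the truncated topology plus unscaled Coulomb coupling to
the point charges.  It makes the cancellation identities *exact* and
machine-checkable: for example, mechanical embedding with matched HL/CL
charges collapses term-by-term onto the plain full-system MM energy.  A
second backend (`fake_qm_backend()`) returns arbitrary smooth energies that
do not depend on any MM parameter; it is used wherever a claim concerns the
MM bookkeeping alone.  This distinction matters: with the surrogate, an
intra-QM MM parameter perturbation moves the "QM" energy too (a real QM
program would be blind to it), so the dummy-parameter invariance and the
BLAC substitution arithmetic are asserted under the parameter-independent
backend.  A file-exchange adapter (`file_exchange_backend()`) writes plain
`element x y z` and `x y z q` files and reads back an energy/gradient file,
so a real QM program can be attached through a small shell wrapper.

## Fixtures: what they emulate, and what they do not

The three built-in systems are generated from code plus an embedded,
versioned toy parameter set (`toyff-1`) with magnitudes typical of general
small-molecule force fields (C–C 310 kcal/mol/Å² at 1.526 Å, C–H 340 at
1.090, tetrahedral angle terms of 35–55 kcal/mol/rad², threefold torsions
of ~0.16 kcal/mol, standard Lennard-Jones wells).  Geometries are built
from internal coordinates near, but not at, equilibrium:

* `ethanol_methanol` — one junction (Q1 = C1, CL = C2), published MM and
  QM-derived charge columns attached, HL charge −0.0108 e;
* `propane_two_junctions` — two junctions whose CL atoms share one
  biochemical unit (exercises the equal-split charge offset);
* `butane_bonded_cl` — two covalently bonded CL atoms (exercises
  cross-junction term removal), structurally analogous to a dithiolene
  ligand truncated out of a larger ring system.

The hydroxyl hydrogen carries zero Lennard-Jones depth, as in the common
biomolecular force fields; this is what makes the subtractive and additive
totals coincide exactly on ethanol.

What passing tests show is that the *coupling algebra* — term selection,
link mapping, charge bookkeeping, gradients — is correct.  The fixtures do
not emulate real electronic structure, protein-scale electrostatics,
conformational diversity, or force-field accuracy, so no conclusion about
the *chemical* quality of any correction level follows from them.
Reproducing published ethanol-scale numbers requires attaching a real DFT
backend through the file-exchange adapter and generating real
general-force-field parameters; that reproduction profile is documentation
only and deliberately outside the test suite.

## Numerical choices

* Internal units: Å, kcal/mol, electron charges, radians; kJ/mol only at
  reporting (×4.184).  Atom indices are 1-based throughout (the natural R
  convention, shared by the field's R packages); prmtop pointer encodings
  are converted at the I/O boundary.
* Coulomb constant 332.0522 kcal·Å/(mol·e²); prmtop charges are stored
  ×18.2223 and normalized on read (testers must not scale twice).
* Angle gradients guard the near-linear case with a sine floor of
  $10^{-12}$; dihedrals use the signed atan2 torsion.
* 1-4 pairs across a junction follow the *full* system's connectivity in
  full-system evaluations and the *truncated* system's connectivity in
  truncated evaluations — exactly what makes the VLAC well defined.
* The minimizer is deterministic L-BFGS-B over the free atoms with the MM
  region frozen bitwise; default convergence thresholds are
  $4.5\times10^{-4}$ (max gradient component) and $3.0\times10^{-4}$ (RMS),
  kcal/mol/Å.  Harmonic distance restraints $k\,(r - r_\mathrm{target})^2$
  support scans.
* RMSD: frozen-environment comparisons share a frame and use no
  superposition; isolated-molecule comparisons superpose first (Kabsch via
  SVD).  Both modes are exposed because published comparisons do not always
  state which was used.  Internal-coordinate MADs wrap dihedral differences
  to (−180°, 180°].
* Problem sizes in the test suite: 9–14-atom fixtures, 100 randomized
  geometries for the equivalence property, 50-point distance grids, and
  finite-difference gradient checks (step $10^{-5}$ Å, tolerance $10^{-6}$
  kcal/mol/Å) over every scheme — sizes chosen so the full suite settles in
  well under a minute while every code path is exercised.

## Known limitations

* No periodic boundaries, Ewald/PME, cutoffs, or implicit solvent — the
  evaluator is deliberately cutoff-free.
* No polarized embedding and no iterative charge-update mechanical
  embedding.
* ELAC's QM–point-charge terms inside $E_{\mathrm{MM1}}$ are unscaled by
  choice (mirroring the QM calculation); whether they should mimic the full
  system's exclusions is genuinely open, and the choice is recorded here
  rather than asserted as established practice.
* BLAC substitutes supplied parameter tables; deriving them (e.g. from QM
  Hessians) is out of scope — the correction consumes alternate parameter
  sets, it does not fit them.
* CMAP and extra-point prmtop sections are rejected rather than modeled.
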