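# qmmlink

Additive and subtractive QM/MM coupling with hydrogen link atoms, in R.

QM/MM calculations treat a small reactive region (system 1) quantum
mechanically and the rest of a macromolecule (system 2) with a classical
force field.  Two energy assemblies dominate the field.  The subtractive
scheme combines three calculations,

    E_sub = E_QM1(HL) + E_MM12(CL) - E_MM1(HL),

while the additive scheme cherry-picks a single MM term,

    E_add = E_QM1(HL) + E_MM2-1(CL),

with hydrogen link atoms (HL) capping the covalent bonds cut at the
boundary in the QM calculation and the real boundary atoms (CL) retained in
the MM terms.  Properly set up — HL placed at
`r_Q1-HL = r_Q1-CL * r0_HL / r0_CL`, the link-bond force constant rescaled
as `k_HL = k_CL (r0_CL / r0_HL)^2`, CL-side angle/dihedral parameters
copied onto the HL side — the two schemes are *identical*; the subtractive
scheme additionally allows the duplicated intra-QM terms to be made
deliberately different, yielding the van der Waals (VLAC), electrostatic
(ELAC) and bonded (BLAC) link-atom corrections.

`qmmlink` is a self-contained laboratory for this coupling algebra, aimed
at QM/MM method developers and at anyone who needs to audit exactly what a
coupling implementation sums:

* an AMBER-dialect MM engine (no cutoffs, analytic gradients, per-term
  region filters) with prmtop and native plain-text topology I/O;
* automatic truncated-topology generation for the QM fragment, including
  the covalently-bonded-CL complication (cross-junction term removal);
* electrostatic and mechanical embedding, with the per-unit QM/MM charge
  merging procedure for mechanical embedding;
* all six scheme variants (`add`, `sub`, `sub-strict`, `me`, `elac`,
  `blac`) over one backend interface, with an MM-surrogate QM backend so
  every identity is testable without an electronic-structure program, and a
  plain-text file-exchange adapter for attaching a real one;
* a frozen-environment minimizer with harmonic distance restraints, plus
  RMSD (optionally Kabsch-superposed) and internal-coordinate MAD metrics.

## Worked example

Ethanol with a methanol QM region, cut across the C1–C2 bond (C2 is the
link atom):

```r
library(qmmlink)

fx <- build_fixture("ethanol_methanol")
rep <- qmmm_energy(fx, scheme = "sub")
print(rep)
#> QM/MM energy [sub, electrostatic embedding, backend mm-surrogate]
#>   total: 0.258833 kcal/mol (1.082958 kJ/mol)
#>   qm           0.066601 kcal/mol
#>   mm12         0.258833 kcal/mol
#>   mm1         -0.066601 kcal/mol
```

The QM term (here the MM surrogate on the HL-capped methanol, embedded in
the three methyl point charges) and the small-system MM term cancel
exactly, a consequence of the scaled link-bond force constant and the
copied junction parameters — so on this system the subtractive total equals
the additive one:

```r
qmmm_energy(fx, scheme = "add")$total
#> [1] 0.2588332
```

Mechanical embedding needs QM-derived charges merged back into the full
system; the CL atom absorbs a constant offset so ethanol stays neutral:

```r
merged <- merge_charges_me(fx$mm_charges, fx$qm_charges, fx$region_map, fx$units)
round(merged$charges, 4)
#> [1]  0.3977 -0.5903  0.2120 -0.0043 -0.0043 -0.1935  0.0609  0.0609  0.0609
```

The merged C2 charge, −0.1935 e, is the original MM charge −0.2324 e plus
the +0.0389 e offset that restores neutrality.

Optimizing the QM region with the methyl group frozen:

```r
opt <- minimize(fx, scheme = "sub")
opt$energy
#> [1] 0.1794176
rmsd(fx$structure, opt$structure, atom_subset = 1:6)
#> [1] 0.03847332
mad_internal_coordinates(fx$structure, opt$structure, fx$topology)
#>     mad_bond    mad_angle mad_dihedral
#> 0.0014239... 0.4663...    0.3303...
```

A thin command-line interface over the same functions is installed at
`inst/cli/qmmlink.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","qmmlink.R",package="qmmlink"))')" \
    fixtures ethanol_methanol -o /tmp/eth
Rscript .../qmmlink.R energy -i /tmp/eth --scheme sub
```

## Documentation

The methods vignette (`vignettes/qmm-coupling-schemes.Rmd`) describes the
model, the term-selection rules, the charge procedures, the numerical
choices and the package's limitations; every exported function carries
roxygen documentation.
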