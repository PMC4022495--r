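---
title: "Comparative analysis of domain-swapped substrate-binding protein dimers"
author: "swapbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of domain-swapped substrate-binding protein dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapbp)
```

## The system and the questions

Periplasmic substrate-binding proteins (SBPs) of ABC import systems are
bilobed receptors that capture their ligand by the Venus fly-trap mechanism:
two lobes connected by a flexible crossover close around the substrate
through a large rigid-body rotation.  The arginine-binding protein of
*Thermotoga maritima* (TmArgBP) adds two unusual features to this canonical
picture: it is extraordinarily thermostable, and it dimerizes by
three-dimensional domain swapping of its C-terminal helix — each subunit's
last helix packs against the *other* subunit's main body, with a short
hinge peptide crossing between the chains.

`swapbp` implements, as reusable and tested R functions, the quantitative
analyses such a system calls for:

* rigid-body superposition (Kabsch) and RMSD between conformers;
* a two-stage fixed/moving-lobe fit that measures the closure angle of the
  fly-trap motion;
* Shrake–Rupley solvent-accessible surface area (SASA) and the buried area
  of the dimer interface;
* a census of salt bridges, hydrogen bonds and hydrophobic contacts, with
  each inter-chain contact assigned to Eisenberg's closed (C-) interface —
  swapped segment against partner main body — or open (O-) interface;
* backbone stereochemistry statistics: peptide planarity
  $\Delta\omega = \omega - 180^\circ$, the N–C$^\alpha$–C bond angle, and
  carbonyl pyramidalization $\vartheta_c$, each examined as a function of
  $\psi$;
* sequence-level thermostability metrics (charged/polar composition,
  theoretical mass, oligomer stoichiometry from light-scattering masses);
* the one-set-of-sites isothermal titration calorimetry (ITC) model, both
  as a forward simulator and as a least-squares fitter.

Everything runs on deterministic synthetic structures built by the package
itself, so the full pipeline is exercisable — and is tested — without any
deposited coordinates.  When PDB files are available, every function
accepts them through the same `read_pdb()` entry point.

## Closure analysis

Domains are supplied explicitly (the lobe ranges of an SBP are known from
its architecture), so no automatic domain detection is attempted.  Given
conformers A and B the closure is measured in two stages: B is superposed
on A over the *fixed* lobe; the residual rotation that then maps B's
*moving* lobe onto A's is reported as the closure, with its angle in
$[0, 180]^\circ$ and a right-handed unit axis.  The angle is
$\arccos((\mathrm{tr}\,R - 1)/2)$; near $0^\circ$ and $180^\circ$ the axis
is recovered from the symmetric part of $R$.  Both per-lobe residual RMSDs
are reported as diagnostics: a genuine hinge motion shows a near-zero
fixed-lobe residual and a large moving-lobe displacement.

Residues are paired across conformers by author number, so C-terminal
residues unmodelled in one form are dropped (with a count) rather than
misaligned.

```{r closure}
mono <- make_two_lobe_monomer(list(n_res_per_lobe = 30, linker_length = 5,
                                   helix_tail_length = 10, seed = 1))
closed <- apply_domain_rotation(mono$structure, mono$domains$lobe2,
                                axis = c(0.36, -0.48, 0.8), angle_deg = 84)
closure_analysis(mono$structure, closed, mono$domains$lobe1,
                 mono$domains$lobe2)
```

## Surface areas and the dimer interface

SASA uses the Shrake–Rupley construction with a *deterministic*
golden-spiral point set (default 960 points), probe radius 1.4 Å, and radii
C 1.70, N 1.55, O 1.52, S 1.80 Å (default 1.70 Å for anything else; all
overridable).  A point on the probe-expanded sphere of an atom counts as
exposed iff it lies outside every neighbour's expanded sphere.  The tests
pin this against three independent references: the analytic area of an
isolated sphere, the closed-form two-intersecting-spheres cap area, and a
latitude–longitude surface quadrature on small random toys.

The buried area of a complex is reported in the *total* convention,
$\mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB}$, because that is
how interface sizes of swapped dimers are usually quoted; the halved
per-interface value is emitted alongside, since tools differ and the two
conventions are a factor of two apart.  Waters are always excluded; bound
ligands are excluded from dimer-interface areas by default (an amino-acid
ligand sits in the intra-monomer cleft, not at the dimer interface).
Agreement with areas computed by other programs (different radii, different
point sets) should be expected only to a few percent.

## Contacts and the C/O-interface classification

Conventional geometric criteria, all configurable: salt bridge = basic
side-chain N (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 — His flagged, its
protonation unknown) within 4.0 Å of an acidic side-chain O; hydrogen bond
= N/O donor–acceptor pair at ≤ 3.5 Å with antecedent–donor–acceptor angle
≥ 120° computed from heavy atoms (pairs whose angle cannot be formed are
kept on distance and flagged); hydrophobic contact = side-chain carbons of
apolar residues at ≤ 4.5 Å.  Each residue pair is stored once per contact
class with its minimum atom–atom distance, in canonical chain/residue
order.

For a two-chain swapped dimer, an inter-chain contact is C-interface iff
one partner lies in the swapped segment and the other in the partner's main
body; every other inter-chain contact (body–body, hinge-mediated,
swap–swap) is O-interface, so the two classes partition the census.  A
loosely packed swapped dimer — the interesting phenotype here — shows all
or nearly all of its contacts at the C-interface.

## Backbone stereochemistry

Per residue *i*: $\phi$, $\psi$, and for the peptide *i*→*i*+1, $\omega$,
$\Delta\omega = \mathrm{wrap}(\omega - 180^\circ)$, and the carbonyl
pyramidalization $\vartheta_c = \mathrm{wrap}(\tau(O_i, C_i, N_{i+1},
C^\alpha_i) - 180^\circ)$ — an improper-torsion measure of the out-of-plane
bend at the carbonyl carbon.  Published definitions of $\vartheta_c$ differ
in handedness, so the sign is exposed (`theta_c_sign`).  The peptide's
$\Delta\omega$ and $\vartheta_c$ are paired with residue *i*'s $\psi$ in
the window statistics, matching how the $\psi$-dependence of these
quantities is normally plotted; the default windows are
$75^\circ < \psi < 105^\circ$ and $135^\circ < \psi < 165^\circ$.
Wrap convention: angles live in $(-180, 180]$, so $\omega = 181^\circ$ is
stored as $-179^\circ$ and $\Delta\omega = +1^\circ$.

Secondary structure is assigned from backbone hydrogen-bond patterns only
(O(i)···N(i+4) runs for H; two nearby cross-strand N···O bonds — a ladder —
for E), not from a DSSP energy model: the assignment only aggregates
geometry statistics, and a full energy model would add dependencies without
changing those aggregates.  Chain breaks (C$^\alpha$–C$^\alpha$ > 4.5 Å)
suppress all cross-gap quantities.

The synthetic helix and sheet fixtures are built with N–C$^\alpha$–C
angles of 111.2° and 108.9° — the helix/sheet averages typical of
atomic-resolution structures — so the qualitative ordering
mean(helix) > mean(sheet) is reproduced by construction and the window
machinery can be verified exactly.

## Synthetic structures

All fixtures are generated from internal coordinates by NeRF chain
extension with idealized bond lengths (N–C$^\alpha$ 1.458, C$^\alpha$–C
1.525, C–N 1.329 Å), which is what lets the stereochemistry tests demand
*exact* recovery of prescribed $\phi/\psi/\omega/\vartheta_c$.  Residues
are poly-Ala with C$^\beta$; there is no rotamer building, packing
optimization or energy model.

The bilobed monomer is two helical-hairpin lobes joined by an extended
linker, then a short extended hinge and a C-terminal helical tail
(`spec(30, 5, 10)` gives 75 residues: lobes 1–30 and 36–65, linker 31–35,
hinge 66–68, tail 69–75).  The swapped dimer places a second copy by an
*exact* 180° rotation about a two-fold axis; the axis position and an
orientation angle are found by a deterministic scan so that the closest
tail/partner-body approach sits at a contact distance (default 3.8 Å)
while body–body, tail–tail and hinge–anything separations stay above the
census cutoffs.  The construction therefore guarantees, rather than merely
tends towards, the two properties the tests assert: exact two-fold chain
equivalence, and inter-chain contacts confined to the C-interface.

What these fixtures deliberately do not emulate: real side chains (so the
synthetic contact census exercises the hydrophobic and backbone classes
only), crystallographic disorder, solvent, or realistic packing densities.
Passing tests on them validates the *measurement machinery* — superposition,
areas, censuses, geometry — not any claim about real proteins.

## The ITC model

For the one-set-of-sites model with parameters $(n, K_d, \Delta H,
q_\mathrm{offset})$, concentrations follow the perfusion-cell displacement
convention — after total injected volume $V$, cell species scale by
$e^{-V/V_0}$ and the ligand accumulates as $X_s(1 - e^{-V/V_0})$ (a linear
convention is available; at 36 µL into 280 µL the two differ by < 1%).
The bound fraction $\Theta$ solves the usual quadratic, and injection *i*
releases $q_i = n M_t(i)\,\Delta H\,V_0\,(\Theta_i - \Theta_{i-1}) +
q_\mathrm{offset}$: complexes carried out of the cell by the displaced
volume generate no heat.  The isotherm's molar-ratio axis is cumulative
*delivered* ligand over *initial* cell macromolecule moles (the default
design, 18 × 2 µL of 1.25 mM into 0.280 mL of 0.05 mM, ends at 45/14 ≈
3.21).

Fitting is nonlinear least squares over $(n, \log_{10} K_d, \Delta H,
q_\mathrm{offset})$ with $K_d \in [10^{-12}, 10^{-2}]$ M.  $K_d$ is fitted
in log space because at the design's Wiseman parameter ($c = n M_t / K_d
\approx 4 \times 10^4$) the isotherm is nearly a step function and the
likelihood is extremely flat in $K_d$; starting values come from a
deterministic grid over $(n, \log_{10} K_d)$ with the two linear
parameters profiled out, followed by a Levenberg–Marquardt polish.  Under
2% noise the Monte-Carlo spread of the recovered $K_d$ spans well over
half a decade while $n$ stays within a few percent — exactly the
information structure expected at high *c*: the titration pins the
stoichiometry and the enthalpy, not the affinity.  Flat isotherms (the
"wrong ligand" control) are flagged `no_binding` instead of being reported
as spuriously tight binders.

```{r itc}
des <- itc_design()
iso <- simulate_isotherm(des, one_site_params(n = 1, k_d = 1.3e-9,
                                              dh = -10))
fit_one_site(iso, des)
```

## Numerical choices and edge cases

* Superposition corrects reflections via the sign of the smallest singular
  value and refuses point sets of rank < 2, where the rotation is
  undefined.
* Altloc handling keeps blank and 'A' conformers; hydrogens are dropped on
  read; the first MODEL is used; author numbering is preserved verbatim.
* The dimer builder's placement scan relaxes its clearance margins once
  (staying above the census cutoffs) before giving up, and reports the
  chosen two-fold offset as an attribute.
* The sheet fixture optimizes the rigid placement of the second strand
  against an ideal hydrogen-bond registry from several deterministic
  starting points; the residual objective is stored as an attribute.
* Angle recovery in tests measures rotation differences through the
  Frobenius form $2\arcsin(\lVert R_1 R_2^\top - I\rVert_F / 2\sqrt{2})$,
  which is well conditioned near zero, rather than the trace/arccos form.

## Problem sizes

The shipped analyses and tests use 75-residue monomers (375–750 atoms per
chain incl. dimers), 960–4000 SASA points, 100-case superposition and
Monte-Carlo loops, and 18-injection titrations.  These sizes keep every
computation exact enough for the stated tolerances while the full suite
runs in minutes on one core; all of them scale with their inputs if larger
studies are needed.

## Known limitations

* The contact census has no $\pi$–$\pi$ or cation–$\pi$ geometry classes,
  and no explicit-hydrogen geometry.
* SASA numbers are algorithm- and radii-dependent; cross-program agreement
  beyond a few percent should not be expected.
* The secondary-structure assignment is intentionally minimal; it is not a
  DSSP replacement.
* The ITC module fits integrated heats; raw thermogram integration and
  baseline modelling are out of scope, as are multi-site and competitive
  models.
* The closure analysis requires domains to be supplied; it does not detect
  them.
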