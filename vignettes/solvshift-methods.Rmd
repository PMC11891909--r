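---
title: "Methods: shift-based conformer assignment under explicit solvation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shift-based conformer assignment under explicit solvation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvshift)
```

## The problem this package addresses

A flexible solute — think of a macrolide with a dozen rotatable bonds and
five hydroxyl groups — has several low-energy conformers that interconvert
fast on the NMR timescale. Quantum chemistry can compute, for each candidate
conformer under each solvation treatment, a set of isotropic shieldings and a
total energy. The experiment supplies one set of chemical shifts. Two
decision rules compete for "which conformer is in solution": pick the
conformer whose computed spectrum best matches the experimental one, or pick
the one with the lowest computed energy. `solvshift` implements both, plus
the statistics needed to say when the data cannot distinguish candidates at
all — and a simulation framework showing *why* the two rules behave so
differently once explicit solvent molecules enter the model.

## The agreement statistic

Per nucleus $i$, the deviation is $\Delta\delta_i = \delta_i -
\delta_i^{exp}$ with $\delta = \sigma_{ref} - \sigma$ referenced against TMS
computed at the same level. The statistic is the *mean-centered* RMSD,

$$\mathrm{RMSD} = \sqrt{\frac{1}{N}\sum_i
  \left(\Delta\delta_i - \overline{\Delta\delta}\right)^2},$$

the population standard deviation of the deviations (population, not sample:
$N$ is the number of nuclei scored, not one less). Centering removes any
uniform offset — an imperfect TMS reference shifts every deviation by the
same constant and should not penalize a conformer. The uncentered
$\sqrt{\tfrac1N\sum\Delta\delta_i^2}$ is exposed as `rmsd_raw()` because the
two differ exactly by the mean component
($\mathrm{raw}^2 = \mathrm{centered}^2 + \overline{\Delta\delta}^2$),
which makes the systematic-offset contribution auditable. Three class
selections mirror the standard reporting modes: all protons (`OH` + `CHn`),
non-exchangeable protons only (`CHn`, the honest choice when the experiment
was run in D₂O where hydroxyl signals exchange away), and carbons (`C`).
Exchangeable protons are therefore *flagged by class*, never dropped
silently; equivalent-nucleus averaging is driven by an explicit
`equiv_group` column rather than inferred from connectivity, so nothing is
averaged that the user did not declare equivalent.

## Discrimination windows

Computed shifts carry an intrinsic accuracy of roughly 0.1 ppm (¹H) and
1 ppm (¹³C) at routine DFT levels. `discriminate()` turns the difference of
two conformers' RMSDs into a verdict with those defaults: within the window
(boundary included) the conformers are *indistinguishable*; beyond it, the
sign names the preferred structure. The boundary convention matters for
reproducibility, so it is pinned by tests: $|\Delta| = w$ is
indistinguishable, the verdict regions partition the axis exactly at $\pm w$.

## Energy bookkeeping and its hazards

Relative energies are $(E - E_{ref}) \times 627.5095$ kcal/mol. Two design
choices guard against the classic mistakes of cluster thermochemistry:

- the solvation-model **variant is a closed enumeration** (`PCM-DisRepCav`,
  `PCM-default`, `SMD`, `vacuum`, `fragment-solute-only`), and
  `relative_energies()` refuses to difference across variants or input tags;
- the **reference conformer is mandatory** — published figures are
  inconsistent often enough about which structure defines zero that a silent
  default would be a trap.

Boltzmann weights use $w_j \propto \exp(-\Delta E_j / k_B T)$ with
$k_B = 1.987204\times10^{-3}$ kcal mol⁻¹ K⁻¹ and a default $T = 298.15$ K
(ambient convention; the temperature is a parameter everywhere it occurs).
Weights are computed after subtracting the minimum energy, making them
invariant to constant shifts by construction. `equal_weights()` provides the
deliberately agnostic limit used to probe what averaging does when
populations are unknown. `ensemble_average()` forms the per-label weighted
mean of computed spectra — the quantity actually comparable to an experiment
that averages over fast-interconverting conformers.

`strip_solvent()` returns the solute-only structure (coordinates bit-exact,
order preserved) for "fragment" single points that eliminate solvent–solvent
interaction energy from cluster totals. `cluster_concentration()` implements
the cube-volume estimate: the largest interatomic distance $L$ of the cluster
defines a cube of volume $(L\times10^{-10}\,\mathrm{m})^3$, and the molarity
is $n_{solute}/(N_A V)$. By default $L$ is measured over *all* atoms
including solvent (the cluster as optimized is the thing whose size is being
estimated); `solute_only = TRUE` restricts it. A 31 Å dimer cluster gives
$2.98\times10^{-26}$ m³ and 0.11 mol/L — the scale of a dilute NMR sample.

## Geometry

Hydrogen-bond tables are specification-driven: the user names
donor–H–acceptor triples and gets H···acceptor distances in input order.
A cutoff detector (`detect_hbonds()`, default 2.5 Å) exists for exploration,
but curated tables in the literature include contacts out to ~3.7 Å, so no
cutoff reproduces a published row selection and the explicit-spec path is
the supported one. Torsions use the standard IUPAC sign convention
(clockwise positive viewed from the second to the third atom), cross-checked
in the tests against an independent dihedral implementation (`bio3d`);
`torsion_deviation()` is the periodic distance on the circle, in
$[0, 180]$ degrees, because deviations from an X-ray reference are
sign-insensitive. Collinear central atoms make the dihedral undefined and
raise an error rather than returning a garbage angle.

## The microsolvation builder

Manual placement of explicit solvent molecules ("chemical intuition") is
irreproducible by definition. `place_solvent()` replaces it with a seeded
surrogate — not a reconstruction of any particular published cluster:

1. donor sites are all O–H and N–H pairs with bond length < 1.2 Å, in atom
   index order;
2. sites are filled sequentially; the template's anchor atom (water O,
   DMSO O, chloroform H) is aimed along the X–H direction at a distance
   drawn uniformly from $d_0 \pm \Delta d$ (defaults 1.9 ± 0.3 Å, spanning
   typical H···acceptor contact ranges of 1.6–2.2 Å), with a random spin
   about that axis and a tilt of up to 20°;
3. molecules beyond the site count form a second shell near previously
   placed solvent (anchor-to-partner 2.7–3.3 Å, pointing away from the
   solute centroid);
4. a candidate pose is rejected if any intermolecular pair comes closer than
   `clash_factor` × (sum of Bondi vdW radii), default 0.8, and re-sampled up
   to `max_attempts` times; failure is an error naming the molecule and its
   tightest clash.

One subtlety is deliberate: the *designated hydrogen-bond contact of each
placed molecule is exempt from the clash rule*. A hydrogen bond is precisely
a contact shorter than the vdW sum — at the 1.9 Å target, H···O is well
inside 0.8 × (1.20 + 1.52) Å — so a scan that counted the intended contact
would reject every correct placement. The exempt pairs are recorded on the
output (`exempt_pairs` attribute, consumed by `clash_scan()` by default) and
in the per-molecule audit table, so the clash-freedom claim is checkable by
brute force at any time. Solute coordinates are never modified; identical
seed and inputs give bit-identical clusters, which is the property that
makes explicit-solvation protocols comparable across machines.

Rigid templates use textbook geometries (water 0.9572 Å / 104.52°;
chloroform tetrahedral, C–H 1.09 Å, C–Cl 1.76 Å; DMSO with S=O 1.50 Å,
S–C 1.80 Å and tetrahedral methyls). No optimization is attempted — clusters
are *inputs* for an external quantum-chemistry engine, and pre-optimizing
them would just move work that engine redoes anyway.

## The synthetic generator and what it does (not) show

`synthetic_spec()` describes a macrolide-like study: 4 conformers; 5
hydroxyl and 30 aliphatic protons plus 37 carbons; base shifts uniform in
1–6 / 0.5–5.5 / 10–180 ppm per class; conformer-to-conformer spread 0.5 /
0.3 / 2.0 ppm; experimental noise 0.05 / 0.05 / 0.5 ppm; per-solvation-level
solvent perturbations 0.5 / 0.1 / 0.3 ppm for OH / CHn / C — hydroxyl
protons move strongly with explicit solvent, aliphatic protons barely, and
carbons' 0.3 ppm is negligible against their 170 ppm scale; conformer energy
gaps of ~2 kcal/mol; and 20 kcal/mol of *input-tag-specific* solvent–solvent
energy noise at explicit-solvation levels, emulating how cluster total
energies depend on the arbitrary starting arrangement of solvent molecules.
These scales are order-of-magnitude choices exposed as parameters, not
claims about any specific molecule. All randomness flows from one seed
through separate derived substreams for shifts, experiment and energies —
so changing an energy dial provably cannot perturb the shift draws.

`recovery_experiment()` runs the two decision rules over replicates: shift
recovery is scored on the implicit-only (level 0) tables — the cleanest
test of the statistic itself — and energy recovery on the highest explicit
level, where the solvent–solvent noise lives, for each input tag. Under the
default conditions the shift rule recovers the true conformer essentially
always while the energy rule falls to the 1/4 chance level; with the noise
turned off both are perfect. That is the pipeline-level statement of why
shift-based assignment is trusted where cluster energies are not.

What passing these simulations does **not** show: the generator draws
independent Gaussian perturbations per nucleus, with no ring-current or
anisotropy structure, no correlated solvent effects between neighbouring
nuclei, no conformer-dependent linewidths, and uniform (not
Karplus-structured) base shifts. It validates the inference machinery, not
any shift-prediction physics.

## Numerical choices and problem sizes

- Population (divide by $N$) normalization throughout the RMSD statistic.
- Boltzmann weights computed after min-subtraction; weight sums are exact to
  1e-12 in the tests.
- Torsion boundary: results in $(-180, 180]$; $-180$ maps to $+180$.
- Shortest-contact ties break deterministically toward the lowest atom-index
  pair.
- Energies are hartree at the I/O boundary and kcal/mol internally
  (1 hartree = 627.5095 kcal/mol).
- Display rounding (2 ppm decimals, 1 kcal/mol decimal) happens only in
  `print()`; CSV/JSON outputs keep full precision.
- Test-suite problem sizes: 1000-vector oracle equivalence for the
  statistic, 100 rigid motions for geometry invariance, 20 seeds × 5
  waters for the placer, and 500-replicate recovery runs — sizes chosen so
  the whole suite completes in about a minute while keeping Monte-Carlo
  standard errors far from the asserted margins.

## Known limitations

- No DP4-style posterior probabilities and no regression scaling of computed
  shifts; the statistic is deliberately the plain centered RMSD.
- The placer produces chemically sensible *starting* clusters, not minima;
  strained solutes with buried donor sites can exhaust `max_attempts`.
- Atom-label ↔ index mapping between a numbering scheme and an XYZ file is
  the user's responsibility (`hbond_table()`/`torsion_table()` take indices).
- TMS reference shieldings are inputs: they depend on level of theory and
  solvent model and no table of them ships with the package.
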