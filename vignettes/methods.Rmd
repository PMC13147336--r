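---
title: "Methods: ensemble descriptors and spin-state analysis for helix-porphyrin-helix miniproteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble descriptors and spin-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimochrome)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the spirit of a methods section: what each
procedure assumes, which parameters matter, and what the synthetic-data
tests do and do not demonstrate about real data.

## The system

A mimochrome is a sandwich of two short helical peptides around a
deuteroporphyrin IX (DPIX): a proximal tetradecapeptide (chain "T" here)
whose His6 coordinates the metal through N-epsilon, and a distal
decapeptide (chain "D") that covers the opposite porphyrin face. The two
propionate groups of DPIX, at ring positions 2 and 18, each carry one
peptide chain; because the cofactor is asymmetric, swapping the chains
between the two propionates gives two regioisomers, and each chain can sit
above or below the ring plane, giving Delta/Lambda diastereomers. NMR
ensembles of such species are summarized by a small set of geometric
descriptors, and the Fe(III) electronic state is characterized by
zero-field Moessbauer parameters and EPR g-values.

## Geometric primitives

**Plane fits** are total least squares: the normal is the smallest
principal component of the centred points, with the rms out-of-plane
residual reported. Collinear input (second singular value numerically
zero) is a hard error, not a degenerate answer.

**Helix axes** use local helix centres rather than a PCA of the raw
C-alpha positions: within each window of four consecutive C-alphas, the
two interior angle bisectors point at the helix axis; intersecting
consecutive bisectors yields a local centre and radius, and a
total-least-squares line through all centres gives the axis. On an
8-12-residue helix a raw-coordinate PCA is biased by the helical winding
(the first PC follows the superhelical spread of the points), while the
bisector construction recovers the canonical rise of ~1.5 A per residue
within 0.06 A. The direction is oriented N- to C-terminus, and
`risePerResidue` is the mean step of the C-alpha projections onto the
axis. Collinear input degrades to a direct line fit.

**Superposition** is the closed-form SVD (Kabsch) solution restricted to
proper rotations. The test suite checks it against an independent
brute-force random-quaternion search and against `bio3d::fit.xyz`.
Ensemble RMSD follows the NMR-bundle convention: superpose on model 1,
form the mean structure, re-superpose on the mean, iterate to a mean
shift below 1e-4 A, then report mean +- sd of the per-model RMSDs. Whether
published bundle RMSDs were computed against a mean structure or pairwise
is often unstated; the two conventions differ by a factor near
sqrt(2n/(2n-2)), which the package's reported sd absorbs at n = 20.

**SASA** is Shrake-Rupley with quasi-uniform golden-spiral sphere points.
Defaults: probe 1.4 A (water), 960 points per atom (quadrature error
below 1 % on an isolated sphere, verified against the closed-form one-
and two-sphere areas), Bondi-type radii shipped as a documented table.
The porphyrin SASA descriptor sums the 24 macrocycle atoms plus the
metal, with the whole model as occluding context; published values for
real complexes depend on the (unpublished) radii set and atom list, so
comparisons should use the reported spread, not the point value.

## Ensemble descriptors

**Interhelical angle** is the angle between the two oriented axis
directions in [0, 180] degrees — deliberately not folded to [0, 90],
because near-antiparallel and near-perpendicular packings are distinct
conformations of the distal chain. Bundles are split into families by 1-D
single-linkage agglomeration: after sorting the per-model angles, the
bundle is split at the largest gap iff that gap exceeds `gapThreshold`
(default 20 degrees, chosen well above the within-family spread of
jittered ensembles and well below the ~30-degree separation of reported
conformational families). The larger family gets label 1; ties break
toward the lower mean.

**His orientation theta** is the signed acute angle, in the porphyrin
plane, from the N21-to-N23 reference axis to the projection of the
imidazole plane normal. Conventions, since a printed signed value is
meaningless without them:

* the porphyrin normal is oriented toward the His-bearing side, and the
  sign of theta follows the right-hand rule about that normal;
* theta is folded into (-90, 90] — plane normals have no intrinsic sign;
* the imidazole plane is fit to the five ring atoms plus any coplanar
  ring hydrogens present (they enlarge the ring's footprint and roughly
  halve the normal's sensitivity to coordinate noise);
* the reference axis is estimated from the centroids of the two opposite
  pyrrole rings containing N21 and N23 when all ten atoms are present —
  identical to the bare N21-to-N23 vector for an ideal macrocycle, but
  sqrt(5)-fold less sensitive to noise on any single atom — and falls
  back to the two nitrogens otherwise.

An imidazole within 10 degrees of coplanarity with the porphyrin has no
meaningful in-plane projection and raises an error. Theta flips sign
under reflection of the model (chirality sensitivity), which the tests
verify on mirrored generator output. This sign convention reproduces
opposite-signed orientations for the two regioisomer geometries.

**Rotamers** map chi1/chi2 to the nearest of +60 (p), 180 (t), -60 (m)
on the circle, concatenated — the letter scheme of the penultimate
rotamer library. **Ramachandran regions** come from a packaged 10x10
degree grid (simplified PROCHECK-style map: elliptical basins around the
alpha-R, beta and alpha-L centres with a hard steric exclusion band near
phi = 0); every cell maps to exactly one of four labels.

**Hydrogen bonds** use heavy-atom distance <= 3.5 A and D-H...A angle
>= 120 degrees. Missing amide hydrogens are built at 1.01 A along the
bisector of the two heavy-atom neighbours; rotatable hydroxyls (Ser/Thr/
Tyr) are scored at their optimal rotamer, i.e. the O-H (0.96 A) is
oriented at the candidate acceptor — a standard convention that avoids
inventing a hydroxyl torsion. Donors whose hydrogen cannot be built are
skipped with a warning rather than silently scored. Occupancy is the
fraction of models in which a donor/acceptor pair satisfies the
criteria; occupancies of different bonds are independent and not
normalized.

**Conformational shifts** are delta_obs - delta_rc against a packaged
Wishart-style random-coil table (supplemented with entries for Aib and
Dab); negative = upfield.

## NOE calibration and isomer assignment

Calibration uses the isolated spin-pair relation u = d_ref
(I_ref/I)^(1/6) with a single reference pair, clamped to [1.8, 7.0] A
(lower bound: van der Waals contact; upper: beyond NOE observability).
Class-specific reference pairs can be supplied where a CALIBA-style
per-class calibration is wanted; the published class constants for this
system are not available, so none are hardcoded. Sequence-separation
classes follow the standard convention (medium range = |i-j| in 2..4);
peptide-to-porphyrin contacts are inter-moiety and therefore counted as
long range, with a separate porphyrin-contact tally. Per-residue counts
are reported both rounded to the nearest integer and raw, since a
published "constraints per residue" figure may use either truncation or
a different residue count.

Regioisomer assignment is a pure rule table on the anchoring contact
pattern: the distal chain's position-9 side-chain amine proton contacts
the propionyl that carries the distal chain, so contacts to propionyl 2
imply the proximal chain sits on propionyl 18 (regioisomer 1) and vice
versa; contacts to both propionyls or to neither are explicit errors,
never a guess. Diastereomer assignment combines the proximal-chain
anchor position with which side of the ring (positions 3/5/7/8/10 vs
12/13/15/17) the Leu5 side chain contacts, given right-handed helices;
the two consistent combinations are Delta, the two mirrored ones Lambda,
and left-handed helices invert every call.

## Spin-state spectroscopy

The zero-field Moessbauer forward model is the standard thin-absorber
picture: each quadrupole doublet contributes two equal-depth Lorentzian
lines at delta +- DeltaEQ/2 with a shared FWHM Gamma, over a constant
baseline. Doublets are weighted by integrated-area fraction; because a
Lorentzian's area is depth x pi Gamma / 2, per-doublet depths are scaled
by areaFraction/Gamma so that `areaFraction` remains a true area fraction
even when linewidths differ between doublets (with a shared Gamma this
reduces to plain depth weighting). Fitting is Levenberg-Marquardt on
(delta, DeltaEQ, log Gamma, log weight) per doublet plus baseline, with
a seeded 20-start multistart when no initial values are given; fitted
fractions are renormalized, doublets are reported in ascending DeltaEQ,
and splittings closer than a linewidth raise an identifiability note.
Simulation-recovery at the conditions of interest (1 % noise, 512-point
grid) recovers delta to ~0.002 mm/s, DeltaEQ to ~0.007 mm/s and a 53:47
area ratio to well under one point.

Spin-state classification compares (delta, DeltaEQ) against literature
windows: five-coordinate high-spin ferric heme (DeltaEQ 0.4-1.0, delta
0.25-0.43 mm/s), six-coordinate high-spin (DeltaEQ 1.22-2.07, delta
0.32-0.45 mm/s), and a quantum-admixed-spin candidate window
(high-spin-like delta with DeltaEQ above 2.5 mm/s — a threshold placed
between the six-coordinate upper bound of 2.07 and the smallest
splittings reported for QS species, ~2.6; configurable). All matching
labels are returned with distances to the non-matching ranges; the
classifier never silently picks one of several matches.

The Maltempo relation a52 = (g_perp - 4)/2 estimates the S = 5/2 weight
of a quantum-admixed S = 3/2 / S = 5/2 state; g_perp is taken as the
arithmetic mean of the two perpendicular g-values when a full g-set is
given (the convention that reproduces the published worked example), and
values outside [3.5, 6.5] are rejected as physically implausible for the
treatment. No correction for the different spin-transition moments of
the two spin manifolds is applied: relative Moessbauer and EPR
intensities are reported raw.

## The synthetic generator: what it emulates, and what it does not

`assembleSandwich()` realizes a blueprint exactly in the jitter-free
structure: porphyrin in the z = 0 plane (idealized planar 24-atom
macrocycle, orthogonal N21-N23 / N22-N24 axes, methyls at positions
3/7/12/17, ring hydrogens at the deutero positions, propionyls with
methylene proton stubs at 2 and 18); the TD helix placed with His6
N-epsilon exactly 2.0 A from the metal and the imidazole rotated about
the bond axis until the measured theta equals the target (theta's
180-degree fold leaves two equivalent azimuths; the one whose C-terminal
end faces the distal chain's propionyl is chosen, mimicking the covalent
linker); the D helix placed at the exact target interhelical angle with
its backbone centre of mass at the target metal offset, spun about its
own axis and tilted toward the anchoring propionyl to shorten the
Dab9-propionyl linker while keeping all inter-moiety heavy-atom
distances above 2.4 A. Construction identities hold to <= 0.5 degrees
and <= 0.05 A and are asserted in tests. Side-chain rotamers of the
pocket residues and the His are fixed construction constants chosen once
for steric consistency.

Models are then jittered with i.i.d. isotropic N(0, 0.3^2 A^2)
per-coordinate noise (the default; configurable), seeded and
reproducible. This white-noise ensemble is deliberately simple: real NMR
bundles have correlated, restraint-shaped heterogeneity, real side
chains populate rotamer distributions, and protons are represented here
as single stubs on methyls and amines. Consequently (i) descriptor
recovery tests demonstrate estimator correctness and noise robustness,
not performance on restrained-MD ensembles; (ii) the porphyrin SASA of
synthetic sandwiches (~130 A^2) is far larger than in the tightly packed
real complexes, because stub side chains cover little surface — SASA
assertions therefore test the algorithm, not the biology; (iii) NOE peak
lists are complete and noise-controlled, unlike peak-picked spectra with
overlap. Analyses of deposited ensembles run through exactly the same
code path via `readEnsemble()`.

Descriptor estimates for jittered bundles are best computed on the
coordinate-mean structure (`ensembleMean()`): the generator's noise is
i.i.d. across models of an already-superposed bundle, so the per-atom
mean is the optimal data reduction, and at 0.3 A jitter with 20 models
the theta estimate lands within ~2 degrees of truth (at the information
limit set by the imidazole's small footprint), interhelical angles
within ~1 degree, and the metal offset within ~0.1 A — the tolerances
asserted over a 4 x 3 grid of blueprint angles and thetas in the test
suite.

## Problem sizes and determinism

The test suite runs entirely on synthetic data: 20-model ensembles of
the 14-mer/10-mer system (~300 atoms), 512-point spectra, 10-20 fits per
stochastic assertion, a 12-point blueprint recovery grid, and a 200,000-
sample quaternion-search oracle for superposition — about half a minute
in total. Every stochastic step takes an explicit integer seed; repeated
runs are bit-identical, and the acceptance script derives its 10
simulation seeds deterministically from a single `--seed`.

## Known limitations

* No mmCIF input; multi-model PDB only, with atom-identity consistency
  across models enforced (never repaired).
* The Ramachandran map is a simplified four-label region grid, not a
  PROCHECK stereochemical audit.
* Hydroxyl donors are scored at their optimal rotamer, which can
  overcount marginal O-H...A bonds with unfavourable real torsions.
* The single-reference NOE calibration ignores spin diffusion and
  mobility corrections (CALIBA's per-class curves can be emulated via
  `classReferences`).
* The Moessbauer model is zero-field, thin-absorber, Lorentzian;
  magnetic (applied-field) spectra and relaxation lineshapes are out of
  scope, as is full spin-Hamiltonian EPR simulation.
* Raw Moessbauer/EPR intensity fractions are reported without
  spin-transition-moment corrections.
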