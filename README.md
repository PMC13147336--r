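# mimochrome

Quantitative analysis of NMR structural ensembles of helix–porphyrin–helix
miniproteins (mimochromes) and of their Fe(III) spin-state spectroscopy.

Mimochromes are miniaturized synthetic heme proteins: two short helical
peptides — a proximal tetradecapeptide (TD chain) carrying the axial His and
a distal decapeptide (D chain) — covalently anchored through the two
propionate groups (ring positions 2 and 18) of an asymmetric
deuteroporphyrin IX (DPIX). The asymmetry of the cofactor produces
regioisomers (which propionate carries which chain) and Δ/Λ diastereomers
(which face of the porphyrin a chain covers). Characterizing these species
requires a pipeline of geometric ensemble descriptors, NOE-based isomer
assignment, and spin-state spectroscopy — the pieces this package
implements as reusable, tested functions for structural chemists working on
de novo heme proteins.

## What it computes

**Ensemble descriptors** (per model and aggregated over a 20-model NMR
bundle):

* interhelical angle between the TD and D helix axes — helix axes are fit
  by the 4-Cα bisector construction (local helix centres + total-least-
  squares line), which is unbiased on 8–12 residue helices where a plain
  PCA is distorted by the helical winding; bundles are split into
  conformational families by 1-D single-linkage clustering on the angle;
* the axial-His orientation angle θ: the signed acute angle between the
  porphyrin N21–N23 reference axis and the projection of the imidazole
  plane normal onto the porphyrin plane — the descriptor that
  distinguishes the two regioisomers' His orientations;
* metal-to-D-chain centre-of-mass distance (distal-site coverage);
* porphyrin solvent-accessible surface area (Shrake–Rupley, probe 1.4 Å,
  960 sphere points, Bondi-type radii);
* backbone φ/ψ statistics (circular means), simplified PROCHECK-style
  Ramachandran regions, χ1/χ2 rotamers in the penultimate-library letter
  scheme (p/t/m), hydrogen bonds with per-ensemble occupancy, and
  conformational shifts δ_obs − δ_rc against random-coil values.

**NOE restraints**: intensity → distance upper limits by the isolated
spin-pair calibration u = d_ref (I_ref / I)^(1/6), clamped to [1.8, 7.0] Å;
restraint bookkeeping by sequence-separation class (intraresidue /
sequential / medium / long, with peptide↔porphyrin contacts tallied
separately); rule-based regioisomer assignment from the Dab9 side-chain
amine contact pattern (contacts to propionyl 2 ⇒ regioisomer 1, TD anchored
at 18; contacts to propionyl 18 ⇒ regioisomer 2) and Δ/Λ diastereomer
assignment from Leu5 ring-side contacts plus helix handedness.

**Spin-state spectroscopy**: zero-field Mössbauer spectra as sums of
Lorentzian quadrupole doublets (two equal-depth lines at δ ± ΔE_Q/2,
shared Γ per doublet, constant baseline); multistart Levenberg–Marquardt
fitting with area-fraction normalization; spin-state classification from
(δ, ΔE_Q) against literature ranges for five-/six-coordinate high-spin
ferric heme and quantum-admixed-spin (QS) candidates; and the Maltempo
admixed-spin weight a²₅/₂ = (g⊥ − 4)/2 from EPR g-values, with
g⊥ = (g_x + g_y)/2.

**Synthetic data with ground truth**: `assembleSandwich()` builds 20-model
helix–DPIX–helix ensembles at a controllable interhelical angle, His θ,
anchoring topology and coordinate jitter (plus ideal helices, r⁻⁶ NOE peak
lists and noisy doublet spectra), so every analysis stage is testable
without downloading deposited structures.

## Worked example

```r
library(mimochrome)

bp  <- sandwichBlueprint(targetInterhelicalAngle = 21,
                         targetThetaHis = -33.4,
                         jitterSd = 0.3, nModels = 20, seed = 1)
ens <- assembleSandwich(bp)
aggregates(describeEnsemble(ens))
#>   family  n interhelical_mean interhelical_sd theta_mean theta_sd co_com_mean
#> 1      1 20                21            2.61      -32.4     5.23        7.69

maltempoFraction(gx = 5.92, gy = 3.56)$a52Squared
#> [1] 0.37

sp <- simulateMossbauer(
  data.frame(delta = c(0.42, 0.40), deltaEQ = c(1.47, 3.20),
             gamma = 0.30, areaFraction = c(0.53, 0.47)),
  noiseSd = 0.01, seed = 1)
fitMossbauer(sp, 2, seed = 1)
#> MossbauerFit: 2 doublet(s), residual sd 0.01011
#>    delta deltaEQ  gamma areaFraction
#> 1 0.4211   1.466 0.3024       0.5305
#> 2 0.3986   3.202 0.2958       0.4695
```

The descriptor aggregate recovers the generator's ground truth (one family
at 21° with the θ and metal-offset targets); the Maltempo worked example
gives the admixed S = 5/2 weight 0.37 from (g_x, g_y) = (5.92, 3.56); and
the two-doublet fit of a 1 %-noise spectrum recovers δ within ±0.003 mm/s,
ΔE_Q within ±0.005 mm/s and the 53:47 area ratio within half a point —
with `classifySpinState()` identifying the doublets as six-coordinate
high-spin and QS-candidate species.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mimochrome-cli` (subcommands: `descriptors`, `hbonds`,
`restraints`, `assign-isomer`, `moessbauer-fit`, `maltempo`, `simulate`).

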