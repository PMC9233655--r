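# sterolSweep

Membrane-aware cholesterol docking sweeps, and the mass-action equilibrium by
which cholesterol binding controls Scap–Insig dimer formation in the
endoplasmic reticulum membrane.

## The problem

Cellular cholesterol synthesis is governed by whether the Scap–SREBP complex
leaves the ER: when membrane cholesterol rises, Scap dimerizes with Insig,
the COPII-binding MELADL motif is occluded, and SREBP transcription factors
are never activated. The dimer interface carries a sterol-binding cleft, and
the question is whether binding at that single site can account for the
measured cholesterol dependence of SREBP processing.

Rigid-body docking can map cholesterol-binding sites on transmembrane (TM)
surfaces, provided the bilayer is represented: sterol hydroxyls hydrogen-bond
to the membrane interfaces rather than to the protein. `sterolSweep`
implements the full analysis pipeline around such docking sweeps, for
structural bioinformaticians working on sterol–membrane-protein recognition:

* **Structure preparation** — read OPM-oriented PDB files whose `DUM` dummy
  layers mark the two bilayer interfaces, convert the dummies to
  hydrogen-bond donor (NH3) pseudo-atom layers, strip heteroligands, and
  build two overlapping search boxes per membrane half.
* **Pose ingestion** — emit engine configurations for the TM scoring regime
  (hydrophobic/hydrogen-bond weights −0.001/−2.0) or the aqueous default
  regime (−0.0351/−0.587), parse multi-model PDBQT pose files into a
  studies × runs × boxes campaign, and remove duplicate poses from
  box-overlap regions.
* **Evidence-based pose selection** — keep only poses with ≥ 8 protein
  residues within 4 Å and a sterol ring long-axis tilt < 30° from the
  membrane normal (the geometry of crystallographically resolved interfacial
  cholesterol sites).
* **Threshold clustering and consensus** — one-pass leader clustering at
  rmsd < 4 Å with energy-best representatives; only clusters containing a
  member from each of five independent docking studies are accepted.
* **Thermodynamics** — the chain from a molar docking energy to a
  mole-fraction association constant:
  ΔG°(mf) = ΔG(dock) − 0.7, ΔG°(protein) = ΔG°(mf) − (−10.4), and
  K_a = exp(−ΔG°/RT) with RT = 0.5925 kcal/mol, where −10.4 kcal/mol is the
  multiplex interfacial hydrogen bond (60% stronger than the canonical
  −6.5 kcal/mol).
* **Dimer equilibrium** — mole-fraction mass action coupling S + I ⇌ SI to
  cholesterol binding at the interfacial site, solved by bisection; reports
  speciation, titration curves and the cholesterol level at which half the
  Scap is present as cholesterol-bound dimer.
* **Synthetic data** — an oriented poly-alanine helical-bundle generator and
  replicate docking campaigns with planted sites, criterion-violating decoys
  and box-overlap duplicates, so every stage is testable without a docking
  engine or downloads.

## Worked example

Binding parameters for the three interfacial sites from their docking
energies:

```r
library(sterolSweep)
bindingEnergyTable(c(dimer = -16.8, insig = -14.0, scap = -12.5))
#>    site dGdockMolar dGmoleFraction dGproteinOnly          Ka
#> 1 dimer       -16.8          -17.5          -7.1 160079.6460
#> 2 insig       -14.0          -14.7          -4.3   1418.8023
#> 3  scap       -12.5          -13.2          -2.8    112.8273
```

The dimer-site constant (1.6 × 10⁵ at 2 s.f.) half-saturates at 0.0006 mol%
cholesterol, and the corrected dimer energy is exactly the sum of the two
monomer contributions (`additivityGap` = 0). Coupling that constant to
Scap–Insig association (K_SI = 4) at realistic membrane abundances
(mole fractions 0.001) moves the midpoint of the *cholesterol-bound dimer*
response into the physiological range:

```r
halfMaximalCholesterol(equilibriumParameters())
#> [1] 5.601328   # mol%; falls as Insig is raised
```

A full sweep on a synthetic campaign with planted ground truth:

```r
b    <- makeMembraneBundle()                     # oriented 8-helix bundle
prep <- convertDummiesToDonorLayers(b)           # DUM -> NH3 donor layers
camp <- makeCampaign(b, campaignBlueprint(seed = 1))
cm   <- assembleCampaign(camp$manifest)
out  <- sweepCampaign(cm, prep)
out$consensus
#> ConsensusSet: 2 accepted, 1 rejected (>= 5 studies required)
print(out$table, digits = 3)
#>   id size   studies repEnergy      x      y     z accepted
#> 1  1    5 1,2,3,4,5     -15.1 -11.29   4.70  8.07     TRUE
#> 2  2    5 1,2,3,4,5     -14.7  11.32   4.79 -7.93     TRUE
#> 3  3    4   1,2,3,4     -13.8   4.66 -11.50 -7.94    FALSE
```

The two sites planted in all five studies are accepted at their planted
coordinates; the site present in only four studies is rejected by the
consensus rule, and every tilt and contact decoy was already removed by the
selection criteria.

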