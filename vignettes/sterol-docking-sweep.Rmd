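---
title: "Mapping membrane cholesterol sites and the sterol-controlled Scap-Insig dimer"
author: "sterolSweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping membrane cholesterol sites and the sterol-controlled Scap-Insig dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolSweep)
```

# The model in brief

Cholesterol-binding sites on the transmembrane (TM) surface of a membrane
protein are shallow, promiscuous hollows. Rigid-body docking can map them,
but only if two features of the membrane environment are represented: the
hydrophobic interior (through re-weighted scoring) and the two
polar/hydrophobic bilayer interfaces (through explicit hydrogen-bond donor
layers), because a bound sterol's hydroxyl hydrogen-bonds to an interface,
not to the protein. Raw docking output then has to be distilled: most poses
are background or false positives, and an evidence-based filter plus
replicate-consensus clustering keeps only poses that look like the
interfacial cholesterol sites resolved crystallographically.

`sterolSweep` implements that distillation pipeline, the conversion of
docking energies into mole-fraction binding constants, and a mass-action
model in which cholesterol binding at the Scap–Insig interfacial site
controls how much of the Scap in the ER membrane is sequestered as the
(SREBP-retaining) dimer.

# Structure preparation

An OPM-oriented structure has its membrane normal along +z and two planar
layers of `DUM` marker atoms at the interface planes. `readOpmPdb()`
identifies the layers and derives the frame; `deriveMembraneFrame()` places
each interface plane at the mean z of its layer, splitting the dummies by an
exact one-dimensional 2-means partition. Layers whose means are separated by
less than 5 Å are rejected as degenerate — real bilayers keep the two
interfaces well over 20 Å apart, so a smaller gap always indicates a broken
input. Every dummy must lie within 1.5 Å of its plane (OPM layers are flat;
the band only absorbs formatting noise).

```{r}
b <- makeMembraneBundle()      # synthetic oriented bundle (below)
deriveMembraneFrame(b)
```

`convertDummiesToDonorLayers()` replaces each marker *in place* by an
NH3-like donor group: the nitrogen takes the exact former dummy coordinate
and three hydrogens sit at 1.01 Å in a tetrahedral umbrella. The umbrella
axis points along the membrane normal away from the midplane, which keeps
the donatable hydrogens at the interface plane rather than buried in the
hydrophobic core. In-place replacement (rather than re-gridding) preserves
the lateral density the orientation database chose; nothing downstream
depends on donor spacing. Pseudo-atoms are flagged and excluded from all
protein-contact counting. Waters are treated as ligands: `stripHeteroligands()`
removes every HETATM residue except markers and pseudo-layers, and leaves
ATOM records untouched.

Search boxes: each membrane half (interface plane to midplane) is covered by
two boxes extended by a 3 Å margin on every face, split laterally at the
protein's x midline with a 25% overlap of the protein's x extent. The exact
dimensions are not critical — the contract is that the union covers every
protein atom of the half-slab and that the two boxes overlap, because
duplicate poses found in the overlap are removed downstream. Box
construction is deterministic and translation-equivariant.

# Docking regimes and pose ingestion

Two scoring regimes are emitted by `makeEngineConfig()`: the TM regime with
hydrophobic-effect and hydrogen-bond weights −0.001 and −2.0 (a hydrophobic
environment suppresses the hydrophobic effect and strengthens hydrogen
bonds), and the aqueous regime with the engine defaults −0.0351 and −0.587
for water-exposed domains. The weight directives are always written
explicitly so a configuration is self-describing. Engine invocation itself
sits outside the package: every downstream stage consumes multi-model pose
files, so the whole pipeline is testable at the desk.

`parsePoseFile()` reads `MODEL` blocks and takes each model's energy from
the first numeric field of its `REMARK VINA RESULT:` line (a
`REMARK  ENERGY` line is accepted as a fallback dialect).
`assembleCampaign()` indexes poses by (study, run, box); missing grid cells
are warnings, not errors, because individual engine runs can fail without
invalidating a campaign. Duplicate keys and out-of-range indices are errors.

`dedupeOverlapPoses()` removes box-overlap duplicates: within one
(study, run), poses from *different* boxes connected by pairwise rmsd below
1 Å form a duplicate group and only the most favourable-energy member
survives. The 1 Å default is deliberately far below the 4 Å clustering
threshold: overlap duplicates are the same placement found twice, not
neighbouring poses. Energy ties break by (study, run, box, model) order, so
the operation is deterministic and idempotent.

# Pose selection

A pose counts as a candidate interfacial site only if

* at least 8 protein residues have a heavy atom within 4 Å of a ligand
  heavy atom, and
* the sterol ring long axis tilts less than 30° from the membrane normal.

These thresholds describe the geometry of cholesterol molecules resolved on
TM surfaces in crystallographic and cryo-EM studies; for aqueous-regime
docking of extra-membranous domains they do not apply and the criteria are
disabled (`selectionCriteria(enabled = FALSE)`).

The ring long axis is operationalized as the first principal component of
the centered coordinates of the 17 fused-ring carbons, with the acute angle
taken via the absolute cosine; collinear ring atoms are an error, not a 0°
tilt. Contacts use heavy atoms only, a residue counts once however many
atom pairs qualify, and interface pseudo-atoms never count. The membrane
half of a pose is assigned from its ring-centroid z against the midplane —
hydroxyl-based assignment would misclassify tail-down decoys. The recorded
`hydroxylDepth` (signed distance of the hydroxyl oxygen from the nearest
interface plane, positive toward the midplane) is a geometric proxy for
interfacial hydrogen bonding; explicit donor-acceptor detection is out of
scope.

`matchToResolved()` declares a resolved sterol matched when some pose's
ring centroid lies within 3 Å of the resolved ring centroid. No standard
numeric criterion exists for "matched" in the literature this package
serves; 3 Å is of the order of one ring radius, is configurable, and is
reported with every match table.

# Clustering and consensus

"Simple threshold clustering" is realized as the leader variant: poses are
sorted by ascending energy (ties broken by study, run, box, model), each
pose joins the first cluster whose *representative* is within 4 Å rmsd,
otherwise it seeds a new cluster. Seeding by best energy makes the
representative rule — the energetically most favourable member represents
the cluster — consistent with membership, and guarantees every member lies
within the cutoff of its representative. Rmsd is computed over name-matched
heavy atoms in the common receptor frame *without* superposition;
superposing would erase the spatial distinctness of sites.

Stochastic docking engines do not find every site in every run, so
reproducibility comes from replication: five independent studies are pooled
and `consensusFilter()` accepts only clusters containing a member from each
study. The pipeline applies per-study selection, pooled clustering, then
consensus; `sweepCampaign(withinStudyPrecluster = TRUE)` instead
pre-clusters within each study and pools only representatives, for users
who prefer the two-stage reading of the protocol. On the synthetic
campaigns below the two orderings accept identical site sets.

# From docking energies to binding constants

Membrane solute concentrations belong on the mole-fraction scale. The chain
implemented by `energyRecord()` is, for a site with molar-scale docking
energy ΔG:

1. ΔG°(mf) = ΔG + (−0.7) kcal/mol. The molar to mole-fraction
   standard-state shift is implemented as a configurable additive constant
   because it is uniform across sites; its closed-form derivation lives in
   the standard-state literature and is not re-derived here.
2. ΔG°(protein) = ΔG°(mf) − (−10.4) kcal/mol. Docking against bare
   interface donor layers counts the sterol-interface *multiplex* hydrogen
   bond (one acceptor engaging several donors, 60% stronger than the
   canonical −6.5 kcal/mol bond: 1.6 × (−6.5) = −10.4). Since a cholesterol
   in the bilayer is interface-bonded whether or not it occupies the
   protein site, that term must be removed to get the protein-only binding
   energy.
3. K_a = exp(−ΔG°(protein)/RT) with RT = 0.5925 kcal/mol (298.15 K). This
   temperature is the unique choice that reconciles every published
   (ΔG°, K_a) pair at two significant figures; it is exposed as a
   parameter.

```{r}
bindingEnergyTable(c(dimer = -16.8, insig = -14.0, scap = -12.5))
```

Derived conveniences: single-site occupancy `occupancy(Ka, mol%)`,
half-occupancy level `100/Ka` mol%, the additivity gap between the dimer
site and the sum of the monomer sites, and the TM-over-luminal domain
preference (luminal mean minus TM mean of docking energies).

# The dimer equilibrium

The speciation model couples dimerization and sterol binding in
mole-fraction units:

* S + I ⇌ SI, with K_SI (default 4),
* SI + n·chol ⇌ SI·chol_n, with the dimer-site constant K_a
  (default 1.6 × 10⁵) governing the cholesterol dependence,
* optionally I + chol ⇌ I·chol with the Insig-monomer constant (1.4 × 10³)
  as an explicit species for pathway analyses.

`speciate()` eliminates free Insig through its conservation relation and
finds free Scap by monotone bisection (the conservation residual is
strictly increasing in free Scap, so bisection is guaranteed to bracket;
Newton iterations would be faster but can escape the physical domain).
Conservation and every mass-action relation hold to better than 1e-10
relative. `halfMaximalCholesterol()` then bisects the cholesterol mole
fraction, to 1e-10, for a cholesterol-bound-dimer fraction of one half —
the fraction of total Scap present as SI·chol_n, which under equal totals
equals the fraction of all Scap and Insig molecules so sequestered. An
equilibrium that saturates below one half (as happens when the
Insig-monomer sink is enabled) is reported as an error rather than clipped.

## Why the bound dimer carries two cholesterol molecules by default

The stoichiometry n is configurable (`nCholDimer`), and the default is 2.
This is a deliberate model-structure choice, made on three grounds:

1. With n = 1 and the constants above, half the Scap is cholesterol-bound
   dimer already at ~0.31 mol% cholesterol — an order of magnitude below
   the ~5.5 mol% midpoint measured for the sterol response of SREBP
   processing in cell-biological work. With n = 2 the model's midpoint is
   5.6 mol% at the same constants.
2. The K_SI that reproduces a 5.6 → 5.5 mol% midpoint exactly under n = 2
   is 4.13, i.e. the published association constant of 4 at one significant
   figure; under n = 1 it would have to be 0.23, which rounds to no
   published value.
3. Doubling the Insig total under n = 2 moves the midpoint to 3.1–3.2 mol%,
   matching the reported behaviour of the system when Insig is
   over-expressed; under n = 1 the shift is three-fold, not the observed
   ~1.8-fold.

Structurally, the interfacial cleft between Scap and Insig spans the
membrane from one leaflet to the other, and docking places sterol poses on
both its luminal and cytosolic aspects, so a doubly-occupied cleft in the
fully cholesterol-loaded dimer is geometrically reasonable. The
single-sterol variant remains available (`nCholDimer = 1`), and the test
suite pins the scaling law of each variant (midpoint ∝ K_a^{-1/n} in the
K_a·x ≫ 1 regime) so the choice is explicit rather than silent.

```{r}
halfMaximalCholesterol(equilibriumParameters())
head(titrationCurve(equilibriumParameters(), c(0, 0.01, 0.05, 0.056, 0.1)))
```

# Synthetic campaigns and what they do (not) show

`makeMembraneBundle()` builds a deterministic, OPM-dialect test structure:
poly-alanine Cα-trace helices (1.5 Å rise, 100° twist per residue, 2.3 Å
helix radius) on a circle, spanning the slab, flanked by two square DUM
grids. A Cα trace provides enough heavy atoms for contact counting without
modelling side chains. `makeCampaign()` plants upright, well-contacted,
favourable-energy poses in the surface hollows between adjacent helices
(energies from Normal(−14.2, 1.1) truncated to [−18, −10], the observed
spread of selected TM cholesterol poses), decoys that violate exactly one
criterion each (55° tilt with ample contacts; upright but well off the
protein surface), duplicated poses in box-overlap regions, and sites
present in only a subset of studies. A single seeded RNG stream drives each
campaign, so file sets are byte-reproducible.

The generator emulates the *bookkeeping* structure of a replicate docking
campaign — geometry, indexing, energies as labels — not docking physics:
energies are draws, not force-field scores; poses have no torsional
freedom; the receptor has no side chains or surface relief beyond the
inter-helix grooves. Passing tests therefore demonstrate that the
selection, deduplication, clustering, consensus and bookkeeping logic is
correct, not that any particular real structure harbours a site.

Problem sizes in the shipped tests: campaigns of ~20–40 poses on a
176-residue bundle, twenty seeded campaigns for the end-to-end
truth-recovery property, one hundred random parameter draws for the
speciation-versus-grid-search comparison. These sizes keep the full suite
around ten seconds while exercising every code path; all generators scale
to larger settings through their parameters.

# Numerical and degenerate-input conventions

* Coordinates are Å throughout, in the OPM frame (+z cytosolic); residue
  numbering is 1-based as in the source PDB.
* Energy ties anywhere (dedup, cluster seeding) break by
  (study, run, box, model) lexicographic order.
* A single-pose energy summary reports sd = 0 with an explicit flag rather
  than NA, so downstream tables stay numeric.
* Collinear ring atoms, empty resolved-ligand sets, zero association
  constants, unbalanced MODEL blocks, missing energy remarks and
  out-of-slab planted sites are errors with specific messages.
* Association constants are kept at full precision internally and shown at
  two significant figures, matching conventional reporting.

# Known limitations

* No protonation assignment, rotamer repair or membrane-thickness
  prediction: inputs are expected to be prepared, oriented structures.
* Hydrogen bonds between ligand and donor layers are not detected
  explicitly; `hydroxylDepth` is the recorded proxy.
* The docking engine itself (scoring, search, ligand torsion trees) is out
  of scope; the package consumes its pose files.
* The equilibrium model is mass action in a well-mixed membrane; COPII
  packaging cooperativity and vesicle-level effects are not modelled.
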