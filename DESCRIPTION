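Package: sterolSweep
Title: Membrane-Aware Cholesterol Docking Sweeps and the Sterol-Controlled
    Scap-Insig Dimer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping cholesterol-binding sites on membrane proteins
    from rigid-body docking sweeps performed inside an explicit bilayer frame.
    Reads OPM-oriented structures with dummy-atom interface layers, converts
    the layers to hydrogen-bond donor pseudo-atoms, builds half-membrane
    search boxes, parses multi-model docking pose files, applies evidence-based
    pose selection (contact count and ring-axis tilt), performs threshold
    clustering with cross-study consensus filtering, converts docking energies
    to mole-fraction binding constants with an interfacial hydrogen-bond
    correction, and solves the mass-action equilibrium by which cholesterol
    binding at the Scap-Insig dimer interface controls dimer formation in the
    endoplasmic reticulum membrane. Includes a synthetic-data generator that
    builds oriented helical-bundle fixtures and replicate docking campaigns
    with planted ground truth.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'docking.R'
    'selection.R'
    'clustering.R'
    'equilibrium.R'
    'pipeline.R'
    'show-methods.R'
    'sterolSweep-package.R'
    'structure-io.R'
    'synthetic.R'
    'thermo.R'
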