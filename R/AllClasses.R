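#' @import methods
NULL

## Atom table columns shared by OrientedStructure and the PDB writer.
.ATOM_COLS <- c("serial", "name", "element", "resname", "resno", "chain",
                "x", "y", "z", "kind", "pseudo")

#' Membrane frame defined by the two bilayer interface planes
#'
#' After OPM-style orientation the membrane normal is the +z axis and the two
#' polar/hydrophobic interfaces are planes of constant z. By the convention
#' used throughout this package the cytosolic interface is the upper (+z)
#' plane and the luminal interface the lower one.
#'
#' @slot normal unit vector along the membrane normal (dimensionless).
#' @slot zUpper z of the cytosolic-side interface plane (Angstrom).
#' @slot zLower z of the luminal-side interface plane (Angstrom).
#' @slot thickness hydrophobic slab thickness, \code{zUpper - zLower} (Angstrom).
#' @slot midplane \code{(zUpper + zLower) / 2} (Angstrom).
#' @exportClass MembraneFrame
setClass("MembraneFrame",
  representation(normal = "numeric", zUpper = "numeric", zLower = "numeric",
                 thickness = "numeric", midplane = "numeric"))

setValidity("MembraneFrame", function(object) {
  msg <- character()
  if (length(object@normal) != 3L || !all(is.finite(object@normal)))
    msg <- c(msg, "normal must be a finite length-3 vector")
  else if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    msg <- c(msg, "normal must have unit length (tolerance 1e-9)")
  if (!(object@zUpper > object@zLower))
    msg <- c(msg, "zUpper must exceed zLower")
  if (abs(object@thickness - (object@zUpper - object@zLower)) > 1e-9 ||
      object@thickness <= 0)
    msg <- c(msg, "thickness must equal zUpper - zLower and be positive")
  if (abs(object@midplane - (object@zUpper + object@zLower) / 2) > 1e-9)
    msg <- c(msg, "midplane must equal (zUpper + zLower)/2")
  if (length(msg)) msg else TRUE
})

#' Construct a MembraneFrame from its two interface planes
#'
#' @param zUpper z of the cytosolic-side interface plane (Angstrom).
#' @param zLower z of the luminal-side interface plane (Angstrom).
#' @param normal membrane normal; defaults to +z, the OPM convention.
#' @return A [MembraneFrame-class] object.
#' @examples
#' membraneFrame(14.2, -14.2)
#' @export
membraneFrame <- function(zUpper, zLower, normal = c(0, 0, 1)) {
  new("MembraneFrame", normal = as.numeric(normal),
      zUpper = as.numeric(zUpper), zLower = as.numeric(zLower),
      thickness = as.numeric(zUpper - zLower),
      midplane = as.numeric((zUpper + zLower) / 2))
}

#' An OPM-oriented structure with interface marker layers
#'
#' Holds the atom table of an oriented membrane-protein structure together
#' with the indices of the DUM interface marker atoms and the membrane frame
#' they define. Interface pseudo-atoms created by
#' [convertDummiesToDonorLayers()] carry \code{pseudo = TRUE} in the atom
#' table and are excluded from protein-contact counting.
#'
#' @slot atoms data.frame with columns serial, name, element, resname, resno,
#'   chain, x, y, z, kind (\code{"ATOM"}/\code{"HETATM"}) and pseudo (logical).
#' @slot dummyIndices integer row indices of DUM marker atoms (empty after
#'   conversion to donor layers).
#' @slot frame the derived [MembraneFrame-class].
#' @slot layerTolerance tolerance band (Angstrom) within which every dummy
#'   atom must sit of its interface plane.
#' @exportClass OrientedStructure
setClass("OrientedStructure",
  representation(atoms = "data.frame", dummyIndices = "integer",
                 frame = "MembraneFrame", layerTolerance = "numeric"))

setValidity("OrientedStructure", function(object) {
  msg <- character()
  at <- object@atoms
  if (!all(.ATOM_COLS %in% names(at)))
    msg <- c(msg, paste("atom table must have columns:",
                        paste(.ATOM_COLS, collapse = ", ")))
  else {
    if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
      msg <- c(msg, "all coordinates must be finite")
    di <- object@dummyIndices
    if (length(di)) {
      if (any(di < 1L | di > nrow(at)))
        msg <- c(msg, "dummyIndices out of range")
      else {
        z <- at$z[di]
        tol <- object@layerTolerance
        inUpper <- abs(z - object@frame@zUpper) <= tol
        inLower <- abs(z - object@frame@zLower) <= tol
        if (!all(inUpper | inLower))
          msg <- c(msg, sprintf(
            "every dummy atom must lie within %.2f Angstrom of an interface plane",
            tol))
        if (!any(inUpper) || !any(inLower))
          msg <- c(msg, "dummy atoms must partition into two interface layers")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' A rectangular docking search box for one membrane half
#'
#' @slot center box center (x, y, z; Angstrom).
#' @slot size box edge lengths (sx, sy, sz; Angstrom), all positive.
#' @slot half \code{"cytosolic"} or \code{"luminal"}.
#' @slot index 1 or 2; each half is tiled by two laterally overlapping boxes.
#' @exportClass SearchBox
setClass("SearchBox",
  representation(center = "numeric", size = "numeric",
                 half = "character", index = "integer"))

setValidity("SearchBox", function(object) {
  msg <- character()
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    msg <- c(msg, "center must be a finite length-3 vector")
  if (length(object@size) != 3L || !all(object@size > 0))
    msg <- c(msg, "all box sizes must be positive")
  if (!object@half %in% c("cytosolic", "luminal"))
    msg <- c(msg, "half must be 'cytosolic' or 'luminal'")
  if (!object@index %in% c(1L, 2L))
    msg <- c(msg, "index must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Docking scoring regime (membrane-interior vs aqueous weights)
#'
#' The transmembrane regime re-weights the docking score for a hydrophobic
#' environment (hydrophobic-effect weight -0.001, hydrogen-bond weight -2.0);
#' the aqueous regime carries the engine's default weights (-0.0351, -0.587).
#'
#' @slot label \code{"TM"} or \code{"aqueous"}.
#' @slot weightHydrophobic hydrophobic-effect scoring weight (dimensionless).
#' @slot weightHydrogen hydrogen-bonding scoring weight (dimensionless).
#' @exportClass DockingRegime
setClass("DockingRegime",
  representation(label = "character", weightHydrophobic = "numeric",
                 weightHydrogen = "numeric"))

.REGIME_WEIGHTS <- list(TM = c(-0.001, -2.0), aqueous = c(-0.0351, -0.587))

setValidity("DockingRegime", function(object) {
  msg <- character()
  if (!object@label %in% names(.REGIME_WEIGHTS))
    msg <- c(msg, "label must be 'TM' or 'aqueous'")
  else {
    w <- .REGIME_WEIGHTS[[object@label]]
    if (object@weightHydrophobic != w[1] || object@weightHydrogen != w[2])
      msg <- c(msg, sprintf("%s regime requires weights (%g, %g)",
                            object@label, w[1], w[2]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DockingRegime
#'
#' @param label \code{"TM"} (membrane-interior weights) or \code{"aqueous"}
#'   (engine default weights).
#' @return A [DockingRegime-class] object.
#' @examples
#' dockingRegime("TM")
#' @export
dockingRegime <- function(label = c("TM", "aqueous")) {
  label <- match.arg(label)
  w <- .REGIME_WEIGHTS[[label]]
  new("DockingRegime", label = label,
      weightHydrophobic = w[1], weightHydrogen = w[2])
}

#' A rigid sterol docking pose
#'
#' One placement of a sterol ligand in the receptor frame, with its docking
#' energy and the (study, run, box, model) indices identifying where in a
#' replicate campaign it came from. The fused-ring atom subset used for tilt
#' and rmsd computations is identified by atom name (\code{ringNames}).
#'
#' @slot ligandName ligand identifier (e.g. \code{"CLR"} for cholesterol).
#' @slot atoms data.frame with columns name, element, x, y, z.
#' @slot energy docking energy, kcal/mol (molar standard state; more negative
#'   is more favourable).
#' @slot studyId,runId,modelId integer indices within the campaign.
#' @slot boxId search-box identifier (e.g. \code{"cytosolic-1"}).
#' @slot ringNames atom names forming the fused sterol ring system.
#' @exportClass Pose
setClass("Pose",
  representation(ligandName = "character", atoms = "data.frame",
                 energy = "numeric", studyId = "integer", runId = "integer",
                 boxId = "character", modelId = "integer",
                 ringNames = "character"))

setValidity("Pose", function(object) {
  msg <- character()
  need <- c("name", "element", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "pose atom table must have columns name, element, x, y, z")
  else {
    if (!all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
             is.finite(object@atoms$z)))
      msg <- c(msg, "pose coordinates must be finite")
    if (!any(object@atoms$name %in% object@ringNames))
      msg <- c(msg, "ring atom subset is empty")
  }
  if (!is.finite(object@energy))
    msg <- c(msg, "docking energy must be finite")
  if (length(msg)) msg else TRUE
})

## Default ring-atom names for the cholesterol-like templates used here:
## the 17 fused-ring carbons.
.RING_NAMES <- paste0("C", 1:17)

#' A replicate docking campaign (studies x runs x boxes)
#'
#' @slot poses list of [Pose-class] objects.
#' @slot regime the [DockingRegime-class] the poses were produced under.
#' @slot nStudies,nRuns declared campaign dimensions (defaults 5 and 5).
#' @slot boxIds the search-box identifiers the campaign covers.
#' @exportClass DockingCampaign
setClass("DockingCampaign",
  representation(poses = "list", regime = "DockingRegime",
                 nStudies = "integer", nRuns = "integer", boxIds = "character"))

setValidity("DockingCampaign", function(object) {
  msg <- character()
  for (p in object@poses) {
    if (!is(p, "Pose")) { msg <- c(msg, "poses must all be Pose objects"); break }
    if (p@studyId < 1L || p@studyId > object@nStudies) {
      msg <- c(msg, sprintf("study id %d outside 1..%d", p@studyId,
                            object@nStudies)); break
    }
    if (p@runId < 1L || p@runId > object@nRuns) {
      msg <- c(msg, sprintf("run id %d outside 1..%d", p@runId, object@nRuns))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pose-selection criteria for transmembrane cholesterol sites
#'
#' A docked pose is kept only if at least \code{minContacts} protein residues
#' lie within \code{contactCutoff} Angstrom of the ligand and the angle
#' between the sterol ring long axis and the membrane normal is below
#' \code{maxTilt} degrees. For aqueous-regime docking the criteria are
#' disabled (\code{enabled = FALSE}) and every pose passes.
#'
#' @slot minContacts minimum number of contact residues (default 8).
#' @slot contactCutoff contact distance cutoff in Angstrom (default 4).
#' @slot maxTilt maximum ring-axis tilt in degrees (default 30).
#' @slot enabled logical; \code{FALSE} disables filtering.
#' @exportClass SelectionCriteria
setClass("SelectionCriteria",
  representation(minContacts = "integer", contactCutoff = "numeric",
                 maxTilt = "numeric", enabled = "logical"))

setValidity("SelectionCriteria", function(object) {
  msg <- character()
  if (object@contactCutoff <= 0) msg <- c(msg, "contactCutoff must be positive")
  if (!(object@maxTilt > 0 && object@maxTilt <= 90))
    msg <- c(msg, "maxTilt must be in (0, 90]")
  if (object@minContacts < 1L) msg <- c(msg, "minContacts must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Construct SelectionCriteria
#'
#' @param minContacts minimum contact-residue count (default 8).
#' @param contactCutoff contact cutoff in Angstrom (default 4).
#' @param maxTilt maximum tilt from the membrane normal, degrees (default 30).
#' @param enabled set \code{FALSE} for aqueous-regime docking, where the
#'   interfacial-site criteria do not apply.
#' @return A [SelectionCriteria-class] object.
#' @examples
#' selectionCriteria()
#' selectionCriteria(enabled = FALSE)  # aqueous regime
#' @export
selectionCriteria <- function(minContacts = 8L, contactCutoff = 4,
                              maxTilt = 30, enabled = TRUE) {
  new("SelectionCriteria", minContacts = as.integer(minContacts),
      contactCutoff = as.numeric(contactCutoff), maxTilt = as.numeric(maxTilt),
      enabled = isTRUE(enabled))
}

#' A threshold cluster of docking poses
#'
#' @slot members list of [Pose-class] members.
#' @slot representative the energetically most favourable member.
#' @slot studiesPresent sorted integer ids of the studies contributing members.
#' @slot rmsdCutoff the clustering threshold the cluster was built with.
#' @exportClass PoseCluster
setClass("PoseCluster",
  representation(members = "list", representative = "Pose",
                 studiesPresent = "integer", rmsdCutoff = "numeric"))

setValidity("PoseCluster", function(object) {
  msg <- character()
  if (!length(object@members)) msg <- c(msg, "cluster has no members")
  else {
    e <- vapply(object@members, function(p) p@energy, numeric(1))
    if (object@representative@energy > min(e) + 1e-12)
      msg <- c(msg, "representative must have the minimum member energy")
    studies <- sort(unique(vapply(object@members, function(p) p@studyId,
                                  integer(1))))
    if (!identical(studies, object@studiesPresent))
      msg <- c(msg, "studiesPresent inconsistent with members")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus partition of pose clusters across replicate studies
#'
#' @slot accepted clusters containing a member from every required study.
#' @slot rejected the remaining clusters.
#' @slot nStudiesRequired number of distinct studies required (default 5).
#' @exportClass ConsensusSet
setClass("ConsensusSet",
  representation(accepted = "list", rejected = "list",
                 nStudiesRequired = "integer"))

setValidity("ConsensusSet", function(object) {
  if (object@nStudiesRequired < 1L) "nStudiesRequired must be at least 1"
  else TRUE
})

#' Thermodynamic constants for the docking-energy to binding-constant chain
#'
#' @slot RT gas constant times temperature, kcal/mol (0.5925 at 298.15 K).
#' @slot canonicalHbond standard free energy of a canonical hydrogen bond in a
#'   hydrophobic environment, mole-fraction units (-6.5 kcal/mol).
#' @slot multiplexFactor strength of a multiplex (one acceptor, several
#'   donors) interfacial hydrogen bond relative to a canonical one (1.6).
#' @slot molarToMoleFractionOffset additive conversion from molar to
#'   mole-fraction standard state (-0.7 kcal/mol).
#' @exportClass ThermoConstants
setClass("ThermoConstants",
  representation(RT = "numeric", canonicalHbond = "numeric",
                 multiplexFactor = "numeric",
                 molarToMoleFractionOffset = "numeric"))

setValidity("ThermoConstants", function(object) {
  msg <- character()
  if (!(object@RT > 0)) msg <- c(msg, "RT must be positive")
  if (!(object@multiplexFactor > 1))
    msg <- c(msg, "multiplexFactor must exceed 1")
  if (length(msg)) msg else TRUE
})

## kcal/(mol K)
.R_KCAL <- 1.98720425864083e-3

#' Construct ThermoConstants
#'
#' @param temperature temperature in Kelvin (default 298.15).
#' @param canonicalHbond canonical hydrogen-bond free energy, kcal/mol in
#'   mole-fraction units (default -6.5).
#' @param multiplexFactor multiplex-to-canonical hydrogen-bond strength ratio
#'   (default 1.6, i.e. 60\% stronger).
#' @param molarToMoleFractionOffset molar to mole-fraction standard-state
#'   offset, kcal/mol (default -0.7).
#' @return A [ThermoConstants-class] object.
#' @examples
#' thermoConstants()@RT  # 0.5925 kcal/mol
#' @export
thermoConstants <- function(temperature = 298.15, canonicalHbond = -6.5,
                            multiplexFactor = 1.6,
                            molarToMoleFractionOffset = -0.7) {
  new("ThermoConstants", RT = .R_KCAL * temperature,
      canonicalHbond = canonicalHbond, multiplexFactor = multiplexFactor,
      molarToMoleFractionOffset = molarToMoleFractionOffset)
}

#' Parameters of the sterol-coupled dimerization equilibrium
#'
#' Mole-fraction mass-action model of Scap-Insig dimer formation coupled to
#' cholesterol binding at the dimer interface. The scheme is configurable:
#' \code{nCholDimer} sets how many cholesterol molecules the cholesterol-bound
#' dimer carries (default 2, one on each side of the interfacial cleft, which
#' spans both membrane leaflets); \code{includeApoDimer} includes the
#' cholesterol-free dimer species; \code{kaInsigMonomer > 0} adds the
#' cholesterol-bound Insig monomer as an explicit species (pathway variant).
#'
#' @slot kSI Scap-Insig association constant, mole-fraction units (default 4).
#' @slot kaDimer cholesterol binding constant at the dimer site, mole-fraction
#'   units (default 1.6e5).
#' @slot kaInsigMonomer cholesterol binding constant of the Insig monomer
#'   site; 0 disables the species (default 0; the published monomer value is
#'   1.4e3).
#' @slot nCholDimer cholesterol stoichiometry of the bound dimer (default 2).
#' @slot includeApoDimer include the cholesterol-free SI dimer (default TRUE).
#' @slot xScapTotal,xInsigTotal total Scap and Insig mole fractions
#'   (defaults 0.001).
#' @slot xChol cholesterol mole fraction in the membrane.
#' @exportClass EquilibriumParameters
setClass("EquilibriumParameters",
  representation(kSI = "numeric", kaDimer = "numeric",
                 kaInsigMonomer = "numeric", nCholDimer = "integer",
                 includeApoDimer = "logical", xScapTotal = "numeric",
                 xInsigTotal = "numeric", xChol = "numeric"))

setValidity("EquilibriumParameters", function(object) {
  msg <- character()
  if (object@kSI < 0 || object@kaDimer < 0 || object@kaInsigMonomer < 0)
    msg <- c(msg, "association constants must be non-negative")
  if (!(object@xScapTotal > 0 && object@xScapTotal < 1))
    msg <- c(msg, "xScapTotal must be in (0, 1)")
  if (!(object@xInsigTotal > 0 && object@xInsigTotal < 1))
    msg <- c(msg, "xInsigTotal must be in (0, 1)")
  if (!(object@xChol >= 0 && object@xChol < 1))
    msg <- c(msg, "xChol must be in [0, 1)")
  if (object@nCholDimer < 1L)
    msg <- c(msg, "nCholDimer must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Construct EquilibriumParameters
#'
#' @param kSI Scap-Insig association constant (mole-fraction units).
#' @param kaDimer dimer-site cholesterol binding constant.
#' @param kaInsigMonomer Insig-monomer-site binding constant; 0 disables the
#'   cholesterol-bound Insig monomer species.
#' @param nCholDimer cholesterol stoichiometry of the bound dimer.
#' @param includeApoDimer include the cholesterol-free dimer species.
#' @param xScapTotal,xInsigTotal total Scap/Insig mole fractions.
#' @param xChol cholesterol mole fraction.
#' @return An [EquilibriumParameters-class] object.
#' @examples
#' equilibriumParameters(xChol = 0.05)
#' @export
equilibriumParameters <- function(kSI = 4, kaDimer = 1.6e5,
                                  kaInsigMonomer = 0, nCholDimer = 2L,
                                  includeApoDimer = TRUE,
                                  xScapTotal = 0.001, xInsigTotal = 0.001,
                                  xChol = 0) {
  new("EquilibriumParameters", kSI = as.numeric(kSI),
      kaDimer = as.numeric(kaDimer),
      kaInsigMonomer = as.numeric(kaInsigMonomer),
      nCholDimer = as.integer(nCholDimer),
      includeApoDimer = isTRUE(includeApoDimer),
      xScapTotal = as.numeric(xScapTotal),
      xInsigTotal = as.numeric(xInsigTotal), xChol = as.numeric(xChol))
}

#' Mass-action speciation of the membrane
#'
#' @slot xS,xI free Scap and Insig monomer mole fractions.
#' @slot xSI cholesterol-free dimer mole fraction.
#' @slot xSIchol cholesterol-bound dimer mole fraction.
#' @slot xIchol cholesterol-bound Insig monomer mole fraction (0 when the
#'   species is disabled).
#' @slot residuals named solver diagnostics (relative conservation and
#'   mass-action residuals).
#' @slot params the [EquilibriumParameters-class] solved.
#' @exportClass Speciation
setClass("Speciation",
  representation(xS = "numeric", xI = "numeric", xSI = "numeric",
                 xSIchol = "numeric", xIchol = "numeric",
                 residuals = "numeric", params = "EquilibriumParameters"))

setValidity("Speciation", function(object) {
  msg <- character()
  sp <- c(object@xS, object@xI, object@xSI, object@xSIchol, object@xIchol)
  if (any(sp < 0)) msg <- c(msg, "all species must be non-negative")
  if (any(abs(object@residuals) > 1e-8))
    msg <- c(msg, "solver residuals exceed tolerance")
  if (length(msg)) msg else TRUE
})

#' Blueprint of a synthetic docking campaign with planted ground truth
#'
#' @slot plantedSites list of site specifications, each a list with elements
#'   \code{center} (xyz, Angstrom), \code{tilt} (degrees), \code{energy}
#'   (kcal/mol) and \code{studies} (integer subset of 1..nStudies).
#' @slot nDecoysTilt number of decoy poses violating only the tilt criterion.
#' @slot nDecoysContact number of decoy poses violating only the
#'   contact-count criterion.
#' @slot nOverlapDuplicates number of planted poses duplicated into the
#'   neighbouring overlap box.
#' @slot jitterSd per-coordinate Gaussian jitter applied to planted poses
#'   (Angstrom).
#' @slot nStudies,nRuns campaign dimensions.
#' @slot seed RNG seed for the campaign.
#' @exportClass CampaignBlueprint
setClass("CampaignBlueprint",
  representation(plantedSites = "list", nDecoysTilt = "integer",
                 nDecoysContact = "integer", nOverlapDuplicates = "integer",
                 jitterSd = "numeric", nStudies = "integer", nRuns = "integer",
                 seed = "integer"))

setValidity("CampaignBlueprint", function(object) {
  msg <- character()
  ns <- length(object@plantedSites)
  if (ns) {
    ctr <- t(vapply(object@plantedSites, function(s) as.numeric(s$center),
                    numeric(3)))
    if (ns > 1L) {
      d <- as.matrix(stats::dist(ctr))
      if (min(d[upper.tri(d)]) < 8)  # 2 x the 4-Angstrom cluster cutoff
        msg <- c(msg, "planted sites must be at least 8 Angstrom apart")
    }
    for (s in object@plantedSites) {
      if (!all(s$studies >= 1L & s$studies <= object@nStudies))
        msg <- c(msg, "site studies outside 1..nStudies")
    }
  }
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be non-negative")
  if (object@nDecoysTilt < 0L || object@nDecoysContact < 0L ||
      object@nOverlapDuplicates < 0L)
    msg <- c(msg, "decoy and duplicate counts must be non-negative")
  if (length(msg)) msg else TRUE
})
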