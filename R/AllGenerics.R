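#' @include AllClasses.R
NULL

#' Derive the membrane frame from the dummy-atom interface layers
#'
#' Splits the z coordinates of the DUM marker atoms into two layers by an
#' exact one-dimensional 2-means partition and places each interface plane at
#' its layer mean. The membrane normal is +z (the OPM orientation
#' convention).
#'
#' @param structure an [OrientedStructure-class] with dummy atoms present.
#' @return A [MembraneFrame-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeOrientedPdb(makeMembraneBundle(), pdb)
#' deriveMembraneFrame(readOpmPdb(pdb))
#' @export
setGeneric("deriveMembraneFrame",
           function(structure) standardGeneric("deriveMembraneFrame"))

#' Convert interface dummy atoms to hydrogen-bond donor pseudo-atoms
#'
#' Each DUM marker atom is replaced in place by an ammonium-like donor group:
#' one nitrogen at the exact former dummy coordinate plus three hydrogens at
#' 1.01 Angstrom in a tetrahedral umbrella whose axis points along the
#' membrane normal away from the midplane. Pseudo-atoms are flagged and are
#' excluded from protein-contact counting.
#'
#' @param structure an [OrientedStructure-class] with dummy atoms present.
#' @return The converted [OrientedStructure-class] (no dummy atoms remain).
#' @export
setGeneric("convertDummiesToDonorLayers",
           function(structure) standardGeneric("convertDummiesToDonorLayers"))

#' Remove heteroligand residues (including waters) before docking
#'
#' Deletes every HETATM residue other than interface markers and interface
#' pseudo-atoms; protein ATOM records are untouched.
#'
#' @param structure an [OrientedStructure-class].
#' @return The stripped [OrientedStructure-class].
#' @export
setGeneric("stripHeteroligands",
           function(structure) standardGeneric("stripHeteroligands"))

#' Build the two overlapping search boxes for one membrane half
#'
#' Each half-membrane slab (interface plane to midplane, plus margin) is
#' covered by two boxes that split the protein's lateral bounding rectangle
#' at its x midline with a configurable overlap, so that their union contains
#' every protein atom of the half-slab and duplicate poses in the overlap can
#' later be removed.
#'
#' @param structure an [OrientedStructure-class] with a derived frame.
#' @param half \code{"cytosolic"} or \code{"luminal"}.
#' @param margin extra extent added to each box face in z and laterally
#'   (Angstrom, default 3).
#' @param overlapFraction lateral overlap between the two boxes as a fraction
#'   of the protein's x extent (default 0.25).
#' @return A list of two [SearchBox-class] objects.
#' @export
setGeneric("buildSearchBoxes",
           function(structure, half, margin = 3, overlapFraction = 0.25)
             standardGeneric("buildSearchBoxes"))

#' Poses held by a campaign
#' @param x a [DockingCampaign-class].
#' @return A list of [Pose-class] objects.
#' @export
setGeneric("poses", function(x) standardGeneric("poses"))

#' Members of a pose cluster
#' @param x a [PoseCluster-class].
#' @return A list of [Pose-class] objects.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Energy-best representative of a pose cluster
#' @param x a [PoseCluster-class].
#' @return A [Pose-class].
#' @export
setGeneric("representative", function(x) standardGeneric("representative"))

#' Studies contributing members to a cluster
#' @param x a [PoseCluster-class].
#' @return Sorted integer vector of study ids.
#' @export
setGeneric("studiesPresent", function(x) standardGeneric("studiesPresent"))

#' Accepted clusters of a consensus set
#' @param x a [ConsensusSet-class].
#' @return List of [PoseCluster-class] objects.
#' @export
setGeneric("acceptedClusters", function(x) standardGeneric("acceptedClusters"))

#' Rejected clusters of a consensus set
#' @param x a [ConsensusSet-class].
#' @return List of [PoseCluster-class] objects.
#' @export
setGeneric("rejectedClusters", function(x) standardGeneric("rejectedClusters"))

#' Solve the mass-action speciation of the membrane
#'
#' Finds the unique non-negative root of the conservation plus mass-action
#' system by monotone bisection on the free Scap mole fraction (free Insig is
#' eliminated through its own conservation relation).
#'
#' @param params an [EquilibriumParameters-class].
#' @return A [Speciation-class].
#' @examples
#' speciate(equilibriumParameters(xChol = 0.05))
#' @export
setGeneric("speciate", function(params) standardGeneric("speciate"))

#' Fraction of Scap present as the cholesterol-bound dimer
#'
#' Under equal Scap and Insig totals this equals the fraction of all Scap and
#' Insig molecules present as the cholesterol-bound dimer, since each dimer
#' contains one of each.
#'
#' @param params an [EquilibriumParameters-class].
#' @return A fraction in [0, 1].
#' @export
setGeneric("cholBoundDimerFraction",
           function(params) standardGeneric("cholBoundDimerFraction"))

#' Cholesterol level at which half the Scap is cholesterol-bound dimer
#'
#' Bisection root (to 1e-10 in cholesterol mole fraction) of
#' \code{cholBoundDimerFraction(params) == 0.5}, returned in mol\%.
#'
#' @param params an [EquilibriumParameters-class]; its \code{xChol} is
#'   ignored.
#' @return Cholesterol level in mol\%.
#' @examples
#' halfMaximalCholesterol(equilibriumParameters())  # about 5.6 mol%
#' @export
setGeneric("halfMaximalCholesterol",
           function(params) standardGeneric("halfMaximalCholesterol"))

#' Speciation along a cholesterol titration
#'
#' @param params an [EquilibriumParameters-class]; its \code{xChol} is
#'   replaced by each grid value in turn.
#' @param xCholGrid sorted vector of cholesterol mole fractions in [0, 1).
#' @return data.frame with columns molPercent, fraction and the species mole
#'   fractions.
#' @export
setGeneric("titrationCurve",
           function(params, xCholGrid) standardGeneric("titrationCurve"))
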