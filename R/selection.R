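#' @include docking.R
NULL

#' Protein residues in contact with a docked pose
#'
#' A residue is included iff any of its protein heavy atoms lies within
#' \code{cutoff} of any ligand heavy atom. Hydrogens and interface
#' pseudo-atoms are excluded on the protein side; hydrogens on the ligand
#' side.
#'
#' @param pose a [Pose-class].
#' @param structure a prepared [OrientedStructure-class].
#' @param cutoff contact distance in Angstrom (default 4).
#' @return data.frame with one row per contact residue (chain, resno,
#'   resname), sorted by chain then residue number.
#' @export
contactResidues <- function(pose, structure, cutoff = 4) {
  at <- structure@atoms
  prot <- at[.proteinRows(at) & toupper(at$element) != "H", , drop = FALSE]
  lig <- .heavyAtoms(pose)
  if (!nrow(prot) || !nrow(lig))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), stringsAsFactors = FALSE))
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm <- as.matrix(lig[, c("x", "y", "z")])
  ## min distance from each protein atom to any ligand atom
  d2 <- outer(rowSums(pm^2), rep(1, nrow(lm))) +
    outer(rep(1, nrow(pm)), rowSums(lm^2)) - 2 * pm %*% t(lm)
  near <- apply(d2, 1L, min) <= cutoff^2 + 1e-12
  res <- unique(prot[near, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tilt of the sterol ring long axis from the membrane normal
#'
#' The ring long axis is the first principal component of the centered
#' fused-ring atom coordinates; the tilt is the acute angle between that axis
#' and the membrane normal (absolute cosine), in degrees.
#'
#' @param pose a [Pose-class] whose ring-atom subset has at least 3
#'   non-collinear atoms.
#' @param frame a [MembraneFrame-class].
#' @return Angle in degrees, in [0, 90].
#' @export
tiltAngle <- function(pose, frame) {
  rc <- ringCoords(pose)
  if (nrow(rc) < 3L)
    stop("ring atom subset has fewer than 3 atoms")
  X <- sweep(rc, 2L, colMeans(rc))
  sv <- svd(X)
  if (sv$d[1] <= 0 || sv$d[2] / sv$d[1] < 1e-8)
    stop("ring atoms are collinear or degenerate")
  axis <- sv$v[, 1L]
  cosang <- abs(sum(axis * frame@normal)) /
    sqrt(sum(axis^2) * sum(frame@normal^2))
  acos(min(1, cosang)) * 180 / pi
}

#' Assess a pose against the interfacial-site selection criteria
#'
#' Populates the per-pose geometry verdict: contact-residue count, ring-axis
#' tilt, membrane half (by ring-centroid z relative to the midplane),
#' hydroxyl depth (signed distance of the hydroxyl oxygen from the nearest
#' interface plane, positive towards the midplane) and the pass flag. When
#' the criteria are disabled (aqueous regime) every pose passes.
#'
#' @param pose a [Pose-class].
#' @param structure a prepared [OrientedStructure-class].
#' @param criteria a [SelectionCriteria-class].
#' @return A one-row data.frame.
#' @export
assessPose <- function(pose, structure, criteria = selectionCriteria()) {
  frame <- structure@frame
  rc <- ringCoords(pose)
  centroid <- colMeans(rc)
  tilt <- tiltAngle(pose, frame)
  contacts <- contactResidues(pose, structure, criteria@contactCutoff)
  half <- if (centroid[3] > frame@midplane) "cytosolic" else "luminal"
  ohRow <- which(toupper(pose@atoms$element) == "O")
  hydroxylDepth <- if (length(ohRow)) {
    zo <- pose@atoms$z[ohRow[1]]
    nearest <- if (abs(zo - frame@zUpper) < abs(zo - frame@zLower))
      frame@zUpper else frame@zLower
    ## positive = inside the slab (towards the midplane)
    (zo - nearest) * sign(frame@midplane - nearest)
  } else NA_real_
  passes <- if (!criteria@enabled) TRUE
            else nrow(contacts) >= criteria@minContacts && tilt < criteria@maxTilt
  data.frame(study = pose@studyId, run = pose@runId, box = pose@boxId,
             model = pose@modelId, ligand = pose@ligandName,
             energy = pose@energy, nContacts = nrow(contacts),
             tiltDeg = tilt, half = half, hydroxylDepth = hydroxylDepth,
             passes = passes, stringsAsFactors = FALSE)
}

#' Assess a list of poses
#'
#' @param poseList list of [Pose-class] objects.
#' @inheritParams assessPose
#' @return data.frame with one row per pose (see [assessPose()]).
#' @export
assessPoses <- function(poseList, structure, criteria = selectionCriteria()) {
  do.call(rbind, lapply(poseList, assessPose, structure = structure,
                        criteria = criteria))
}

#' Filter poses by the selection criteria
#'
#' Pure filter: the result is a subset of the input and the operation is
#' idempotent.
#'
#' @inheritParams assessPoses
#' @return The passing subset of \code{poseList}.
#' @export
selectPoses <- function(poseList, structure, criteria = selectionCriteria()) {
  if (!length(poseList)) return(poseList)
  verdicts <- assessPoses(poseList, structure, criteria)
  poseList[verdicts$passes]
}

#' Match docking poses to resolved sterol ligands
#'
#' A resolved ligand is matched iff some pose's ring centroid lies within
#' \code{threshold} of the resolved ring centroid. The numeric criterion is a
#' package choice (configurable) and is reported with every match table.
#'
#' @param poseList list of [Pose-class] objects.
#' @param resolved list of resolved ligands, each either a [Pose-class] or a
#'   numeric matrix of ring-atom coordinates.
#' @param threshold centroid-distance criterion in Angstrom (default 3).
#' @return A list with \code{table} (per-ligand best distance, best pose
#'   index and matched flag), \code{matchedFraction}, and the
#'   \code{threshold} used.
#' @export
matchToResolved <- function(poseList, resolved, threshold = 3) {
  if (!length(resolved))
    stop("no resolved ligands supplied")
  if (!length(poseList))
    stop("no poses supplied")
  poseCentroids <- t(vapply(poseList, function(p) colMeans(ringCoords(p)),
                            numeric(3)))
  rows <- lapply(seq_along(resolved), function(i) {
    r <- resolved[[i]]
    rc <- if (is(r, "Pose")) ringCoords(r) else matrix(as.numeric(r), ncol = 3)
    ctr <- colMeans(rc)
    d <- sqrt(rowSums(sweep(poseCentroids, 2L, ctr)^2))
    data.frame(ligand = i, bestDistance = min(d), bestPose = which.min(d),
               matched = min(d) <= threshold)
  })
  table <- do.call(rbind, rows)
  list(table = table, matchedFraction = mean(table$matched),
       threshold = threshold)
}

#' Mean and spread of pose docking energies
#'
#' @param poseList list of [Pose-class] objects, or a numeric vector of
#'   energies.
#' @return A list with \code{mean}, \code{sd} (sample standard deviation,
#'   n - 1; 0 for a single pose, with \code{sdFlagged = TRUE}) and \code{n}.
#' @examples
#' summarizeEnergies(c(-15, -14, -13))  # mean -14, sd 1
#' @export
summarizeEnergies <- function(poseList) {
  e <- if (is.numeric(poseList)) poseList
       else vapply(poseList, function(p) p@energy, numeric(1))
  if (!length(e))
    stop("no poses supplied")
  list(mean = mean(e),
       sd = if (length(e) > 1L) stats::sd(e) else 0,
       n = length(e),
       sdFlagged = length(e) == 1L)
}
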