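#' @include AllClasses.R
NULL

#' Coordinates of a pose's fused-ring atoms
#'
#' @param pose a [Pose-class].
#' @return Numeric matrix (n x 3) of the ring-atom coordinates, in ring-name
#'   order.
#' @export
ringCoords <- function(pose) {
  at <- pose@atoms
  idx <- match(pose@ringNames, at$name)
  idx <- idx[!is.na(idx)]
  as.matrix(at[idx, c("x", "y", "z")])
}

## Heavy (non-hydrogen) atoms of a pose, named.
.heavyAtoms <- function(pose) {
  at <- pose@atoms
  at[toupper(at$element) != "H", , drop = FALSE]
}

## Lexicographic (study, run, box, model) order key, used for deterministic
## energy tie-breaking.
.poseOrder <- function(poseList) {
  order(vapply(poseList, function(p) p@energy, numeric(1)),
        vapply(poseList, function(p) p@studyId, integer(1)),
        vapply(poseList, function(p) p@runId, integer(1)),
        vapply(poseList, function(p) p@boxId, character(1)),
        vapply(poseList, function(p) p@modelId, integer(1)))
}

#' Emit a docking-engine configuration file
#'
#' Produces the text of an AutoDock-Vina-style configuration for one search
#' box under a given scoring regime. The two regime weight directives are
#' always written explicitly (also for the aqueous regime, where they equal
#' the engine defaults), so the configuration is self-describing. Output is
#' byte-stable for identical inputs.
#'
#' @param regime a [DockingRegime-class].
#' @param box a [SearchBox-class].
#' @param receptorPath,ligandPath paths written into the configuration.
#' @param exhaustiveness,numModes optional engine pass-through options; no
#'   defaults are asserted.
#' @return A single character string (the configuration text).
#' @examples
#' box <- new("SearchBox", center = c(0, 0, 7), size = c(30, 30, 20),
#'            half = "cytosolic", index = 1L)
#' cat(makeEngineConfig(dockingRegime("TM"), box, "prot.pdbqt", "chl.pdbqt"))
#' @export
makeEngineConfig <- function(regime, box, receptorPath, ligandPath,
                             exhaustiveness = NULL, numModes = NULL) {
  stopifnot(is(regime, "DockingRegime"), is(box, "SearchBox"))
  if (any(box@size <= 0))
    stop("search box sizes must all be positive")
  num <- function(v) sprintf("%.10g", v)
  lines <- c(
    sprintf("receptor = %s", receptorPath),
    sprintf("ligand = %s", ligandPath),
    sprintf("center_x = %s", num(box@center[1])),
    sprintf("center_y = %s", num(box@center[2])),
    sprintf("center_z = %s", num(box@center[3])),
    sprintf("size_x = %s", num(box@size[1])),
    sprintf("size_y = %s", num(box@size[2])),
    sprintf("size_z = %s", num(box@size[3])),
    sprintf("weight_hydrophobic = %s", num(regime@weightHydrophobic)),
    sprintf("weight_hydrogen = %s", num(regime@weightHydrogen)))
  if (!is.null(exhaustiveness))
    lines <- c(lines, sprintf("exhaustiveness = %s", num(exhaustiveness)))
  if (!is.null(numModes))
    lines <- c(lines, sprintf("num_modes = %s", num(numModes)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a multi-model docking pose file (PDBQT dialect)
#'
#' Reads MODEL/ENDMDL blocks; the docking energy of each model is taken from
#' the first numeric field of its \code{REMARK VINA RESULT:} line (a
#' \code{REMARK  ENERGY} line is accepted as a fallback dialect). Atom names
#' and elements are preserved.
#'
#' @param file path to a pose file, or a character vector of its lines.
#' @param studyId,runId,boxId campaign indices attached to every pose.
#' @param ligandName ligand label (default read from a
#'   \code{REMARK  LIGAND} line if present, else \code{"CLR"}).
#' @param ringNames atom names of the fused sterol ring system.
#' @return A list of [Pose-class] objects, one per MODEL.
#' @export
parsePoseFile <- function(file, studyId = 1L, runId = 1L, boxId = "box-1",
                          ligandName = NULL, ringNames = .RING_NAMES) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file)
           else as.character(file)
  starts <- grep("^MODEL", lines)
  if (!length(starts))
    stop("no MODEL blocks found in pose file")
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL blocks")
  out <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    block <- lines[starts[m]:ends[m]]
    eLine <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (!length(eLine))
      eLine <- grep("^REMARK\\s+ENERGY", block, value = TRUE)
    if (!length(eLine))
      stop(sprintf("model %d has no energy remark", m))
    nums <- regmatches(eLine[1],
                       gregexpr("-?[0-9]+\\.?[0-9]*", eLine[1]))[[1]]
    if (!length(nums))
      stop(sprintf("model %d has an unparseable energy remark", m))
    energy <- as.numeric(nums[1])
    lig <- ligandName
    if (is.null(lig)) {
      lLine <- grep("^REMARK\\s+LIGAND", block, value = TRUE)
      lig <- if (length(lLine))
        utils::tail(strsplit(trimws(lLine[1]), "\\s+")[[1]], 1L) else "CLR"
    }
    atomLines <- block[grepl("^(ATOM|HETATM)", block)]
    if (!length(atomLines))
      stop(sprintf("model %d has no atom records", m))
    atoms <- data.frame(
      name = trimws(substr(atomLines, 13, 16)),
      element = trimws(substr(atomLines, 77, 78)),
      x = as.numeric(substr(atomLines, 31, 38)),
      y = as.numeric(substr(atomLines, 39, 46)),
      z = as.numeric(substr(atomLines, 47, 54)),
      stringsAsFactors = FALSE)
    blank <- atoms$element == ""
    atoms$element[blank] <- substr(gsub("[0-9']", "", atoms$name[blank]), 1, 1)
    out[[m]] <- new("Pose", ligandName = lig, atoms = atoms, energy = energy,
                    studyId = as.integer(studyId), runId = as.integer(runId),
                    boxId = as.character(boxId), modelId = as.integer(m),
                    ringNames = ringNames)
  }
  out
}

#' Write poses as a multi-model pose file (PDBQT dialect)
#'
#' Inverse of [parsePoseFile()]; used by the synthetic campaign generator.
#'
#' @param poseList list of [Pose-class] objects.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writePoseFile <- function(poseList, file) {
  con <- character()
  for (m in seq_along(poseList)) {
    p <- poseList[[m]]
    con <- c(con,
             sprintf("MODEL %d", m),
             sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000",
                     p@energy),
             sprintf("REMARK  LIGAND %s", p@ligandName))
    at <- p@atoms
    for (i in seq_len(nrow(at))) {
      con <- c(con, sprintf(
        "HETATM%5d %-4s %3s A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, substr(at$name[i], 1, 4), substr(p@ligandName, 1, 3),
        at$x[i], at$y[i], at$z[i], at$element[i]))
    }
    con <- c(con, "ENDMDL")
  }
  writeLines(con, file)
  invisible(file)
}

#' Assemble a replicate docking campaign from per-cell pose files
#'
#' @param manifest data.frame with columns \code{study}, \code{run},
#'   \code{box} and \code{file}, one row per (study, run, box) cell for which
#'   the engine produced poses. Cells of the full study x run x box grid that
#'   are absent from the manifest are reported as warnings (engine runs can
#'   fail), not errors.
#' @param regime a [DockingRegime-class].
#' @param nStudies,nRuns declared campaign dimensions (defaults 5, 5).
#' @param ringNames atom names of the fused sterol ring system.
#' @param warnMissing warn about absent grid cells (default TRUE).
#' @return A [DockingCampaign-class].
#' @export
assembleCampaign <- function(manifest, regime = dockingRegime("TM"),
                             nStudies = 5L, nRuns = 5L,
                             ringNames = .RING_NAMES, warnMissing = TRUE) {
  stopifnot(all(c("study", "run", "box", "file") %in% names(manifest)))
  key <- paste(manifest$study, manifest$run, manifest$box, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (study, run, box) key in manifest: ",
         key[duplicated(key)][1])
  if (any(manifest$study < 1L | manifest$study > nStudies))
    stop(sprintf("study id outside 1..%d", nStudies))
  if (any(manifest$run < 1L | manifest$run > nRuns))
    stop(sprintf("run id outside 1..%d", nRuns))
  ## order-independent assembly
  manifest <- manifest[order(manifest$study, manifest$run, manifest$box), ,
                       drop = FALSE]
  boxes <- sort(unique(as.character(manifest$box)))
  if (warnMissing) {
    grid <- expand.grid(study = seq_len(nStudies), run = seq_len(nRuns),
                        box = boxes, stringsAsFactors = FALSE)
    gKey <- paste(grid$study, grid$run, grid$box, sep = "/")
    missing <- setdiff(gKey, paste(manifest$study, manifest$run, manifest$box,
                                   sep = "/"))
    if (length(missing))
      warning(sprintf("%d campaign cell(s) have no pose file: %s",
                      length(missing),
                      paste(utils::head(missing, 5L), collapse = ", ")))
  }
  allPoses <- list()
  for (i in seq_len(nrow(manifest))) {
    allPoses <- c(allPoses, parsePoseFile(
      manifest$file[i], studyId = manifest$study[i], runId = manifest$run[i],
      boxId = as.character(manifest$box[i]), ringNames = ringNames))
  }
  new("DockingCampaign", poses = allPoses, regime = regime,
      nStudies = as.integer(nStudies), nRuns = as.integer(nRuns),
      boxIds = boxes)
}

#' @rdname poses
setMethod("poses", "DockingCampaign", function(x) x@poses)

#' Remove duplicate poses arising in search-box overlap regions
#'
#' Among poses of the same (study, run) that came from different boxes and
#' lie within \code{duplicateRmsd} of each other (connected by pairwise
#' rmsd), only the most favourable-energy pose is retained; ties are broken
#' by (study, run, box, model) order. Poses from the same box are never
#' deduplicated against each other. The operation is idempotent.
#'
#' @param poseList list of [Pose-class] objects sharing a ligand topology.
#' @param duplicateRmsd duplicate threshold in Angstrom (default 1; distinct
#'   from the 4-Angstrom clustering threshold, since box-overlap duplicates
#'   are near-identical placements).
#' @return The deduplicated list of poses, in input order.
#' @export
dedupeOverlapPoses <- function(poseList, duplicateRmsd = 1.0) {
  if (length(poseList) < 2L) return(poseList)
  cellOf <- vapply(poseList, function(p) paste(p@studyId, p@runId, sep = "/"),
                   character(1))
  keep <- rep(TRUE, length(poseList))
  for (cell in unique(cellOf)) {
    idx <- which(cellOf == cell)
    if (length(idx) < 2L) next
    ## duplicate graph: edges only between poses from different boxes
    n <- length(idx)
    comp <- seq_len(n)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      pa <- poseList[[idx[a]]]
      pb <- poseList[[idx[b]]]
      if (pa@boxId == pb@boxId) next
      if (poseRmsd(pa, pb) < duplicateRmsd) {
        old <- comp[b]
        comp[comp == old] <- comp[a]
      }
    }
    for (g in unique(comp)) {
      grp <- idx[comp == g]
      if (length(grp) < 2L) next
      best <- grp[.poseOrder(poseList[grp])[1L]]
      keep[setdiff(grp, best)] <- FALSE
    }
  }
  poseList[keep]
}
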