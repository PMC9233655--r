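#' @include structure-io.R docking.R
NULL

.rotZ <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.rotY <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
.rotX <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Rigid cholesterol-skeleton template
#'
#' A geometric stand-in for cholesterol: 17 fused-ring carbon positions laid
#' out in symmetric pairs so that the ring system's principal axis is exactly
#' +z (long axis about 9 Angstrom), a hydroxyl oxygen 1.2 Angstrom below the
#' ring bottom, and an 8-carbon iso-octyl tail proxy above the ring top
#' (total length about 19 Angstrom, matching cholesterol). The symmetric
#' construction makes the template's tilt identically zero, so a pose rotated
#' by a requested tilt measures back that tilt exactly.
#'
#' @return data.frame with columns name, element, x, y, z.
#' @examples
#' head(sterolTemplate())
#' @export
sterolTemplate <- function() {
  s <- c(1, 1, -1, -1, 1, 1, -1, -1)
  t <- c(1, -1, 1, -1, 1, -1, 1, -1)
  k <- 1:8
  ring <- data.frame(
    name = c(paste0("C", 2 * k - 1), paste0("C", 2 * k), "C17"),
    element = "C",
    x = c(0.8 * s, 0.8 * s, 0),
    y = c(0.3 * t, 0.3 * t, 0),
    z = c(0.55 * k, -0.55 * k, 0),
    stringsAsFactors = FALSE)
  oh <- data.frame(name = "O3", element = "O", x = 0, y = 0, z = -5.6,
                   stringsAsFactors = FALSE)
  j <- 1:8
  tail <- data.frame(
    name = paste0("C", 19 + j), element = "C",
    x = 0.5 * (-1)^j, y = 0, z = 4.95 + 1.15 * (j - 1),
    stringsAsFactors = FALSE)
  rbind(ring, oh, tail)
}

#' Generate a rigid sterol pose at a planted site
#'
#' Rotates the [sterolTemplate()] to the requested tilt (about an in-plane
#' axis set by \code{azimuthDeg}), translates its ring centroid to
#' \code{center}, and applies optional Gaussian coordinate jitter. With zero
#' jitter, [tiltAngle()] on the resulting pose returns \code{tiltDeg}
#' exactly (up to floating point).
#'
#' @param center xyz of the ring centroid (Angstrom).
#' @param tiltDeg requested ring-axis tilt from the membrane normal, degrees
#'   in [0, 90].
#' @param azimuthDeg direction the long axis tips towards, degrees.
#' @param energy docking energy to assign, kcal/mol.
#' @param studyId,runId,boxId,modelId campaign indices.
#' @param jitterSd per-coordinate Gaussian jitter, Angstrom (default 0).
#' @param hydroxylUp orient the hydroxyl towards +z before tilting (used for
#'   cytosolic-half poses, where the interface is the upper plane).
#' @param ligandName ligand label (default \code{"CLR"}).
#' @param seed optional RNG seed for the jitter draw.
#' @return A [Pose-class].
#' @examples
#' p <- makeSterolPose(c(0, 0, -8), tiltDeg = 25, energy = -14.2)
#' tiltAngle(p, membraneFrame(14.2, -14.2))
#' @export
makeSterolPose <- function(center, tiltDeg = 0, azimuthDeg = 0,
                           energy = -14.2, studyId = 1L, runId = 1L,
                           boxId = "luminal-1", modelId = 1L, jitterSd = 0,
                           hydroxylUp = FALSE, ligandName = "CLR",
                           seed = NULL) {
  stopifnot(tiltDeg >= 0, tiltDeg <= 90)
  if (!is.null(seed)) set.seed(seed)
  tpl <- sterolTemplate()
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  if (hydroxylUp) xyz <- xyz %*% t(.rotX(180))
  R <- .rotZ(azimuthDeg) %*% .rotY(tiltDeg) %*% .rotZ(-azimuthDeg)
  xyz <- xyz %*% t(R)
  ringRows <- tpl$name %in% .RING_NAMES
  xyz <- sweep(xyz, 2L, colMeans(xyz[ringRows, , drop = FALSE]))
  xyz <- sweep(xyz, 2L, as.numeric(center), "+")
  if (jitterSd > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitterSd), ncol = 3)
  at <- data.frame(name = tpl$name, element = tpl$element,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  new("Pose", ligandName = ligandName, atoms = at, energy = as.numeric(energy),
      studyId = as.integer(studyId), runId = as.integer(runId),
      boxId = as.character(boxId), modelId = as.integer(modelId),
      ringNames = .RING_NAMES)
}

#' Idealized oriented transmembrane helical bundle with interface layers
#'
#' Builds a poly-alanine C-alpha-trace bundle: \code{nHelices} idealized
#' helices (1.5 Angstrom rise and 100 degrees twist per residue, 2.3
#' Angstrom helix radius) arranged on a circle of the given radius and
#' spanning the hydrophobic slab, flanked by two planar square grids of DUM
#' marker atoms at the two interface planes. Surface hollows between
#' adjacent helices serve as plantable sterol sites (see [hollowSites()]).
#' The construction is fully deterministic.
#'
#' @param nHelices number of helices (at least 3; default 8).
#' @param radius bundle circle radius, Angstrom (default 12).
#' @param thickness hydrophobic slab thickness, Angstrom (default 28.4).
#' @param dumSpacing lateral DUM grid spacing, Angstrom (default 4).
#' @param dumExtent half-width of the DUM grid, Angstrom (default
#'   \code{radius + 8}).
#' @return An [OrientedStructure-class] whose derived frame thickness equals
#'   \code{thickness}.
#' @examples
#' b <- makeMembraneBundle()
#' b@frame@thickness
#' @export
makeMembraneBundle <- function(nHelices = 8L, radius = 12, thickness = 28.4,
                               dumSpacing = 4, dumExtent = radius + 8) {
  if (nHelices < 3L) stop("degenerate geometry: need at least 3 helices")
  if (thickness <= 0 || radius <= 0 || dumSpacing <= 0)
    stop("degenerate geometry: non-positive dimension")
  zmin <- -thickness / 2 - 2
  nRes <- floor((thickness + 4) / 1.5) + 1L
  helixAtoms <- list()
  for (h in seq_len(nHelices)) {
    phi <- 2 * pi * (h - 1) / nHelices
    cx <- radius * cos(phi)
    cy <- radius * sin(phi)
    i <- seq_len(nRes)
    ang <- phi + (100 * pi / 180) * (i - 1)
    helixAtoms[[h]] <- data.frame(
      serial = NA_integer_, name = "CA", element = "C", resname = "ALA",
      resno = as.integer(i), chain = LETTERS[h],
      x = cx + 2.3 * cos(ang), y = cy + 2.3 * sin(ang),
      z = zmin + 1.5 * (i - 1),
      kind = "ATOM", pseudo = FALSE, stringsAsFactors = FALSE)
  }
  g <- seq(-dumExtent, dumExtent, by = dumSpacing)
  grid <- expand.grid(x = g, y = g)
  dum <- data.frame(
    serial = NA_integer_, name = "DUM", element = "N", resname = "DUM",
    resno = as.integer(seq_len(2L * nrow(grid))), chain = "",
    x = rep(grid$x, 2L), y = rep(grid$y, 2L),
    z = c(rep(thickness / 2, nrow(grid)), rep(-thickness / 2, nrow(grid))),
    kind = "HETATM", pseudo = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(do.call(rbind, helixAtoms), dum)
  atoms$serial <- seq_len(nrow(atoms))
  new("OrientedStructure", atoms = atoms,
      dummyIndices = which(atoms$resname == "DUM"),
      frame = membraneFrame(thickness / 2, -thickness / 2),
      layerTolerance = 1.5)
}

#' Candidate sterol sites in the bundle's surface hollows
#'
#' One site per groove between adjacent helices and per membrane half, at
#' the radial distance where an upright sterol pose picks up contacts from
#' both flanking helices. Site z places the ring centroid so that the
#' hydroxyl sits near the half's interface plane.
#'
#' @inheritParams makeMembraneBundle
#' @return data.frame with columns hollow, half, azimuthDeg, x, y, z.
#' @export
hollowSites <- function(nHelices = 8L, radius = 12, thickness = 28.4) {
  rows <- list()
  rSite <- radius + 0.3
  for (k in seq_len(nHelices)) {
    ang <- 2 * pi * (k - 0.5) / nHelices
    for (half in c("cytosolic", "luminal")) {
      zc <- if (half == "cytosolic") thickness / 2 - 6.2 else -thickness / 2 + 6.2
      rows[[length(rows) + 1L]] <- data.frame(
        hollow = k, half = half, azimuthDeg = ang * 180 / pi,
        x = rSite * cos(ang), y = rSite * sin(ang), z = zc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Construct a CampaignBlueprint
#'
#' With \code{plantedSites = NULL} a default truth layout is generated for
#' the default bundle: two sites present in every study and one site present
#' in only four of five, in distinct hollows, with energies drawn from
#' Normal(-14.2, 1.1) truncated to [-18, -10] (the observed distribution of
#' selected transmembrane cholesterol poses).
#'
#' @param plantedSites list of site specs (center, tilt, energy, studies),
#'   or NULL for the default layout.
#' @param nDecoysTilt,nDecoysContact decoy counts (each decoy violates
#'   exactly one selection criterion).
#' @param nOverlapDuplicates how many planted sites get a duplicate pose in
#'   the neighbouring overlap box.
#' @param jitterSd planted-pose coordinate jitter, Angstrom (default 0.25).
#' @param nStudies,nRuns campaign dimensions (defaults 5, 5).
#' @param seed campaign RNG seed.
#' @return A [CampaignBlueprint-class].
#' @export
campaignBlueprint <- function(plantedSites = NULL, nDecoysTilt = 3L,
                              nDecoysContact = 3L, nOverlapDuplicates = 2L,
                              jitterSd = 0.25, nStudies = 5L, nRuns = 5L,
                              seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(plantedSites)) {
    set.seed(seed)
    hs <- hollowSites()
    pick <- list(
      list(row = which(hs$hollow == 1 & hs$half == "luminal"),
           studies = seq_len(nStudies)),
      list(row = which(hs$hollow == 4 & hs$half == "cytosolic"),
           studies = seq_len(nStudies)),
      list(row = which(hs$hollow == 7 & hs$half == "luminal"),
           studies = seq_len(max(1L, nStudies - 1L))))
    plantedSites <- lapply(pick, function(p) {
      h <- hs[p$row, ]
      list(center = c(h$x, h$y, h$z), tilt = stats::runif(1, 0, 12),
           azimuth = h$azimuthDeg, half = h$half,
           energy = .truncNorm(-14.2, 1.1, -18, -10),
           studies = as.integer(p$studies))
    })
  }
  new("CampaignBlueprint", plantedSites = plantedSites,
      nDecoysTilt = as.integer(nDecoysTilt),
      nDecoysContact = as.integer(nDecoysContact),
      nOverlapDuplicates = as.integer(nOverlapDuplicates),
      jitterSd = as.numeric(jitterSd), nStudies = as.integer(nStudies),
      nRuns = as.integer(nRuns), seed = seed)
}

.truncNorm <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  mean
}

## Assign a pose centre to a (half, box index) id given the structure's
## search boxes.
.assignBox <- function(center, boxesByHalf, midplane) {
  half <- if (center[3] > midplane) "cytosolic" else "luminal"
  bx <- boxesByHalf[[half]]
  inside <- vapply(bx, function(b) all(boxContains(b, matrix(center, 1))),
                   logical(1))
  idx <- if (any(inside)) which(inside)[1L] else
    which.min(vapply(bx, function(b)
      sum((b@center - center)^2), numeric(1)))
  sprintf("%s-%d", half, idx)
}

#' Generate a replicate docking campaign with planted ground truth
#'
#' Writes multi-model pose files for every populated (study, run, box) cell
#' of a synthetic campaign on the given structure: planted sterol sites
#' (upright, well-contacted, favourable energies) present in their declared
#' studies; decoy poses violating exactly one selection criterion each
#' (excess tilt, or too few contacts); and duplicated poses in box-overlap
#' regions. The truth table records, per planted site and decoy, whether the
#' full pipeline must accept it (accept iff it passes the criteria and is
#' present in all required studies).
#'
#' @param structure an [OrientedStructure-class] (typically from
#'   [makeMembraneBundle()]).
#' @param blueprint a [CampaignBlueprint-class].
#' @param dir output directory for the pose files (created if needed).
#' @return A list with \code{manifest} (data.frame study, run, box, file),
#'   \code{truth} (data.frame of planted objects and expected verdicts) and
#'   \code{dir}.
#' @export
makeCampaign <- function(structure, blueprint,
                         dir = tempfile("campaign")) {
  validObject(blueprint)
  frame <- structure@frame
  for (s in blueprint@plantedSites) {
    if (s$center[3] < frame@zLower || s$center[3] > frame@zUpper)
      stop("planted site outside the membrane slab")
  }
  set.seed(blueprint@seed + 1L)
  boxesByHalf <- list(cytosolic = buildSearchBoxes(structure, "cytosolic"),
                      luminal = buildSearchBoxes(structure, "luminal"))
  poseSet <- list()
  truthRows <- list()
  addPose <- function(p) poseSet[[length(poseSet) + 1L]] <<- p

  for (i in seq_along(blueprint@plantedSites)) {
    s <- blueprint@plantedSites[[i]]
    boxId <- .assignBox(s$center, boxesByHalf, frame@midplane)
    half <- sub("-[12]$", "", boxId)
    for (st in s$studies) {
      run <- sample.int(blueprint@nRuns, 1L)
      p <- makeSterolPose(s$center, tiltDeg = s$tilt,
                          azimuthDeg = s$azimuth %||% 0,
                          energy = s$energy + stats::rnorm(1, 0, 0.15),
                          studyId = st, runId = run, boxId = boxId,
                          jitterSd = blueprint@jitterSd,
                          hydroxylUp = half == "cytosolic")
      addPose(p)
      if (st == s$studies[1] && i <= blueprint@nOverlapDuplicates) {
        dup <- p
        dup@boxId <- sprintf("%s-%d", half,
                             if (endsWith(boxId, "1")) 2L else 1L)
        dup@energy <- p@energy + 0.2
        addPose(dup)
      }
    }
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      object = sprintf("site-%d", i), kind = "planted",
      x = s$center[1], y = s$center[2], z = s$center[3],
      studies = paste(s$studies, collapse = ","),
      expectAccept = length(unique(s$studies)) >= blueprint@nStudies,
      stringsAsFactors = FALSE)
  }

  hs <- hollowSites()
  usedHollows <- unique(vapply(blueprint@plantedSites, function(s)
    round(atan2(s$center[2], s$center[1]) * 4 / pi - 0.5) %% 8 + 1,
    numeric(1)))
  freeRows <- hs[!(hs$hollow %in% usedHollows), ]
  for (k in seq_len(blueprint@nDecoysTilt)) {
    h <- freeRows[(k - 1L) %% nrow(freeRows) + 1L, ]
    ## 0.4 A deeper into the groove than planted sites: keeps the contact
    ## count comfortably above threshold while the tilt criterion fails
    lat <- sqrt(h$x^2 + h$y^2)
    ctr <- c(h$x, h$y, h$z) * c(rep((lat - 0.4) / lat, 2L), 1)
    p <- makeSterolPose(ctr, tiltDeg = 55,
                        azimuthDeg = h$azimuthDeg + 90,
                        energy = .truncNorm(-11, 1, -13, -8),
                        studyId = sample.int(blueprint@nStudies, 1L),
                        runId = sample.int(blueprint@nRuns, 1L),
                        boxId = .assignBox(ctr, boxesByHalf, frame@midplane),
                        jitterSd = blueprint@jitterSd,
                        hydroxylUp = h$half == "cytosolic")
    addPose(p)
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      object = sprintf("decoy-tilt-%d", k), kind = "decoy-tilt",
      x = ctr[1], y = ctr[2], z = ctr[3], studies = as.character(p@studyId),
      expectAccept = FALSE, stringsAsFactors = FALSE)
  }
  for (k in seq_len(blueprint@nDecoysContact)) {
    ang <- stats::runif(1, 0, 2 * pi)
    zc <- sample(c(-6.2, 6.2), 1L) * frame@thickness / 28.4
    ctr <- c(22 * cos(ang), 22 * sin(ang), zc)
    p <- makeSterolPose(ctr, tiltDeg = 0,
                        energy = .truncNorm(-11, 1, -13, -8),
                        studyId = sample.int(blueprint@nStudies, 1L),
                        runId = sample.int(blueprint@nRuns, 1L),
                        boxId = .assignBox(ctr, boxesByHalf, frame@midplane),
                        jitterSd = blueprint@jitterSd,
                        hydroxylUp = zc > 0)
    addPose(p)
    truthRows[[length(truthRows) + 1L]] <- data.frame(
      object = sprintf("decoy-contact-%d", k), kind = "decoy-contact",
      x = ctr[1], y = ctr[2], z = ctr[3], studies = as.character(p@studyId),
      expectAccept = FALSE, stringsAsFactors = FALSE)
  }

  ## write one pose file per populated (study, run, box) cell
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cellOf <- vapply(poseSet, function(p)
    paste(p@studyId, p@runId, p@boxId, sep = "/"), character(1))
  manifest <- list()
  for (cell in sort(unique(cellOf))) {
    idx <- which(cellOf == cell)
    parts <- strsplit(cell, "/")[[1]]
    file <- file.path(dir, sprintf("study%s_run%s_%s.pdbqt",
                                   parts[1], parts[2], parts[3]))
    cellPoses <- poseSet[idx]
    for (m in seq_along(cellPoses)) cellPoses[[m]]@modelId <- as.integer(m)
    writePoseFile(cellPoses, file)
    manifest[[length(manifest) + 1L]] <- data.frame(
      study = as.integer(parts[1]), run = as.integer(parts[2]),
      box = parts[3], file = file, stringsAsFactors = FALSE)
  }
  list(manifest = do.call(rbind, manifest),
       truth = do.call(rbind, truthRows), dir = dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the canonical small fixture suite
#'
#' Writes, under \code{outdir}: the default oriented bundle as a PDB file,
#' a default synthetic campaign (pose files plus truth table as JSON), a CSV
#' of the printed molar docking energies for the three interfacial sites
#' (dimer -16.8, Insig monomer -14.0, Scap monomer -12.5 kcal/mol), and a
#' manifest of MD5 checksums. Regeneration with the same seed reproduces
#' identical checksums.
#'
#' @param outdir output directory.
#' @param seed campaign seed (default 17).
#' @return data.frame manifest (file, md5), invisibly; also written as
#'   \code{manifest.json}.
#' @export
writeFixtureSet <- function(outdir, seed = 17L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- makeMembraneBundle()
  pdbPath <- file.path(outdir, "bundle.pdb")
  writeOrientedPdb(bundle, pdbPath)
  camp <- makeCampaign(bundle, campaignBlueprint(seed = seed),
                       dir = file.path(outdir, "campaign"))
  truthPath <- file.path(outdir, "truth.json")
  jsonlite::write_json(camp$truth, truthPath, digits = NA)
  tabPath <- file.path(outdir, "table1.csv")
  utils::write.csv(data.frame(
    site = c("dimer", "insig_monomer", "scap_monomer"),
    dGdockMolar = c(-16.8, -14.0, -12.5)), tabPath, row.names = FALSE)
  files <- c(pdbPath, camp$manifest$file, truthPath, tabPath)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  if (any(file.size(files) == 0))
    stop("fixture write failure: empty file in set")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}
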