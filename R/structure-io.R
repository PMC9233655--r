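#' @include AllGenerics.R
NULL

## Exact one-dimensional 2-means split: returns the membership (TRUE = upper
## group) minimising total within-group sum of squares.
.split2means <- function(z) {
  o <- order(z)
  zs <- z[o]
  n <- length(zs)
  best <- NULL
  bestSS <- Inf
  for (k in seq_len(n - 1L)) {
    lo <- zs[seq_len(k)]
    hi <- zs[(k + 1L):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < bestSS) {
      bestSS <- ss
      best <- k
    }
  }
  upper <- logical(n)
  upper[o[(best + 1L):n]] <- TRUE
  upper
}

.proteinRows <- function(atoms) atoms$kind == "ATOM" & !atoms$pseudo

#' Read an OPM-dialect PDB file
#'
#' Parses an OPM-oriented PDB file in which planar layers of \code{DUM}
#' dummy atoms mark the two bilayer interfaces, identifies the dummy layers,
#' and derives the membrane frame. Original coordinates are preserved.
#'
#' @param file path to a PDB file.
#' @param layerTolerance maximum distance (Angstrom) of a dummy atom from its
#'   interface plane (default 1.5).
#' @return An [OrientedStructure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeOrientedPdb(makeMembraneBundle(), pdb)
#' s <- readOpmPdb(pdb)
#' s@frame@thickness
#' @export
readOpmPdb <- function(file, layerTolerance = 1.5) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  a <- pdb$atom
  element <- a$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- substr(gsub("[0-9']", "", a$elety[bad]), 1L, 1L)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    element = as.character(element),
    resname = as.character(a$resid),
    resno = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    x = a$x, y = a$y, z = a$z,
    kind = as.character(a$type),
    pseudo = FALSE,
    stringsAsFactors = FALSE)
  dummy <- which(atoms$resname == "DUM")
  if (!length(dummy))
    stop("not an OPM-oriented structure: no DUM interface marker atoms")
  if (!any(atoms$kind == "ATOM"))
    stop("no protein ATOM records in file")
  structure0 <- new("OrientedStructure", atoms = atoms,
                    dummyIndices = integer(0),
                    frame = membraneFrame(1, -1),  # placeholder
                    layerTolerance = as.numeric(layerTolerance))
  frame <- tryCatch(.frameFromDummyZ(atoms$z[dummy]),
                    error = function(e)
                      stop("cannot define slab: ", conditionMessage(e),
                           call. = FALSE))
  structure0@frame <- frame
  structure0@dummyIndices <- as.integer(dummy)
  validObject(structure0)
  structure0
}

.frameFromDummyZ <- function(z) {
  if (length(z) < 2L)
    stop("fewer than two dummy atoms")
  upper <- .split2means(z)
  zUp <- mean(z[upper])
  zLo <- mean(z[!upper])
  if (!is.finite(zUp) || !is.finite(zLo) || (zUp - zLo) <= 5)
    stop("degenerate layers: dummy planes separated by less than 5 Angstrom")
  membraneFrame(zUp, zLo)
}

#' @rdname deriveMembraneFrame
setMethod("deriveMembraneFrame", "OrientedStructure", function(structure) {
  if (!length(structure@dummyIndices))
    stop("no dummy atoms: frame cannot be derived")
  .frameFromDummyZ(structure@atoms$z[structure@dummyIndices])
})

#' List strippable heteroligand residues
#'
#' Residues that [stripHeteroligands()] would remove: HETATM residues other
#' than interface markers and interface pseudo-atoms (waters included).
#'
#' @param structure an [OrientedStructure-class].
#' @return data.frame with columns resname, chain, resno (one row per
#'   residue).
#' @export
heteroLigands <- function(structure) {
  at <- structure@atoms
  drop <- at$kind == "HETATM" & !at$pseudo & at$resname != "DUM"
  unique(at[drop, c("resname", "chain", "resno")])
}

#' @rdname stripHeteroligands
setMethod("stripHeteroligands", "OrientedStructure", function(structure) {
  at <- structure@atoms
  keep <- !(at$kind == "HETATM" & !at$pseudo & at$resname != "DUM")
  newAtoms <- at[keep, , drop = FALSE]
  rownames(newAtoms) <- NULL
  structure@dummyIndices <- as.integer(
    match(structure@dummyIndices, which(keep)))
  structure@atoms <- newAtoms
  validObject(structure)
  structure
})

#' @rdname convertDummiesToDonorLayers
setMethod("convertDummiesToDonorLayers", "OrientedStructure",
          function(structure) {
  di <- structure@dummyIndices
  if (!length(di))
    stop("no dummy atoms: structure is already converted or not OPM-oriented")
  at <- structure@atoms
  frame <- structure@frame
  normal <- frame@normal
  theta <- (180 - 109.4712206) * pi / 180  # umbrella half-angle from axis
  nhBond <- 1.01
  rows <- vector("list", length(di))
  for (i in seq_along(di)) {
    d <- at[di[i], ]
    axis <- normal * sign(d$z - frame@midplane)
    u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- u - sum(u * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    phi <- c(0, 2, 4) * pi / 3
    hxyz <- t(vapply(phi, function(p) {
      c(d$x, d$y, d$z) + nhBond *
        (cos(theta) * axis + sin(theta) * (cos(p) * e1 + sin(p) * e2))
    }, numeric(3)))
    rows[[i]] <- data.frame(
      serial = NA_integer_,
      name = c("N", "H1", "H2", "H3"),
      element = c("N", "H", "H", "H"),
      resname = "NH3",
      resno = d$resno,
      chain = d$chain,
      x = c(d$x, hxyz[, 1]), y = c(d$y, hxyz[, 2]), z = c(d$z, hxyz[, 3]),
      kind = "HETATM",
      pseudo = TRUE,
      stringsAsFactors = FALSE)
  }
  newAtoms <- rbind(at[-di, , drop = FALSE], do.call(rbind, rows))
  newAtoms$serial <- seq_len(nrow(newAtoms))
  rownames(newAtoms) <- NULL
  structure@atoms <- newAtoms
  structure@dummyIndices <- integer(0)
  validObject(structure)
  structure
})

#' @rdname buildSearchBoxes
setMethod("buildSearchBoxes", "OrientedStructure",
          function(structure, half, margin = 3, overlapFraction = 0.25) {
  half <- match.arg(half, c("cytosolic", "luminal"))
  frame <- structure@frame
  at <- structure@atoms
  prot <- at[.proteinRows(at), , drop = FALSE]
  inHalf <- if (half == "cytosolic")
    prot$z >= frame@midplane & prot$z <= frame@zUpper
  else
    prot$z <= frame@midplane & prot$z >= frame@zLower
  slab <- prot[inHalf, , drop = FALSE]
  if (!nrow(slab))
    stop(sprintf("no protein atoms in the %s half-slab", half))
  xr <- range(slab$x)
  yr <- range(slab$y)
  W <- diff(xr)
  xmid <- mean(xr)
  ov <- overlapFraction * W / 2
  zr <- if (half == "cytosolic") c(frame@midplane, frame@zUpper)
        else c(frame@zLower, frame@midplane)
  zlim <- c(zr[1] - margin, zr[2] + margin)
  mkBox <- function(xlim, index) {
    ylim <- c(yr[1] - margin, yr[2] + margin)
    new("SearchBox",
        center = c(mean(xlim), mean(ylim), mean(zlim)),
        size = c(diff(xlim), diff(ylim), diff(zlim)),
        half = half, index = as.integer(index))
  }
  list(mkBox(c(xr[1] - margin, xmid + ov + margin), 1L),
       mkBox(c(xmid - ov - margin, xr[2] + margin), 2L))
})

#' Test points for inclusion in a search box
#'
#' @param box a [SearchBox-class].
#' @param xyz numeric matrix with columns x, y, z.
#' @return Logical vector, one element per row of \code{xyz}.
#' @export
boxContains <- function(box, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  lo <- box@center - box@size / 2
  hi <- box@center + box@size / 2
  xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
}

#' Serialize search boxes to JSON
#'
#' @param boxes list of [SearchBox-class] objects.
#' @param file output path.
#' @return The path, invisibly.
#' @export
boxesToJson <- function(boxes, file) {
  payload <- lapply(boxes, function(b)
    list(half = b@half, index = b@index,
         center = as.numeric(b@center), size = as.numeric(b@size)))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write an OrientedStructure to a PDB file
#'
#' Writes ATOM/HETATM records (including dummy or pseudo-layer atoms) in
#' fixed-column PDB format, so the file round-trips through [readOpmPdb()].
#'
#' @param structure an [OrientedStructure-class].
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeOrientedPdb <- function(structure, file) {
  at <- structure@atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = file, xyz = xyz,
                   type = at$kind,
                   resno = at$resno,
                   resid = at$resname,
                   eleno = seq_len(nrow(at)),
                   elety = at$name,
                   chain = ifelse(at$chain == "", NA, at$chain),
                   elesy = at$element,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(file)
}
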