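## Tiny hand-written OPM-dialect fixture: a 24-atom poly-ALA stub flanked by
## 8 + 8 DUM markers at z = +/-14.2, with optional heteroligand residues.
## Written independently of the package's own PDB writer.
writeTinyOpmFixture <- function(file, withDum = TRUE, singleLayer = FALSE,
                                hetResnames = character()) {
  fmt <- function(kind, serial, name, resname, chain, resno, x, y, z, el) {
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            kind, serial, name, resname, chain, resno, x, y, z, el)
  }
  lines <- character()
  serial <- 0L
  for (i in 1:24) {
    serial <- serial + 1L
    lines <- c(lines, fmt("ATOM", serial, "CA", "ALA", "A", i,
                          3 * cos(i), 3 * sin(i), -12 + i, "C"))
  }
  for (rn in hetResnames) {
    serial <- serial + 1L
    lines <- c(lines, fmt("HETATM", serial, "C1", rn, "B", 200L + serial,
                          8, 8, 0, "C"))
  }
  if (withDum) {
    for (i in 1:8) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, "DUM", "DUM", " ", 300L + i,
                            4 * i - 18, 0, 14.2, "N"))
    }
    if (!singleLayer) {
      for (i in 1:8) {
        serial <- serial + 1L
        lines <- c(lines, fmt("HETATM", serial, "DUM", "DUM", " ", 310L + i,
                              4 * i - 18, 0, -14.2, "N"))
      }
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

## Build a Pose directly from a coordinate matrix (rows follow `names`).
makePoseFromCoords <- function(xyz, names = paste0("C", seq_len(nrow(xyz))),
                               element = "C", energy = -10,
                               studyId = 1L, runId = 1L, boxId = "b1",
                               modelId = 1L,
                               ringNames = paste0("C", 1:17)) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  new("Pose", ligandName = "CLR",
      atoms = data.frame(name = names,
                         element = rep_len(element, nrow(xyz)),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE),
      energy = energy, studyId = as.integer(studyId),
      runId = as.integer(runId), boxId = boxId,
      modelId = as.integer(modelId), ringNames = ringNames)
}

## An artificial receptor: single-CA residues at prescribed positions.
makePointStructure <- function(xyz, zUpper = 14.2, zLower = -14.2) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resno = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    kind = "ATOM", pseudo = FALSE, stringsAsFactors = FALSE)
  new("OrientedStructure", atoms = atoms, dummyIndices = integer(0),
      frame = membraneFrame(zUpper, zLower), layerTolerance = 1.5)
}

## Brute-force all-pairs contact oracle: residues with any heavy atom within
## cutoff of any ligand heavy atom.
bruteContactResidues <- function(pose, structure, cutoff) {
  at <- structure@atoms
  prot <- at[at$kind == "ATOM" & !at$pseudo & toupper(at$element) != "H", ]
  lig <- pose@atoms[toupper(pose@atoms$element) != "H", ]
  hits <- character()
  for (i in seq_len(nrow(prot))) for (j in seq_len(nrow(lig))) {
    d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
              (prot$z[i] - lig$z[j])^2)
    if (d <= cutoff)
      hits <- c(hits, paste(prot$chain[i], prot$resno[i]))
  }
  sort(unique(hits))
}

## Brute-force atom-by-atom rmsd oracle (name-matched heavy atoms).
bruteRmsd <- function(p1, p2) {
  a1 <- p1@atoms[toupper(p1@atoms$element) != "H", ]
  a2 <- p2@atoms[toupper(p2@atoms$element) != "H", ]
  total <- 0
  for (i in seq_len(nrow(a1))) {
    j <- which(a2$name == a1$name[i])
    total <- total + (a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
      (a1$z[i] - a2$z[j])^2
  }
  sqrt(total / nrow(a1))
}

## Independent refining-grid oracle for the speciation solver: scans the
## free-Scap conservation residual on successively finer grids.
gridSpeciationOracle <- function(params) {
  p <- params
  c <- p@xChol
  kApo <- if (p@includeApoDimer) p@kSI else 0
  beta <- p@kSI * p@kaDimer * c^p@nCholDimer
  cplx <- kApo + beta
  g <- function(s) {
    xI <- p@xInsigTotal / (1 + p@kaInsigMonomer * c + s * cplx)
    s * (1 + xI * cplx) - p@xScapTotal
  }
  lo <- 0
  hi <- p@xScapTotal
  for (pass in 1:10) {
    grid <- seq(lo, hi, length.out = 201)
    vals <- vapply(grid, g, numeric(1))
    k <- which(vals >= 0)[1]
    if (is.na(k)) k <- length(grid)
    hi <- grid[k]
    lo <- grid[max(1L, k - 1L)]
  }
  s <- (lo + hi) / 2
  xI <- p@xInsigTotal / (1 + p@kaInsigMonomer * c + s * cplx)
  list(xS = s, xI = xI, xSI = kApo * s * xI, xSIchol = beta * s * xI,
       xIchol = p@kaInsigMonomer * c * xI)
}

## Default bundle + donor-layer structure, shared across tests.
sharedBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- makeMembraneBundle()
      cache <<- list(raw = b, prepared = convertDummiesToDonorLayers(b))
    }
    cache
  }
})
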