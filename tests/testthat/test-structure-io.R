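test_that("OPM fixture parses with two dummy layers and the expected frame", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyOpmFixture(f)
  s <- readOpmPdb(f)
  expect_length(s@dummyIndices, 16L)
  expect_equal(s@frame@thickness, 28.4)
  expect_equal(s@frame@zUpper, 14.2)
  expect_equal(sum(s@atoms$kind == "ATOM"), 24L)
  ## original coordinates preserved
  expect_equal(s@atoms$z[1], -11, tolerance = 1e-9)
})

test_that("missing or degenerate dummy layers are rejected", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeTinyOpmFixture(f1, withDum = FALSE)
  expect_error(readOpmPdb(f1), "not an OPM-oriented structure")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeTinyOpmFixture(f2, singleLayer = TRUE)
  expect_error(readOpmPdb(f2), "cannot define slab")
})

test_that("heteroligand residues are detected and strippable", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTinyOpmFixture(f, hetResnames = c("CLR", "AJP", "HOH"))
  s <- readOpmPdb(f)
  lig <- heteroLigands(s)
  expect_setequal(lig$resname, c("CLR", "AJP", "HOH"))
  stripped <- stripHeteroligands(s)
  expect_equal(nrow(heteroLigands(stripped)), 0L)
  expect_equal(sum(stripped@atoms$kind == "ATOM"), 24L)
  expect_length(stripped@dummyIndices, 16L)
  ## identity on a ligand-free structure
  f0 <- withr::local_tempfile(fileext = ".pdb")
  writeTinyOpmFixture(f0)
  s0 <- readOpmPdb(f0)
  expect_equal(nrow(stripHeteroligands(s0)@atoms), nrow(s0@atoms))
})

test_that("membrane frame derivation averages jittered layers and is
          permutation invariant", {
  b <- sharedBundle()$raw
  fr <- deriveMembraneFrame(b)
  expect_equal(fr@thickness, 28.4, tolerance = 1e-12)

  ## jittered layers: planes at the layer means
  set.seed(11)
  zUp <- 15 + runif(8, -0.3, 0.3)
  zLo <- -15 + runif(8, -0.3, 0.3)
  at <- b@atoms
  jit <- at
  di <- b@dummyIndices[1:16]
  jit$z[di] <- c(zUp, zLo)
  jit <- jit[c(which(at$resname != "DUM"), di), ]
  jit$serial <- seq_len(nrow(jit))
  s2 <- new("OrientedStructure", atoms = jit,
            dummyIndices = which(jit$resname == "DUM"),
            frame = membraneFrame(mean(zUp), mean(zLo)),
            layerTolerance = 1.5)
  fr2 <- deriveMembraneFrame(s2)
  expect_equal(fr2@zUpper, mean(zUp), tolerance = 1e-12)
  expect_equal(fr2@zLower, mean(zLo), tolerance = 1e-12)

  ## permutation invariance
  perm <- sample(nrow(jit))
  s3 <- s2
  s3@atoms <- jit[perm, ]
  s3@dummyIndices <- which(s3@atoms$resname == "DUM")
  fr3 <- deriveMembraneFrame(s3)
  expect_equal(fr3@zUpper, fr2@zUpper)
  expect_equal(fr3@zLower, fr2@zLower)

  ## merged single layer is degenerate
  s4 <- s2
  s4@atoms$z[s4@dummyIndices] <- 15
  s4@frame <- membraneFrame(16, 14)  # placeholder to bypass band check
  s4@layerTolerance <- 10
  expect_error(deriveMembraneFrame(s4), "degenerate layers")
})

test_that("dummy-to-donor conversion replaces each marker by an NH3 group", {
  b <- sharedBundle()$raw
  nDum <- length(b@dummyIndices)
  dumXyz <- as.matrix(b@atoms[b@dummyIndices, c("x", "y", "z")])
  conv <- convertDummiesToDonorLayers(b)
  expect_length(conv@dummyIndices, 0L)
  expect_equal(sum(conv@atoms$resname == "DUM"), 0L)
  expect_equal(sum(conv@atoms$pseudo & conv@atoms$element == "N"), nDum)
  expect_equal(sum(conv@atoms$pseudo & conv@atoms$element == "H"), 3L * nDum)
  ## nitrogen takes the exact former dummy coordinate
  nXyz <- as.matrix(conv@atoms[conv@atoms$pseudo & conv@atoms$element == "N",
                               c("x", "y", "z")])
  expect_equal(nXyz[order(nXyz[, 1], nXyz[, 2], nXyz[, 3]), ],
               dumXyz[order(dumXyz[, 1], dumXyz[, 2], dumXyz[, 3]), ],
               ignore_attr = TRUE)
  ## N-H geometry: 1.01 A bonds
  firstN <- which(conv@atoms$element == "N" & conv@atoms$pseudo)[1]
  hRows <- firstN + 1:3
  d <- unname(sqrt(rowSums((as.matrix(conv@atoms[hRows, c("x", "y", "z")]) -
    matrix(unlist(conv@atoms[firstN, c("x", "y", "z")]), 3, 3,
           byrow = TRUE))^2)))
  expect_equal(d, rep(1.01, 3), tolerance = 1e-9)
  expect_error(convertDummiesToDonorLayers(conv), "no dummy atoms")
})

test_that("search boxes cover each half-slab with a lateral overlap", {
  b <- sharedBundle()$raw
  for (half in c("cytosolic", "luminal")) {
    boxes <- buildSearchBoxes(b, half)
    expect_length(boxes, 2L)
    for (bx in boxes)
      expect_equal(bx@size[3], b@frame@thickness / 2 + 6, tolerance = 1e-9)
    ## nonempty intersection
    lo <- pmax(boxes[[1]]@center - boxes[[1]]@size / 2,
               boxes[[2]]@center - boxes[[2]]@size / 2)
    hi <- pmin(boxes[[1]]@center + boxes[[1]]@size / 2,
               boxes[[2]]@center + boxes[[2]]@size / 2)
    expect_true(all(hi > lo))
    ## union contains every protein atom of the half-slab
    at <- b@atoms
    prot <- at[at$kind == "ATOM", ]
    inHalf <- if (half == "cytosolic")
      prot$z >= b@frame@midplane & prot$z <= b@frame@zUpper
    else prot$z <= b@frame@midplane & prot$z >= b@frame@zLower
    pts <- as.matrix(prot[inHalf, c("x", "y", "z")])
    expect_true(all(boxContains(boxes[[1]], pts) |
                    boxContains(boxes[[2]], pts)))
  }
})

test_that("box construction is translation equivariant in x", {
  b <- sharedBundle()$raw
  shifted <- b
  shifted@atoms$x <- shifted@atoms$x + 7.5
  b1 <- buildSearchBoxes(b, "cytosolic")
  b2 <- buildSearchBoxes(shifted, "cytosolic")
  for (k in 1:2) {
    expect_equal(b2[[k]]@center - b1[[k]]@center, c(7.5, 0, 0),
                 tolerance = 1e-9)
    expect_equal(b2[[k]]@size, b1[[k]]@size, tolerance = 1e-9)
  }
  ## a half with no protein atoms errors
  lower <- b
  lower@atoms <- lower@atoms[!(lower@atoms$kind == "ATOM" &
                               lower@atoms$z > b@frame@midplane), ]
  lower@dummyIndices <- which(lower@atoms$resname == "DUM")
  expect_error(buildSearchBoxes(lower, "cytosolic"), "no protein atoms")
})

test_that("PDB round trip preserves atoms, names and coordinates to 1e-3", {
  b <- sharedBundle()$raw
  f <- withr::local_tempfile(fileext = ".pdb")
  writeOrientedPdb(b, f)
  s <- readOpmPdb(f)
  expect_equal(nrow(s@atoms), nrow(b@atoms))
  expect_equal(s@atoms$name, b@atoms$name)
  expect_equal(s@atoms$resname, b@atoms$resname)
  for (col in c("x", "y", "z"))
    expect_equal(s@atoms[[col]], b@atoms[[col]], tolerance = 1.1e-3)
  expect_equal(length(s@dummyIndices), length(b@dummyIndices))
  ## JSON serialization of boxes
  jf <- withr::local_tempfile(fileext = ".json")
  boxesToJson(buildSearchBoxes(b, "luminal"), jf)
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(nrow(parsed), 2L)
  expect_equal(unlist(parsed$size[1]) > 0, rep(TRUE, 3), ignore_attr = TRUE)
})
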