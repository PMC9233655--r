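tmBox <- function() new("SearchBox", center = c(0, 0, 7.1),
                        size = c(30, 30, 20.2), half = "cytosolic",
                        index = 1L)

test_that("engine configuration carries the regime weights and box geometry", {
  cfg <- makeEngineConfig(dockingRegime("TM"), tmBox(), "r.pdbqt", "l.pdbqt")
  expect_match(cfg, "weight_hydrophobic = -0.001", fixed = TRUE)
  expect_match(cfg, "weight_hydrogen = -2", fixed = TRUE)
  expect_match(cfg, "center_z = 7.1", fixed = TRUE)
  expect_match(cfg, "size_x = 30", fixed = TRUE)
  cfgA <- makeEngineConfig(dockingRegime("aqueous"), tmBox(), "r", "l")
  expect_match(cfgA, "-0.0351", fixed = TRUE)
  expect_match(cfgA, "-0.587", fixed = TRUE)
  ## byte stability
  expect_identical(cfg,
    makeEngineConfig(dockingRegime("TM"), tmBox(), "r.pdbqt", "l.pdbqt"))
  badBox <- tmBox()
  badBox@size <- c(0, 20, 20)
  expect_error(makeEngineConfig(dockingRegime("TM"), badBox, "r", "l"),
               "positive")
  ## regime weights are locked to their labels
  expect_error(new("DockingRegime", label = "TM", weightHydrophobic = -0.03,
                   weightHydrogen = -2), "requires weights")
})

test_that("multi-model pose files parse one pose per MODEL with its energy", {
  ps <- lapply(1:9, function(m)
    makeSterolPose(c(0, 0, -8 + m / 10), energy = -14.2 - m / 10,
                   modelId = m))
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writePoseFile(ps, f)
  parsed <- parsePoseFile(f, studyId = 2, runId = 3, boxId = "luminal-1")
  expect_length(parsed, 9L)
  expect_equal(parsed[[1]]@energy, -14.3)
  expect_equal(parsed[[5]]@studyId, 2L)
  expect_equal(parsed[[5]]@modelId, 5L)
  expect_equal(parsed[[3]]@atoms$name, sterolTemplate()$name)
  ## coordinates survive the fixed-format round trip
  expect_equal(as.matrix(parsed[[1]]@atoms[, c("x", "y", "z")]),
               as.matrix(ps[[1]]@atoms[, c("x", "y", "z")]),
               tolerance = 1.1e-3, ignore_attr = TRUE)
  expect_error(parsePoseFile(character(0)), "no MODEL")
  noEnergy <- c("MODEL 1", "HETATM    1  C1  CLR A   1       0.000   0.000   0.000  1.00  0.00           C",
                "ENDMDL")
  expect_error(parsePoseFile(noEnergy), "model 1")
})

test_that("the fallback energy-remark dialect is accepted", {
  lines <- c("MODEL 1", "REMARK  ENERGY  -12.75",
             sprintf("HETATM%5d %-4s CLR A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     1:3, c("C1", "C2", "C3"), c(0, 1, 2), 0, c(0, 0, 1)),
             "ENDMDL")
  p <- parsePoseFile(lines)
  expect_equal(p[[1]]@energy, -12.75)
})

test_that("campaign assembly indexes the full grid and flags missing cells", {
  dir <- withr::local_tempdir()
  boxes <- c("cytosolic-1", "cytosolic-2", "luminal-1", "luminal-2")
  manifest <- expand.grid(study = 1:5, run = 1:5, box = boxes,
                          stringsAsFactors = FALSE)
  manifest$file <- file.path(dir, sprintf("s%d_r%d_%s.pdbqt",
                                          manifest$study, manifest$run,
                                          manifest$box))
  for (i in seq_len(nrow(manifest))) {
    z <- if (grepl("cytosolic", manifest$box[i])) 8 else -8
    writePoseFile(lapply(1:3, function(m)
      makeSterolPose(c(0, 0, z + m), energy = -12 - m)), manifest$file[i])
  }
  camp <- assembleCampaign(manifest)
  expect_length(poses(camp), 300L)
  expect_s4_class(camp, "DockingCampaign")

  ## one missing cell: warning, 297 poses
  expect_warning(camp2 <- assembleCampaign(manifest[-1, ]), "no pose file")
  expect_length(poses(camp2), 297L)

  ## order independence over file enumeration
  camp3 <- suppressWarnings(
    assembleCampaign(manifest[rev(seq_len(nrow(manifest))[-1]), ]))
  expect_equal(vapply(poses(camp3), function(p) p@energy, numeric(1)),
               vapply(poses(camp2), function(p) p@energy, numeric(1)))

  ## out-of-range and duplicate keys
  bad <- manifest[1, ]
  bad$study <- 6L
  expect_error(assembleCampaign(rbind(manifest, bad)), "study id")
  expect_error(assembleCampaign(rbind(manifest, manifest[1, ])), "duplicate")
})

test_that("overlap deduplication keeps the best-energy member per duplicate
          group and is idempotent", {
  mk <- function(energy, box, dx = 0, study = 1L, run = 1L)
    makeSterolPose(c(dx, 0, -8), energy = energy, boxId = box,
                   studyId = study, runId = run)
  ## identical pose in two boxes: best energy survives
  out <- dedupeOverlapPoses(list(mk(-14.0, "luminal-1"), mk(-13.8, "luminal-2")))
  expect_length(out, 1L)
  expect_equal(out[[1]]@energy, -14.0)
  ## distant poses both retained
  out2 <- dedupeOverlapPoses(list(mk(-14, "luminal-1"),
                                  mk(-13, "luminal-2", dx = 10)))
  expect_length(out2, 2L)
  ## same box never deduplicated
  out3 <- dedupeOverlapPoses(list(mk(-14, "luminal-1"), mk(-13.8, "luminal-1")))
  expect_length(out3, 2L)
  ## different (study, run) cells never deduplicated
  out4 <- dedupeOverlapPoses(list(mk(-14, "luminal-1", study = 1L),
                                  mk(-13.8, "luminal-2", study = 2L)))
  expect_length(out4, 2L)
  ## three mutual duplicates across boxes: single survivor, energy minimum
  ## (brute-force expectation: all pairwise rmsd < 1, so one group)
  trio <- list(mk(-13.5, "luminal-1"), mk(-14.2, "luminal-2"),
               mk(-13.9, "cytosolic-1"))
  rms <- c(poseRmsd(trio[[1]], trio[[2]]), poseRmsd(trio[[1]], trio[[3]]),
           poseRmsd(trio[[2]], trio[[3]]))
  expect_true(all(rms < 1))
  out5 <- dedupeOverlapPoses(trio)
  expect_length(out5, 1L)
  expect_equal(out5[[1]]@energy, -14.2)
  ## idempotence
  expect_equal(length(dedupeOverlapPoses(out5)), 1L)
  mixed <- list(mk(-14.0, "luminal-1"), mk(-13.8, "luminal-2"),
                mk(-12, "luminal-1", dx = 12), mk(-11.9, "luminal-2", dx = 12))
  once <- dedupeOverlapPoses(mixed)
  twice <- dedupeOverlapPoses(once)
  expect_equal(vapply(twice, function(p) p@energy, numeric(1)),
               vapply(once, function(p) p@energy, numeric(1)))
})
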