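test_that("contact counting matches a brute-force all-pairs oracle", {
  set.seed(21)
  pose <- makeSterolPose(c(0, 0, -8))
  rc <- ringCoords(pose)
  ## engineer exactly 8 residues with one heavy atom 3.5 A from a ring atom,
  ## plus 6 residues far away
  near <- t(vapply(1:8, function(i) {
    base <- rc[i, ]
    base + c(3.5, 0, 0)
  }, numeric(3)))
  far <- matrix(rnorm(18, mean = 40), ncol = 3)
  struct <- makePointStructure(rbind(near, far))
  got <- contactResidues(pose, struct, 4)
  expect_equal(nrow(got), 8L)
  oracle <- bruteContactResidues(pose, struct, 4)
  expect_equal(sort(paste(got$chain, got$resno)), oracle)

  ## far pose has no contacts
  farPose <- makeSterolPose(c(50, 50, -8))
  expect_equal(nrow(contactResidues(farPose, struct, 4)), 0L)

  ## monotonicity in the cutoff
  b <- sharedBundle()$prepared
  hs <- hollowSites()[3, ]
  p <- makeSterolPose(c(hs$x, hs$y, hs$z), tiltDeg = 5,
                      azimuthDeg = hs$azimuthDeg)
  c4 <- contactResidues(p, b, 4)
  c5 <- contactResidues(p, b, 5)
  expect_true(all(paste(c4$chain, c4$resno) %in% paste(c5$chain, c5$resno)))
  ## oracle agreement on the realistic bundle too
  expect_equal(sort(paste(c4$chain, c4$resno)), bruteContactResidues(p, b, 4))
})

test_that("contact counting ignores hydrogens and interface pseudo-atoms", {
  b <- sharedBundle()$prepared
  ## a pose sitting right on the upper donor layer, far from the protein
  p <- makeSterolPose(c(30, 30, 8), tiltDeg = 0)
  expect_equal(nrow(contactResidues(p, b, 4)), 0L)
  ## atom-order permutation leaves the contact set unchanged
  hs <- hollowSites()[1, ]
  p2 <- makeSterolPose(c(hs$x, hs$y, hs$z), tiltDeg = 3,
                       azimuthDeg = hs$azimuthDeg, hydroxylUp = TRUE)
  before <- contactResidues(p2, b, 4)
  p3 <- p2
  p3@atoms <- p3@atoms[rev(seq_len(nrow(p3@atoms))), ]
  expect_equal(contactResidues(p3, b, 4), before)
})

test_that("ring-axis tilt equals the constructed rotation angle", {
  fr <- membraneFrame(14.2, -14.2)
  expect_equal(tiltAngle(makeSterolPose(c(0, 0, -8), tiltDeg = 0), fr), 0,
               tolerance = 1e-9)
  expect_equal(tiltAngle(makeSterolPose(c(0, 0, -8), tiltDeg = 90), fr), 90,
               tolerance = 1e-9)
  for (az in c(0, 40, 210))
    expect_equal(tiltAngle(makeSterolPose(c(0, 0, -8), tiltDeg = 25,
                                          azimuthDeg = az), fr),
                 25, tolerance = 1e-6)
  ## tilts beyond 90 degrees fold back to the acute angle
  p <- makeSterolPose(c(0, 0, -8), tiltDeg = 0, hydroxylUp = TRUE)
  expect_equal(tiltAngle(p, fr), 0, tolerance = 1e-9)
  ## invariance under rotation about the membrane normal
  p25 <- makeSterolPose(c(0, 0, -8), tiltDeg = 25)
  rot <- p25
  a <- 73 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rot@atoms[, c("x", "y", "z")] <-
    as.matrix(p25@atoms[, c("x", "y", "z")]) %*% t(R)
  expect_equal(tiltAngle(rot, fr), 25, tolerance = 1e-6)
  ## collinear ring atoms are degenerate
  line <- makePoseFromCoords(cbind(0, 0, seq_len(17)))
  expect_error(tiltAngle(line, fr), "collinear")
})

test_that("pose assessment combines both criteria and honours the aqueous
          switch", {
  pose <- makeSterolPose(c(0, 0, -8), tiltDeg = 29.9)
  rc <- ringCoords(pose)
  near8 <- sweep(rc[1:8, ], 2L, c(3.5, 0, 0), "+")
  struct8 <- makePointStructure(near8)
  a <- assessPose(pose, struct8)
  expect_equal(a$nContacts, 8L)
  expect_equal(a$tiltDeg, 29.9, tolerance = 1e-6)
  expect_true(a$passes)
  expect_equal(a$half, "luminal")

  ## 7 contacts, modest tilt: fails
  pose5 <- makeSterolPose(c(0, 0, -8), tiltDeg = 5)
  near7 <- sweep(ringCoords(pose5)[1:7, ], 2L, c(3.5, 0, 0), "+")
  a7 <- assessPose(pose5, makePointStructure(near7))
  expect_equal(a7$nContacts, 7L)
  expect_false(a7$passes)

  ## 12 contacts but 31 degrees: fails with criteria on, passes when off
  pose31 <- makeSterolPose(c(0, 0, -8), tiltDeg = 31)
  near12 <- sweep(ringCoords(pose31)[1:12, ], 2L, c(3.5, 0, 0), "+")
  s12 <- makePointStructure(near12)
  expect_false(assessPose(pose31, s12)$passes)
  expect_true(assessPose(pose31, s12,
                         selectionCriteria(enabled = FALSE))$passes)

  ## half assignment by ring centroid
  up <- makeSterolPose(c(0, 0, 8), hydroxylUp = TRUE)
  expect_equal(assessPose(up, struct8)$half, "cytosolic")
})

test_that("selection is a pure, idempotent filter", {
  b <- sharedBundle()$prepared
  hs <- hollowSites()
  set.seed(5)
  mixed <- c(
    lapply(1:4, function(i)
      makeSterolPose(c(hs$x[i], hs$y[i], hs$z[i]), tiltDeg = 5,
                     azimuthDeg = hs$azimuthDeg[i],
                     hydroxylUp = hs$half[i] == "cytosolic")),
    lapply(1:3, function(i)
      makeSterolPose(c(40 + 10 * i, 0, -8), tiltDeg = 0)))
  kept <- selectPoses(mixed, b)
  expect_length(kept, 4L)
  expect_true(all(vapply(kept, function(p) any(vapply(mixed, identical,
    logical(1), p)), logical(1))))
  expect_length(selectPoses(kept, b), 4L)
})

test_that("pose-to-resolved matching uses ring-centroid distance", {
  p0 <- makeSterolPose(c(3, 4, -8))
  ## identical ring: matched at distance 0
  m <- matchToResolved(list(p0), list(ringCoords(p0)))
  expect_true(m$table$matched)
  expect_equal(m$table$bestDistance, 0, tolerance = 1e-12)
  ## 20 A away: unmatched
  m2 <- matchToResolved(list(p0), list(ringCoords(makeSterolPose(c(3, 24, -8)))))
  expect_false(m2$table$matched)
  expect_equal(m2$matchedFraction, 0)
  ## four planted resolved sites, poses jittered at most 1 A: all matched
  set.seed(9)
  centers <- list(c(0, 0, -8), c(12, 0, -8), c(0, 12, 8), c(-12, 0, 8))
  resolved <- lapply(centers, function(ct) ringCoords(makeSterolPose(ct)))
  jittered <- lapply(centers, function(ct)
    makeSterolPose(ct + runif(3, -0.5, 0.5)))
  m4 <- matchToResolved(jittered, resolved)
  expect_equal(m4$matchedFraction, 1.0)
  expect_error(matchToResolved(list(p0), list()), "no resolved ligands")
})

test_that("energy summaries use the sample standard deviation", {
  s <- summarizeEnergies(c(-15, -14, -13))
  expect_equal(s$mean, -14)
  expect_equal(s$sd, 1)
  expect_false(s$sdFlagged)
  one <- summarizeEnergies(list(makeSterolPose(c(0, 0, -8), energy = -16.8)))
  expect_equal(one$mean, -16.8)
  expect_equal(one$sd, 0)
  expect_true(one$sdFlagged)
  ## translation equivariance of the mean
  set.seed(3)
  e <- rnorm(20, -14, 1)
  expect_equal(summarizeEnergies(e + 2.5)$mean,
               summarizeEnergies(e)$mean + 2.5)
  expect_error(summarizeEnergies(numeric(0)), "no poses")
})
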