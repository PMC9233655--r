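#' @include AllGenerics.R
NULL

## Free-Insig mole fraction given free Scap s, by Insig conservation.
.freeInsig <- function(s, p, cplx) {
  p@xInsigTotal / (1 + p@kaInsigMonomer * p@xChol + s * cplx)
}

#' @rdname speciate
setMethod("speciate", "EquilibriumParameters", function(params) {
  p <- params
  validObject(p)
  c <- p@xChol
  kApo <- if (p@includeApoDimer) p@kSI else 0
  beta <- p@kSI * p@kaDimer * c^p@nCholDimer  # chol-bound dimer, overall
  cplx <- kApo + beta
  ## Scap conservation residual as a function of free Scap; strictly
  ## increasing, so bisection brackets the unique root.
  g <- function(s) s * (1 + .freeInsig(s, p, cplx) * cplx) - p@xScapTotal
  lo <- 0
  hi <- p@xScapTotal
  if (g(hi) < 0) hi <- p@xScapTotal * (1 + 1e-9)  # guard against roundoff
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) < .Machine$double.eps * p@xScapTotal) break
  }
  s <- (lo + hi) / 2
  xI <- .freeInsig(s, p, cplx)
  xSI <- kApo * s * xI
  xSIchol <- beta * s * xI
  xIchol <- p@kaInsigMonomer * c * xI
  res <- c(
    scapConservation = (s + xSI + xSIchol - p@xScapTotal) / p@xScapTotal,
    insigConservation =
      (xI + xIchol + xSI + xSIchol - p@xInsigTotal) / p@xInsigTotal,
    apoDimerMassAction = if (kApo > 0 && xSI > 0)
      xSI / (p@kSI * s * xI) - 1 else 0,
    cholDimerMassAction = if (beta > 0 && xSIchol > 0)
      xSIchol / (beta * s * xI) - 1 else 0,
    insigMonomerMassAction = if (p@kaInsigMonomer > 0 && xIchol > 0)
      xIchol / (p@kaInsigMonomer * c * xI) - 1 else 0)
  new("Speciation", xS = s, xI = xI, xSI = xSI, xSIchol = xSIchol,
      xIchol = xIchol, residuals = res, params = p)
})

#' Species mole fractions as a one-row data.frame
#'
#' @param speciation a [Speciation-class].
#' @return data.frame with columns xS, xI, xSI, xSIchol, xIchol.
#' @export
speciesTable <- function(speciation) {
  data.frame(xS = speciation@xS, xI = speciation@xI, xSI = speciation@xSI,
             xSIchol = speciation@xSIchol, xIchol = speciation@xIchol)
}

#' @rdname cholBoundDimerFraction
setMethod("cholBoundDimerFraction", "EquilibriumParameters",
          function(params) {
  speciate(params)@xSIchol / params@xScapTotal
})

#' @rdname halfMaximalCholesterol
setMethod("halfMaximalCholesterol", "EquilibriumParameters",
          function(params) {
  fOf <- function(c) {
    params@xChol <- c
    cholBoundDimerFraction(params)
  }
  hi <- 1 - 1e-9
  if (fOf(hi) < 0.5)
    stop("saturating below half-maximal: ",
         "cholesterol-bound dimer fraction never reaches 0.5")
  lo <- 0
  while ((hi - lo) > 1e-10) {
    mid <- (lo + hi) / 2
    if (fOf(mid) < 0.5) lo <- mid else hi <- mid
  }
  100 * (lo + hi) / 2
})

#' @rdname titrationCurve
setMethod("titrationCurve", "EquilibriumParameters",
          function(params, xCholGrid) {
  if (is.unsorted(xCholGrid))
    stop("xCholGrid must be sorted increasing")
  if (any(xCholGrid < 0 | xCholGrid >= 1))
    stop("xCholGrid values must lie in [0, 1)")
  rows <- lapply(xCholGrid, function(c) {
    params@xChol <- c
    sp <- speciate(params)
    cbind(data.frame(molPercent = 100 * c,
                     fraction = sp@xSIchol / params@xScapTotal),
          speciesTable(sp))
  })
  do.call(rbind, rows)
})
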