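#' @include AllClasses.R
NULL

#' Convert a molar-scale docking energy to mole-fraction units
#'
#' Membrane solute concentrations are best expressed in mole-fraction units;
#' the standard-state change from molar to mole-fraction units is a constant
#' additive offset (default -0.7 kcal/mol).
#'
#' @param dGmolar docking energy, kcal/mol, molar standard state.
#' @param constants a [ThermoConstants-class].
#' @return Energy in kcal/mol, mole-fraction standard state.
#' @examples
#' toMoleFraction(-16.8)  # -17.5
#' @export
toMoleFraction <- function(dGmolar, constants = thermoConstants()) {
  dGmolar + constants@molarToMoleFractionOffset
}

#' Free energy of a multiplex interfacial hydrogen bond
#'
#' A sterol hydroxyl at the bilayer interface engages several donors at once
#' (a multiplex hydrogen bond), taken to be 60\% stronger than a single
#' canonical hydrogen bond: 1.6 x (-6.5) = -10.4 kcal/mol in mole-fraction
#' units.
#'
#' @param constants a [ThermoConstants-class].
#' @return Energy in kcal/mol.
#' @examples
#' multiplexHbondEnergy()  # -10.4
#' @export
multiplexHbondEnergy <- function(constants = thermoConstants()) {
  constants@multiplexFactor * constants@canonicalHbond
}

#' Remove the interfacial hydrogen-bond term from a binding energy
#'
#' Docking against a receptor flanked by bare interface donor layers counts
#' both ligand-protein interactions and the ligand-interface multiplex
#' hydrogen bond; subtracting the latter leaves the free energy of binding
#' to the protein alone.
#'
#' @param dGmoleFraction binding energy in mole-fraction units, kcal/mol.
#' @param constants a [ThermoConstants-class].
#' @return Corrected energy, kcal/mol.
#' @examples
#' subtractInterfaceHbond(-17.5)  # -7.1
#' @export
subtractInterfaceHbond <- function(dGmoleFraction,
                                   constants = thermoConstants()) {
  dGmoleFraction - multiplexHbondEnergy(constants)
}

#' Association constant from a standard binding free energy
#'
#' \code{Ka = exp(-dG / RT)} (mole-fraction units).
#'
#' @param dG standard free energy of binding, kcal/mol.
#' @param constants a [ThermoConstants-class] (RT = 0.5925 kcal/mol at
#'   298.15 K).
#' @return Dimensionless association constant.
#' @examples
#' signif(associationConstant(-7.1), 2)  # 1.6e5
#' @export
associationConstant <- function(dG, constants = thermoConstants()) {
  exp(-dG / constants@RT)
}

#' Single-site occupancy at a given membrane cholesterol level
#'
#' \code{f = Ka x / (1 + Ka x)} with \code{x = molPercent / 100} the
#' cholesterol mole fraction.
#'
#' @param Ka association constant (mole-fraction units), non-negative.
#' @param molPercent cholesterol level in mol\%, non-negative.
#' @return Occupancy fraction in [0, 1).
#' @examples
#' occupancy(1.4e3, 5)  # about 0.986
#' @export
occupancy <- function(Ka, molPercent) {
  stopifnot(all(Ka >= 0), all(molPercent >= 0))
  x <- molPercent / 100
  Ka * x / (1 + Ka * x)
}

#' Cholesterol level giving 50\% single-site occupancy
#'
#' \code{100 / Ka} mol\% (the level at which \code{Ka x = 1}). Results at or
#' above 100 mol\% are formally valid but unphysical and trigger a warning.
#'
#' @param Ka association constant (mole-fraction units), positive.
#' @return Half-occupancy level in mol\%.
#' @examples
#' halfOccupancyMolPercent(1.6e5)  # 0.000625, i.e. 0.0006 at 1 s.f.
#' @export
halfOccupancyMolPercent <- function(Ka) {
  if (any(Ka == 0))
    stop("Ka must be positive")
  out <- 100 / Ka
  if (any(out >= 100))
    warning("half-occupancy at or above 100 mol% is unphysical")
  out
}

#' Additivity gap between dimer-site and monomer-site binding energies
#'
#' Reports \code{dimer - (scap + insig)} on protein-only (interface-
#' corrected) energies; a gap of zero means the Scap-side and Insig-side
#' contributions to the dimer site are independent.
#'
#' @param dimer,scap,insig protein-only binding energies, kcal/mol, either
#'   bare numbers or rows from [bindingEnergyTable()].
#' @return Gap in kcal/mol (dimer minus monomer sum).
#' @examples
#' additivityGap(-7.1, -2.8, -4.3)  # 0
#' @export
additivityGap <- function(dimer, scap, insig) {
  grab <- function(v) if (is.data.frame(v)) v$dGproteinOnly else v
  grab(dimer) - (grab(scap) + grab(insig))
}

#' Energetic preference for the transmembrane over the luminal surface
#'
#' @param meanTM mean docking energy of transmembrane-domain poses, kcal/mol.
#' @param meanLuminal mean docking energy of luminal-domain poses, kcal/mol.
#' @return \code{meanLuminal - meanTM}, kcal/mol; positive values favour the
#'   transmembrane surface.
#' @examples
#' domainPreference(-15.8, -8.4)  # 7.4
#' @export
domainPreference <- function(meanTM, meanLuminal) {
  meanLuminal - meanTM
}

#' Full docking-energy to association-constant record for one site
#'
#' Applies the chain molar docking energy -> mole-fraction energy ->
#' interface-hydrogen-bond-corrected (protein-only) energy -> association
#' constant.
#'
#' @param site site label.
#' @param dGdockMolar docking energy, kcal/mol, molar standard state.
#' @param constants a [ThermoConstants-class].
#' @return One-row data.frame with columns site, dGdockMolar,
#'   dGmoleFraction, dGproteinOnly, Ka (full precision; display at 2
#'   significant figures to match conventional reporting).
#' @examples
#' energyRecord("dimer", -16.8)
#' @export
energyRecord <- function(site, dGdockMolar, constants = thermoConstants()) {
  stopifnot(is.finite(dGdockMolar))
  dGmf <- toMoleFraction(dGdockMolar, constants)
  dGp <- subtractInterfaceHbond(dGmf, constants)
  data.frame(site = site, dGdockMolar = dGdockMolar, dGmoleFraction = dGmf,
             dGproteinOnly = dGp, Ka = associationConstant(dGp, constants),
             stringsAsFactors = FALSE)
}

#' Binding-energy table for a set of sites
#'
#' @param dGdockMolar named numeric vector of molar docking energies,
#'   kcal/mol.
#' @param constants a [ThermoConstants-class].
#' @return data.frame with one [energyRecord()] row per site.
#' @examples
#' bindingEnergyTable(c(dimer = -16.8, insig = -14.0, scap = -12.5))
#' @export
bindingEnergyTable <- function(dGdockMolar, constants = thermoConstants()) {
  sites <- names(dGdockMolar)
  if (is.null(sites)) sites <- paste0("site", seq_along(dGdockMolar))
  out <- do.call(rbind, lapply(seq_along(dGdockMolar), function(i)
    energyRecord(sites[i], dGdockMolar[[i]], constants)))
  rownames(out) <- NULL
  out
}
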