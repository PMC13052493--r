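# Hemoglobin and water spectroscopy: extinction coefficients, Beer's-law
# composition <-> absorption, and the two-wavelength inversion used to turn
# absorption changes into hemoglobin concentration changes.
#
# Unit conventions used throughout the package:
#   wavelength        nm
#   mua, mus'         mm^-1
#   concentrations    uM
#   extinction eps    decadic, cm^-1 M^-1 (compendium units)
# so that mua[mm^-1] = ln(10) * eps * C[uM] * 1e-7 (+ water term).

# conversion: decadic cm^-1 M^-1 times uM to napierian mm^-1
.KAPPA <- log(10) * 1e-7

.fdnirs_env <- new.env(parent = emptyenv())

#' Packaged extinction and water-absorption table
#'
#' Decadic molar extinction coefficients of oxy- and deoxyhemoglobin
#' (cm^-1 M^-1) and the absorption coefficient of water (mm^-1) on a
#' 650-1000 nm grid (compiled compendium values; Prahl/Gratzer lineage for
#' hemoglobin).
#'
#' @return A data frame with columns `wavelength_nm`, `eps_hbo2_cm1_M1`,
#'   `eps_hb_cm1_M1`, `mua_water_mm1`.
#' @export
extinction_table <- function() {
  if (is.null(.fdnirs_env$extinction)) {
    path <- system.file("extdata", "extinction_hb_water.csv",
                        package = "fdnirs", mustWork = TRUE)
    tab <- utils::read.csv(path)
    stopifnot(all(diff(tab$wavelength_nm) > 0), all(tab$eps_hbo2_cm1_M1 >= 0),
              all(tab$eps_hb_cm1_M1 >= 0), all(tab$mua_water_mm1 >= 0))
    .fdnirs_env$extinction <- tab
  }
  .fdnirs_env$extinction
}

#' Look up extinction coefficients and water absorption
#'
#' Linear interpolation on the packaged 650-1000 nm grid; a query at a grid
#' point returns the tabulated value exactly.
#'
#' @param lambda Wavelength(s) in nm, within the supported 650-1000 nm range.
#' @return A list with numeric elements `epsO`, `epsD` (cm^-1 M^-1) and
#'   `muaWater` (mm^-1), each the length of `lambda`.
#' @export
lookup_extinction <- function(lambda) {
  tab <- extinction_table()
  rng <- range(tab$wavelength_nm)
  if (any(!is.finite(lambda)) || any(lambda < rng[1]) || any(lambda > rng[2]))
    stop("wavelength out of supported range [", rng[1], ", ", rng[2], "] nm")
  list(
    epsO = stats::approx(tab$wavelength_nm, tab$eps_hbo2_cm1_M1, lambda)$y,
    epsD = stats::approx(tab$wavelength_nm, tab$eps_hb_cm1_M1, lambda)$y,
    muaWater = stats::approx(tab$wavelength_nm, tab$mua_water_mm1, lambda)$y
  )
}

#' Tissue chromophore composition
#'
#' @param O Oxyhemoglobin concentration, uM.
#' @param D Deoxyhemoglobin concentration, uM.
#' @param waterFraction Water volume fraction in `[0, 1]`.
#' @param scatteringPower Dimensionless exponent b of the mus' ~ lambda^-b
#'   power law.
#' @param musRef Reduced scattering coefficient at `lambdaRef`, mm^-1.
#' @param lambdaRef Reference wavelength for `musRef`, nm.
#' @return An object of class `tissue_composition`. Total hemoglobin `T = O+D`
#'   and `StO2 = O/T` are derived fields.
#' @export
tissue_composition <- function(O, D, waterFraction = 0, scatteringPower = 1,
                               musRef = 1, lambdaRef = 690) {
  if (O < 0 || D < 0) stop("hemoglobin concentrations must be non-negative")
  if (waterFraction < 0 || waterFraction > 1)
    stop("waterFraction must be within [0, 1]")
  if (musRef <= 0) stop("musRef must be positive")
  structure(list(O = O, D = D, total = O + D,
                 StO2 = if (O + D > 0) O / (O + D) else NA_real_,
                 waterFraction = waterFraction,
                 scatteringPower = scatteringPower,
                 musRef = musRef, lambdaRef = lambdaRef),
            class = "tissue_composition")
}

#' Absorption coefficient from chromophore composition
#'
#' Beer's law with decadic extinction coefficients:
#' `mua = ln(10) (epsO O + epsD D) 1e-7 + waterFraction * muaWater`, in mm^-1.
#'
#' @param comp A [tissue_composition()].
#' @param lambda Wavelength in nm.
#' @param include_water Include the water absorption term (default `TRUE`).
#' @return Absorption coefficient in mm^-1.
#' @export
mua_from_composition <- function(comp, lambda, include_water = TRUE) {
  stopifnot(inherits(comp, "tissue_composition"))
  ext <- lookup_extinction(lambda)
  mua <- .KAPPA * (ext$epsO * comp$O + ext$epsD * comp$D)
  if (include_water) mua <- mua + comp$waterFraction * ext$muaWater
  mua
}

#' Reduced scattering by wavelength power law
#'
#' `mus'(lambda) = musRef * (lambda / lambdaRef)^(-b)`.
#'
#' @param musRef mus' at the reference wavelength, mm^-1.
#' @param b Scattering power (dimensionless).
#' @param lambda Target wavelength, nm.
#' @param lambdaRef Reference wavelength, nm (default 690).
#' @return mus' at `lambda`, mm^-1.
#' @export
mus_prime_power_law <- function(musRef, b, lambda, lambdaRef = 690) {
  if (musRef <= 0) stop("musRef must be positive")
  if (any(lambda <= 0) || lambdaRef <= 0) stop("wavelengths must be positive")
  musRef * (lambda / lambdaRef)^(-b)
}

#' Two-wavelength inversion coefficients
#'
#' Coefficients of the hemoglobin-difference combinations of absorption
#' changes at a wavelength pair, in uM * mm units (for `dmua` in mm^-1 and
#' concentrations in uM):
#' `dT      = aMinus * dmua(lambda1) + bMinus * dmua(lambda2)`
#' `dD - dO = aPlus  * dmua(lambda1) + bPlus  * dmua(lambda2)`
#'
#' @param pair Numeric length-2 wavelength pair in nm, e.g. `c(690, 830)`.
#' @return A list with elements `aPlus`, `aMinus`, `bPlus`, `bMinus` and the
#'   wavelength pair.
#' @export
inversion_coefficients <- function(pair) {
  stopifnot(length(pair) == 2)
  if (pair[1] == pair[2]) stop("degenerate wavelength pair: lambda1 == lambda2")
  e1 <- lookup_extinction(pair[1])
  e2 <- lookup_extinction(pair[2])
  det <- e1$epsO * e2$epsD - e2$epsO * e1$epsD
  if (abs(det) < 1e-12 * (e1$epsO * e2$epsD + e2$epsO * e1$epsD))
    stop("singular extinction matrix for this wavelength pair")
  kd <- .KAPPA * det
  list(aMinus = (e2$epsD - e2$epsO) / kd,
       bMinus = (e1$epsO - e1$epsD) / kd,
       aPlus  = -(e2$epsD + e2$epsO) / kd,
       bPlus  = (e1$epsO + e1$epsD) / kd,
       pair = pair)
}

#' Hemoglobin concentration changes from absorption changes
#'
#' Solves the 2x2 Beer's-law system at a wavelength pair for `dO` and `dD`
#' (uM) from absorption changes (mm^-1); `dT = dO + dD`. Inputs may be
#' vectors (time series), matched element-wise.
#'
#' @param dmua1,dmua2 Absorption changes at `pair[1]` and `pair[2]`, mm^-1.
#' @param pair Wavelength pair in nm.
#' @return A list of numeric vectors `dO`, `dD`, `dT` in uM.
#' @export
delta_hb_from_delta_mua <- function(dmua1, dmua2, pair) {
  stopifnot(length(dmua1) == length(dmua2), all(is.finite(dmua1)),
            all(is.finite(dmua2)))
  if (pair[1] == pair[2]) stop("degenerate wavelength pair: lambda1 == lambda2")
  e1 <- lookup_extinction(pair[1])
  e2 <- lookup_extinction(pair[2])
  M <- .KAPPA * matrix(c(e1$epsO, e2$epsO, e1$epsD, e2$epsD), 2, 2)
  sol <- solve(M, rbind(dmua1, dmua2))
  list(dO = sol[1, ], dD = sol[2, ], dT = sol[1, ] + sol[2, ])
}

#' Convert blood hemoglobin mass concentration to molarity
#'
#' @param massConc Hemoglobin concentration in whole blood, g/dL.
#' @param molarMass Hemoglobin molar mass, g/mol (default 64500).
#' @return Molar concentration in uM.
#' @export
blood_concentration <- function(massConc, molarMass = 64500) {
  if (any(massConc < 0)) stop("mass concentration must be non-negative")
  massConc * 10 / molarMass * 1e6
}

#' Blood volume fraction of a tissue
#'
#' @param tissueT Total hemoglobin concentration in tissue, uM.
#' @param ctHb Hemoglobin concentration in whole blood, uM.
#' @return Dimensionless volume fraction `tissueT / ctHb`.
#' @export
blood_volume_fraction <- function(tissueT, ctHb) {
  if (any(tissueT < 0) || any(ctHb < 0)) stop("inputs must be non-negative")
  if (any(ctHb == 0)) stop("ctHb must be non-zero")
  tissueT / ctHb
}
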