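# Partial generalized pathlengths, normalized layer sensitivities, and the
# two-wavelength ratio engine for effective total-hemoglobin changes (blood
# flow) and effective oxy-deoxy differences (oxygen consumption), plus the
# thickness / optical-property sweeps of the simulation studies.

#' Partial generalized pathlengths of a data type
#'
#' First derivative of the data value (ln ac for intensity, phase for phase;
#' the dual-slope variants differentiate the slope) with respect to each
#' layer's absorption coefficient, by central finite differences on the
#' layered forward model. Units: mm for intensity data (negative: more
#' absorption, less light), rad mm for phase.
#'
#' @param medium A [layered_medium()].
#' @param kind One of [data_type_kinds()].
#' @param delta Finite-difference step in mm^-1 (default 1e-5).
#' @param r_short,r_long Channel separations, mm.
#' @return A list with per-layer derivatives `lk` and their sum `total`.
#' @export
partial_pathlengths <- function(medium, kind, delta = 1e-5,
                                r_short = 25, r_long = 37) {
  kind <- match.arg(kind, data_type_kinds())
  L <- pathlength_matrix(medium, delta, r_short, r_long)
  list(lk = unname(L[, kind]), total = sum(L[, kind]))
}

#' Partial generalized pathlengths of all data types at once
#'
#' Central finite differences of the six data values with respect to each
#' layer's absorption, sharing forward-model evaluations across data types.
#'
#' @inheritParams partial_pathlengths
#' @return Matrix `[layer, kind]` of derivatives (mm or rad mm).
#' @export
pathlength_matrix <- function(medium, delta = 1e-5, r_short = 25,
                              r_long = 37) {
  K <- length(medium$layers)
  L <- t(vapply(seq_len(K), function(k) {
    d <- replace(numeric(K), k, delta)
    yp <- model_datavalues(perturb_mua(medium, d), r_short, r_long)
    ym <- model_datavalues(perturb_mua(medium, -d), r_short, r_long)
    (yp - ym) / (2 * delta)
  }, numeric(6)))
  if (any(!is.finite(L))) stop("non-finite forward response in derivative")
  rownames(L) <- NULL
  L
}

#' Normalized layer sensitivities
#'
#' `S_k = l_k / sum_j l_j`: the partial generalized pathlength of each layer
#' relative to the total generalized pathlength, so that `sum_k S_k = 1`
#' exactly. Sensitivities are wavelength-specific via the medium's properties.
#'
#' @inheritParams partial_pathlengths
#' @return Numeric vector `Sk`, one entry per layer, summing to 1.
#' @export
normalized_sensitivity <- function(medium, kind, delta = 1e-5,
                                   r_short = 25, r_long = 37) {
  kind <- match.arg(kind, data_type_kinds())
  sensitivity_matrix(medium, delta, r_short, r_long)[, kind]
}

#' Normalized layer sensitivities of all data types at once
#'
#' @inheritParams partial_pathlengths
#' @return Matrix `[layer, kind]`, each column summing to 1.
#' @export
sensitivity_matrix <- function(medium, delta = 1e-5, r_short = 25,
                               r_long = 37) {
  L <- pathlength_matrix(medium, delta, r_short, r_long)
  tot <- colSums(L)
  if (any(abs(tot) < .Machine$double.eps * apply(abs(L), 2, max) * 100))
    stop("vanishing total generalized pathlength")
  sweep(L, 2, tot, "/")
}

#' Layered hemodynamic scenario
#'
#' Programmed per-layer hemoglobin changes driving the occlusion simulations:
#' venous mode assigns per-layer total-hemoglobin accumulations `dT_k`
#' (split into oxy/deoxy by an accumulation saturation, default the 75%
#' baseline StO2); arterial mode assigns per-layer desaturations `dD_k` with
#' `dO_k = -dD_k` (no total change).
#'
#' @param mode `"venous"` or `"arterial"`.
#' @param dT Per-layer total-hemoglobin change amplitudes, uM (venous).
#' @param dD Per-layer deoxyhemoglobin change amplitudes, uM (arterial,
#'   all >= 0).
#' @param saturation Oxygen saturation of accumulating blood (venous),
#'   in `[0, 1]`.
#' @return An object of class `hemodynamic_scenario`.
#' @export
hemodynamic_scenario <- function(mode = c("venous", "arterial"), dT = NULL,
                                 dD = NULL, saturation = 0.75) {
  mode <- match.arg(mode)
  if (mode == "venous") {
    if (is.null(dT)) stop("venous scenario needs per-layer dT")
    if (saturation < 0 || saturation > 1)
      stop("saturation must be within [0, 1]")
    amp <- dT
  } else {
    if (is.null(dD)) stop("arterial scenario needs per-layer dD")
    if (any(dD < 0)) stop("arterial dD must be non-negative")
    amp <- dD
  }
  structure(list(mode = mode, amplitude = amp, saturation = saturation),
            class = "hemodynamic_scenario")
}

#' Per-layer absorption changes of a scenario
#'
#' Beer's law per layer and wavelength: venous
#' `dmua_k = ln10 1e-7 (epsO s + epsD (1 - s)) dT_k`; arterial
#' `dmua_k = ln10 1e-7 (epsD - epsO) dD_k` (in mm^-1 for uM amplitudes).
#'
#' @param scenario A [hemodynamic_scenario()].
#' @param pair Wavelength pair, nm.
#' @return Matrix `[layer, wavelength]` of absorption changes in mm^-1.
#' @export
scenario_to_absorption <- function(scenario, pair) {
  stopifnot(inherits(scenario, "hemodynamic_scenario"))
  K <- length(scenario$amplitude)
  vapply(pair, function(lam) {
    e <- lookup_extinction(lam)
    if (scenario$mode == "venous") {
      s <- scenario$saturation
      .KAPPA * (e$epsO * s + e$epsD * (1 - s)) * scenario$amplitude
    } else {
      .KAPPA * (e$epsD - e$epsO) * scenario$amplitude
    }
  }, numeric(K)) |> matrix(nrow = K, ncol = length(pair))
}

# effective absorption change seen by one data type at one wavelength:
# Sk-weighted combination of the per-layer changes
.effective_dmua <- function(S, dmua_col) sum(S * dmua_col)

#' Ratio of effective total-hemoglobin changes between two data types
#'
#' The blood-flow ratio proxy: with `S_k,x(lambda_i)` the normalized layer
#' sensitivities and `a-, b-` the two-wavelength total-hemoglobin inversion
#' coefficients, the effective `dT` of each data type is
#' `a- sum_k S_k(l1) dmua_k(l1) + b- sum_k S_k(l2) dmua_k(l2)` and the result
#' is `dT(kind_num) / dT(kind_den)`.
#'
#' @param kind_num,kind_den Data types forming numerator and denominator
#'   (e.g. `"SDI37"`, `"SDI25"`).
#' @param media Named list of per-wavelength [layered_medium()] objects
#'   (see [make_subject_pair()]), in the order of `pair`.
#' @param change Matrix `[layer, wavelength]` of absorption changes, mm^-1.
#' @param pair Wavelength pair, nm.
#' @param r_short,r_long Channel separations, mm.
#' @param sens Optional precomputed list (one per wavelength) of
#'   [sensitivity_matrix()] results for `media`, to share forward-model work
#'   across ratios.
#' @return The dimensionless ratio.
#' @export
ratio_deltaT <- function(kind_num, kind_den, media, change, pair,
                         r_short = 25, r_long = 37, sens = NULL) {
  .ratio_engine(kind_num, kind_den, media, change, pair, "minus",
                r_short, r_long, sens)
}

#' Ratio of effective (dD - dO) between two data types
#'
#' The oxygen-consumption ratio proxy, identical in structure to
#' [ratio_deltaT()] but with the `a+, b+` coefficients of the oxy-deoxy
#' difference.
#'
#' @inheritParams ratio_deltaT
#' @return The dimensionless ratio.
#' @export
ratio_deoxy_oxy <- function(kind_num, kind_den, media, change, pair,
                            r_short = 25, r_long = 37, sens = NULL) {
  .ratio_engine(kind_num, kind_den, media, change, pair, "plus",
                r_short, r_long, sens)
}

.ratio_engine <- function(kind_num, kind_den, media, change, pair, which,
                          r_short, r_long, sens = NULL) {
  stopifnot(length(media) == 2, nrow(change) == length(media[[1]]$layers),
            ncol(change) == 2)
  co <- inversion_coefficients(pair)
  a <- if (which == "minus") co$aMinus else co$aPlus
  b <- if (which == "minus") co$bMinus else co$bPlus
  if (is.null(sens))
    sens <- lapply(media, sensitivity_matrix, r_short = r_short,
                   r_long = r_long)
  eff <- function(kind) {
    a * .effective_dmua(sens[[1]][, kind], change[, 1]) +
      b * .effective_dmua(sens[[2]][, kind], change[, 2])
  }
  den <- eff(kind_den)
  if (abs(den) < .Machine$double.xmin * 1e10)
    stop("zero denominator in data-type ratio")
  eff(kind_num) / den
}

#' Sweep data-type ratios over layer geometry
#'
#' Computes the effective blood-flow (`dT`) or oxygen-consumption (`dD - dO`)
#' ratio between data-type pairs over a grid of adipose thickness `L1`
#' (two-layer model) or bone depth `L1 + L2` at fixed `L1` (three-layer
#' model), under a programmed per-layer scenario. Deterministic.
#'
#' @param model `"two"` or `"three"` layer model.
#' @param scenario A [hemodynamic_scenario()] with as many amplitudes as the
#'   model has layers.
#' @param pair Wavelength pair, nm.
#' @param L1 Grid of adipose thicknesses, mm (two-layer model), or a single
#'   fixed adipose thickness (three-layer model).
#' @param bone_depth Grid of bone depths `L1 + L2`, mm (three-layer model).
#' @param kind_pairs List of `c(numerator, denominator)` data-type pairs.
#' @param include_water Baseline absorption branch (see [make_subject()]).
#' @param musp1_690 Optional override of the adipose mus' at 690 nm (its
#'   830 nm value follows the layer's power law); used by the
#'   scattering sweep.
#' @param mua1 Optional override of the adipose mua, applied at both
#'   wavelengths; used by the absorption sweep.
#' @return A data frame with columns `L1_mm`, `bone_depth_mm`, `kind_pair`,
#'   `quantity`, `ratio`.
#' @export
sweep_ratios <- function(model = c("two", "three"), scenario,
                         pair = c(690, 830),
                         L1 = seq(1.5, 9.5, length.out = 25),
                         bone_depth = seq(14, 26, length.out = 25),
                         kind_pairs = list(c("SDI37", "SDI25"),
                                           c("SDPhi37", "SDPhi25"),
                                           c("DSI", "SDI25"),
                                           c("DSPhi", "SDPhi25")),
                         include_water = TRUE, musp1_690 = NULL,
                         mua1 = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(scenario, "hemodynamic_scenario"))
  nlay <- if (model == "two") 2L else 3L
  if (length(scenario$amplitude) != nlay)
    stop("scenario must have one amplitude per model layer")
  change <- scenario_to_absorption(scenario, pair)
  quantity <- if (scenario$mode == "venous") "dT" else "dDminusdO"
  ratio_fun <- if (scenario$mode == "venous") ratio_deltaT else ratio_deoxy_oxy

  override <- function(m, lam_idx) {
    if (is.null(musp1_690) && is.null(mua1)) return(m)
    l1 <- m$layers[[1]]
    lam <- pair[lam_idx]
    musp <- if (is.null(musp1_690)) l1$musp else
      mus_prime_power_law(musp1_690, tissue_baseline_params()$scatteringPower[1],
                          lam)
    mua <- if (is.null(mua1)) l1$mua else mua1
    m$layers[[1]] <- optical_layer(mua, musp, l1$thickness)
    m
  }

  configs <- if (model == "two") {
    lapply(L1, function(x) c(L1 = x, bone = NA_real_))
  } else {
    if (length(L1) != 1) stop("three-layer sweep uses a single fixed L1")
    lapply(bone_depth, function(x) c(L1 = L1, bone = x))
  }

  rows <- lapply(configs, function(cf) {
    mtt <- if (model == "two") Inf else cf[["bone"]] - cf[["L1"]]
    if (is.finite(mtt) && mtt <= 0) stop("bone depth must exceed L1")
    media <- make_subject_pair(cf[["L1"]], mtt, pair,
                               include_water = include_water)
    media <- lapply(seq_along(media), function(i) override(media[[i]], i))
    sens <- lapply(media, sensitivity_matrix)
    data.frame(
      L1_mm = cf[["L1"]], bone_depth_mm = cf[["bone"]],
      kind_pair = vapply(kind_pairs, paste, character(1), collapse = "/"),
      quantity = quantity,
      ratio = vapply(kind_pairs, function(kp)
        ratio_fun(kp[1], kp[2], media, change, pair, sens = sens),
        numeric(1)))
  })
  do.call(rbind, rows)
}
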