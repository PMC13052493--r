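# Layered optical media and the muscle/adipose/bone parameterization used in
# the simulation studies (three layers: adipose on top, muscle, bone below;
# the bottom layer extends to infinite depth).

#' A single optical layer
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, mm^-1 (> 0).
#' @param thickness Layer thickness in mm; `Inf` for the bottom layer.
#' @return An object of class `optical_layer`.
#' @export
optical_layer <- function(mua, musp, thickness = Inf) {
  if (!is.finite(mua) || mua < 0) stop("mua must be finite and >= 0")
  if (!is.finite(musp) || musp <= 0) stop("musp must be finite and > 0")
  if (is.na(thickness) || thickness <= 0) stop("thickness must be > 0 or Inf")
  structure(list(mua = mua, musp = musp, thickness = thickness),
            class = "optical_layer")
}

#' A laterally infinite layered medium
#'
#' Ordered layers, top first; the last layer must be semi-infinite. All layers
#' share one refractive index, and the medium carries the source modulation
#' frequency.
#'
#' @param layers List of [optical_layer()] objects (top first). Zero-thickness
#'   layers are dropped.
#' @param n Refractive index (default 1.4, the soft-tissue convention).
#' @param frequency Source modulation frequency in Hz (default 140e6).
#' @return An object of class `layered_medium`.
#' @export
layered_medium <- function(layers, n = 1.4, frequency = 140e6) {
  if (inherits(layers, "optical_layer")) layers <- list(layers)
  layers <- Filter(function(l) l$thickness > 0, lapply(layers, function(l) {
    stopifnot(inherits(l, "optical_layer")); l
  }))
  if (length(layers) < 1) stop("medium needs at least one layer")
  thk <- vapply(layers, `[[`, numeric(1), "thickness")
  if (!is.infinite(thk[length(thk)]))
    stop("the bottom layer must be semi-infinite (thickness = Inf)")
  if (any(is.infinite(thk[-length(thk)])))
    stop("only the bottom layer may be semi-infinite")
  if (n <= 0 || frequency < 0) stop("invalid refractive index or frequency")
  structure(list(layers = layers, n = n, frequency = frequency),
            class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("layered_medium: %d layer(s), n = %g, f = %g MHz\n",
              length(x$layers), x$n, x$frequency / 1e6))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: mua = %.4f mm^-1, mus' = %.3f mm^-1, L = %s mm\n",
                i, l$mua, l$musp,
                if (is.infinite(l$thickness)) "Inf" else format(l$thickness)))
  }
  invisible(x)
}

.medium_mua <- function(medium) vapply(medium$layers, `[[`, numeric(1), "mua")
.medium_musp <- function(medium) vapply(medium$layers, `[[`, numeric(1), "musp")
.medium_thk <- function(medium) vapply(medium$layers, `[[`, numeric(1), "thickness")

# return a copy of `medium` with per-layer absorption increments `dmua`
perturb_mua <- function(medium, dmua) {
  stopifnot(length(dmua) == length(medium$layers))
  layers <- mapply(function(l, d) optical_layer(l$mua + d, l$musp, l$thickness),
                   medium$layers, dmua, SIMPLIFY = FALSE)
  layered_medium(layers, n = medium$n, frequency = medium$frequency)
}

#' Baseline tissue parameterization (adipose / muscle / bone)
#'
#' The per-layer baseline compositions used throughout the simulation studies:
#' oxy-/deoxyhemoglobin concentrations, water volume fraction, scattering
#' power and mus' at the 690 nm reference wavelength for adipose (layer 1),
#' muscle (layer 2) and bone (layer 3).
#'
#' @return A data frame with one row per layer.
#' @export
tissue_baseline_params <- function() {
  data.frame(
    layer = 1:3,
    tissue = c("adipose", "muscle", "bone"),
    O_uM = c(37.5, 75, 37.5),
    D_uM = c(12.5, 25, 12.5),
    waterFraction = c(0.20, 0.80, 0.32),
    scatteringPower = c(0.1, 1, 0.7),
    musp690_mm1 = c(1.0, 0.5, 1.5)
  )
}

# (mua, musp) of a baseline tissue layer at wavelength lambda
tissue_layer_properties <- function(layer, lambda, include_water = TRUE) {
  p <- tissue_baseline_params()[layer, ]
  comp <- tissue_composition(p$O_uM, p$D_uM, p$waterFraction,
                             p$scatteringPower, p$musp690_mm1, 690)
  list(mua = mua_from_composition(comp, lambda, include_water = include_water),
       musp = mus_prime_power_law(p$musp690_mm1, p$scatteringPower, lambda))
}

#' Build a layered medium from forearm anatomy
#'
#' Constructs a two-layer (adipose over semi-infinite muscle) or three-layer
#' (adipose, muscle, semi-infinite bone) medium at one wavelength using the
#' baseline tissue parameterization. A zero adipose thickness degenerates
#' gracefully to one fewer layer.
#'
#' @param att Adipose tissue thickness L1, mm (>= 0).
#' @param mtt Muscle tissue thickness L2, mm; `Inf` gives the two-layer model
#'   (bone depth `att + mtt` then has no meaning).
#' @param lambda Wavelength, nm.
#' @param include_water Include water absorption in baseline mua
#'   (default `TRUE`).
#' @param n,frequency Refractive index and modulation frequency.
#' @return A [layered_medium()].
#' @export
make_subject <- function(att, mtt = Inf, lambda = 690, include_water = TRUE,
                         n = 1.4, frequency = 140e6) {
  if (att < 0 || mtt <= 0) stop("invalid layer thicknesses")
  p2 <- tissue_layer_properties(2, lambda, include_water)
  layers <- list(optical_layer(p2$mua, p2$musp, mtt))
  if (att > 0) {
    p1 <- tissue_layer_properties(1, lambda, include_water)
    layers <- c(list(optical_layer(p1$mua, p1$musp, att)), layers)
  }
  if (is.finite(mtt)) {
    p3 <- tissue_layer_properties(3, lambda, include_water)
    layers <- c(layers, list(optical_layer(p3$mua, p3$musp, Inf)))
  }
  layered_medium(layers, n = n, frequency = frequency)
}

#' Media at both wavelengths of a pair
#'
#' Convenience wrapper around [make_subject()] returning one medium per
#' wavelength of a pair, as used by the two-wavelength ratio and occlusion
#' machinery.
#'
#' @inheritParams make_subject
#' @param pair Wavelength pair, nm.
#' @return A named list of two [layered_medium()] objects.
#' @export
make_subject_pair <- function(att, mtt = Inf, pair = c(690, 830),
                              include_water = TRUE, n = 1.4,
                              frequency = 140e6) {
  out <- lapply(pair, function(l)
    make_subject(att, mtt, l, include_water, n, frequency))
  names(out) <- as.character(pair)
  out
}
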