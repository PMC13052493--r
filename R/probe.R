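# Measurement channels and data types: single-distance intensity/phase at 25
# and 37 mm, dual-slope intensity/phase from the symmetric 1AB2 arrangement,
# and the self-calibrating baseline fit of absolute mua / mus'.

#' FD-NIRS data-type kinds
#'
#' The six data types: single-distance intensity and phase at the short and
#' long separations (`SDI25`, `SDI37`, `SDPhi25`, `SDPhi37`) and dual-slope
#' intensity and phase (`DSI`, `DSPhi`).
#'
#' @return Character vector of the six kind names.
#' @export
data_type_kinds <- function() c("SDI25", "SDI37", "SDPhi25", "SDPhi37",
                                "DSI", "DSPhi")

.kind_is_phase <- function(kind) grepl("Phi", kind)
.kind_is_ds <- function(kind) grepl("^DS", kind)

#' Collinear symmetric probe geometry
#'
#' Default positions (mm along the probe) source1 = 0, detectorA = 25,
#' detectorB = 37, source2 = 62, giving two short channels at 25 mm (1A, 2B),
#' two long channels at 37 mm (1B, 2A) and one dual-slope set (1AB2). The
#' arrangement must be symmetric about its midpoint.
#'
#' @param source1,detectorA,detectorB,source2 Positions in mm.
#' @return An object of class `probe_geometry` with a `channels` table
#'   (channel, source, detector, distance_mm).
#' @export
probe_geometry <- function(source1 = 0, detectorA = 25, detectorB = 37,
                           source2 = 62) {
  d <- c(`1A` = abs(detectorA - source1), `1B` = abs(detectorB - source1),
         `2A` = abs(detectorA - source2), `2B` = abs(detectorB - source2))
  if (!isTRUE(all.equal(d[["1A"]], d[["2B"]])) ||
      !isTRUE(all.equal(d[["1B"]], d[["2A"]])))
    stop("geometry must be symmetric: |1A| = |2B| and |1B| = |2A|")
  if (d[["1A"]] >= d[["1B"]]) stop("detectorA must be the short channel")
  structure(list(
    positions = c(source1 = source1, detectorA = detectorA,
                  detectorB = detectorB, source2 = source2),
    channels = data.frame(
      channel = c("1A", "1B", "2A", "2B"),
      source = c("1", "1", "2", "2"),
      detector = c("A", "B", "A", "B"),
      distance_mm = as.numeric(d[c("1A", "1B", "2A", "2B")]))),
    class = "probe_geometry")
}

#' Single-distance data value
#'
#' The data value entering slopes and the modified Beer-Lambert law:
#' `Y = ln(ac)` for intensity, `Y = phase` (radians) for phase.
#'
#' @param ac AC amplitude (> 0); ignored for `kind = "phase"`.
#' @param phase Phase in radians; ignored for `kind = "intensity"`.
#' @param kind `"intensity"` or `"phase"`.
#' @return Numeric data value.
#' @export
sd_datavalue <- function(ac = NULL, phase = NULL,
                         kind = c("intensity", "phase")) {
  kind <- match.arg(kind)
  if (kind == "intensity") {
    if (is.null(ac) || any(ac <= 0)) stop("ac must be positive")
    log(ac)
  } else {
    if (is.null(phase) || any(!is.finite(phase))) stop("phase must be finite")
    phase
  }
}

#' Dual-slope data value
#'
#' Average of the two paired slopes of the symmetric arrangement,
#' `DS = 0.5 [ (Y(1B) - Y(1A)) + (Y(2A) - Y(2B)) ] / (r_long - r_short)`,
#' with `Y = ln(r^2 ac)` for intensity and `Y = phase` for phase. Any
#' per-source or per-detector multiplicative gain (intensity) or additive
#' offset (phase) cancels exactly.
#'
#' @param readings A data frame with columns `channel` (1A, 1B, 2A, 2B), `ac`,
#'   `phase_rad` and `distance_mm`; `ac`/`phase_rad` entries may be vectors
#'   laid out in long format (one row per channel per time point with a shared
#'   `time` ordering), but the canonical use is one row per channel.
#' @param kind `"intensity"` or `"phase"`.
#' @return Slope in mm^-1 (intensity) or rad/mm (phase).
#' @export
dual_slope <- function(readings, kind = c("intensity", "phase")) {
  kind <- match.arg(kind)
  need <- c("1A", "1B", "2A", "2B")
  if (!all(need %in% readings$channel))
    stop("dual slope needs all four channels 1A, 1B, 2A, 2B")
  get <- function(ch) readings[readings$channel == ch, , drop = FALSE]
  y <- function(row) {
    if (kind == "intensity") log(row$distance_mm^2 * row$ac) else row$phase_rad
  }
  a1 <- get("1A"); b1 <- get("1B"); a2 <- get("2A"); b2 <- get("2B")
  dr <- b1$distance_mm[1] - a1$distance_mm[1]
  0.5 * ((y(b1) - y(a1)) + (y(a2) - y(b2))) / dr
}

# Model data values of all six data-type kinds for a medium (layered or
# 1-layer) from a single forward evaluation at both distances; intensity
# slope variable is ln(r^2 ac).
model_datavalues <- function(medium, r_short = 25, r_long = 37, tol = 1e-8) {
  resp <- layered_fd_reflectance(medium, c(r_short, r_long), tol = tol)
  dr <- r_long - r_short
  c(SDI25 = log(resp$ac[1]), SDI37 = log(resp$ac[2]),
    SDPhi25 = resp$phase[1], SDPhi37 = resp$phase[2],
    DSI = (log(r_long^2 * resp$ac[2]) - log(r_short^2 * resp$ac[1])) / dr,
    DSPhi = (resp$phase[2] - resp$phase[1]) / dr)
}

model_datavalue <- function(medium, kind, r_short = 25, r_long = 37,
                            tol = 1e-8) {
  kind <- match.arg(kind, data_type_kinds())
  model_datavalues(medium, r_short, r_long, tol)[[kind]]
}

# Model dual-slope pair (intensity, phase) from the homogeneous closed form;
# used by the self-calibrating fit.
.model_ds_slopes <- function(mua, musp, n, frequency, r_short, r_long) {
  resp <- homogeneous_fd_reflectance(mua, musp, n, frequency,
                                     c(r_short, r_long))
  c(int = (log(r_long^2 * resp$ac[2]) - log(r_short^2 * resp$ac[1])) /
      (r_long - r_short),
    phase = (resp$phase[2] - resp$phase[1]) / (r_long - r_short))
}

#' Self-calibrating baseline fit of absolute optical properties
#'
#' Inverts the homogeneous semi-infinite model so that its two-distance
#' dual-slope intensity and phase slopes reproduce a measured pair, yielding
#' absolute `mua` and `mus'` without instrument calibration. The initial
#' guess comes from the infinite-medium analytic slope relations
#' (`k ~ -S_ac + i S_phi`); Newton iterations with a finite-difference
#' Jacobian refine it against the true semi-infinite closed form.
#'
#' @param ds_int_slope Dual-slope intensity slope, mm^-1 (must be < 0).
#' @param ds_phase_slope Dual-slope phase slope, rad/mm (must be > 0).
#' @param n Refractive index.
#' @param frequency Modulation frequency, Hz.
#' @param r_short,r_long The two separations, mm.
#' @param tol Convergence tolerance on the slope residuals.
#' @return A list with `mua` and `musp` in mm^-1 plus fit diagnostics.
#' @export
fit_baseline_selfcal <- function(ds_int_slope, ds_phase_slope, n = 1.4,
                                 frequency = 140e6, r_short = 25, r_long = 37,
                                 tol = 1e-12) {
  if (!is.finite(ds_int_slope) || ds_int_slope >= 0)
    stop("dual-slope intensity slope must be negative")
  if (!is.finite(ds_phase_slope) || ds_phase_slope <= 0)
    stop("dual-slope phase slope must be positive")
  omega <- 2 * pi * frequency
  v <- .C_MM_S / n
  # infinite-medium initial guess
  musp0 <- max(-2 * ds_int_slope * ds_phase_slope * v / (3 * omega), 1e-3)
  mua0 <- max((ds_int_slope^2 - ds_phase_slope^2) / (3 * musp0), 1e-4)

  target <- c(ds_int_slope, ds_phase_slope)
  x <- log(c(mua0, musp0))
  f <- function(x) {
    p <- exp(x)
    .model_ds_slopes(p[1], p[2], n, frequency, r_short, r_long) - target
  }
  res <- f(x)
  for (it in seq_len(60)) {
    if (max(abs(res)) < tol * max(abs(target))) break
    J <- matrix(0, 2, 2)
    hstep <- 1e-6
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + hstep
      xm <- x; xm[j] <- xm[j] - hstep
      J[, j] <- (f(xp) - f(xm)) / (2 * hstep)
    }
    step <- tryCatch(solve(J, res), error = function(e)
      stop("self-calibrating fit: singular Jacobian"))
    # damped update, keeping parameters in a physical range
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      resn <- tryCatch(f(xn), error = function(e) NULL)
      if (!is.null(resn) && all(is.finite(resn)) &&
          sum(resn^2) < sum(res^2) * (1 - 1e-4 * lambda) + 1e-300) {
        x <- xn; res <- resn; break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8)
        stop("self-calibrating fit did not converge (line search failed)")
    }
  }
  if (max(abs(res)) >= tol * max(abs(target)) * 10)
    stop("self-calibrating fit did not converge within iteration budget")
  p <- exp(x)
  list(mua = p[1], musp = p[2], residual = res, iterations = it)
}
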