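# Independent oracles used by the tests. These are deliberately separate
# codings of textbook results, kept free of the package's internal routines.

# Independently coded semi-infinite FD reflectance: extrapolated-boundary
# image-source solution, written in explicit real/imaginary arithmetic.
oracle_homogeneous_fd <- function(mua, musp, n, f, r) {
  c_mm_s <- 2.99792458e11
  v <- c_mm_s / n
  w <- 2 * pi * f
  D <- 1 / (3 * musp)
  # k = sqrt((mua + i w/v)/D) via polar decomposition
  re <- mua / D
  im <- w / (v * D)
  mod_k <- (re^2 + im^2)^0.25
  arg_k <- atan2(im, re) / 2
  k <- complex(modulus = mod_k, argument = arg_k)
  reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + reff) / (1 - reff)
  z0 <- 1 / musp
  zb <- 2 * A * D
  rho1 <- sqrt(r^2 + z0^2)
  rho2 <- sqrt(r^2 + (z0 + 2 * zb)^2)
  (exp(-k * rho1) / rho1 - exp(-k * rho2) / rho2) / (4 * pi * D)
}

# Richardson-extrapolated central-difference derivative of f at x
oracle_richardson <- function(f, x, h) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# Brute-force data-type ratio: effective per-kind absorption changes ->
# direct two-wavelength Beer's-law inversion (solve()) -> ratio of dT or
# of (dD - dO). Independent of the package's a+/-, b+/- coefficient path.
oracle_ratio <- function(kind_num, kind_den, sens, change, pair,
                         quantity = c("dT", "dDmdO")) {
  quantity <- match.arg(quantity)
  ext <- lapply(pair, lookup_extinction)
  M <- log(10) * 1e-7 *
    matrix(c(ext[[1]]$epsO, ext[[2]]$epsO, ext[[1]]$epsD, ext[[2]]$epsD),
           2, 2)
  val <- function(kind) {
    dmua <- c(sum(sens[[1]][, kind] * change[, 1]),
              sum(sens[[2]][, kind] * change[, 2]))
    hb <- solve(M, dmua)
    if (quantity == "dT") hb[1] + hb[2] else hb[2] - hb[1]
  }
  val(kind_num) / val(kind_den)
}

# shared fixture media (computed once per test run)
.fixture_env <- new.env()

fixture_two_layer_pair <- function() {
  if (is.null(.fixture_env$two))
    .fixture_env$two <- make_subject_pair(7, Inf)
  .fixture_env$two
}

fixture_three_layer_pair <- function() {
  if (is.null(.fixture_env$three))
    .fixture_env$three <- make_subject_pair(3, 12)
  .fixture_env$three
}

fixture_muscle_homogeneous_pair <- function() {
  if (is.null(.fixture_env$muscle)) {
    .fixture_env$muscle <- lapply(c(690, 830), function(lam) {
      p <- fdnirs:::tissue_layer_properties(2, lam)
      layered_medium(list(optical_layer(p$mua, p$musp, Inf)))
    })
  }
  .fixture_env$muscle
}
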