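# Meridional (R = 0) diffraction from per-monomer axial positions. On the
# meridian only the n = 0 Bessel term of the helical transform survives, so
# the axial positions of the subunit centres determine the profile; the full
# layer-line machinery is not needed.

#' Reciprocal-space window around a reflection order
#'
#' @param order reflection order n (>= 1)
#' @param s0 real-space repeat, nm (default 2.73)
#' @param halfwidth relative half-width of the window (default 0.02)
#' @return numeric `c(Zlo, Zhi)` in 1/nm; attribute `center` = n/s0
#' @examples
#' peakOrderWindow(2)   # centred at 0.7326 1/nm, i.e. 1.365 nm spacing
#' @export
peakOrderWindow <- function(order, s0 = 2.73, halfwidth = 0.02) {
  if (order < 1) stop("order must be >= 1")
  ctr <- order / s0
  out <- c(ctr * (1 - halfwidth), ctr * (1 + halfwidth))
  attr(out, "center") <- ctr
  out
}

#' Uniform evaluation grid for a reflection window
#'
#' At least `pointsPerPct` points per 1% of relative width (default 2000),
#' so metrology on different orders uses comparable resolution.
#'
#' @inheritParams peakOrderWindow
#' @param pointsPerPct grid density, points per 1% relative window
#' @return numeric vector of Z values, 1/nm
#' @export
orderGrid <- function(order, s0 = 2.73, halfwidth = 0.02,
                      pointsPerPct = 2000) {
  w <- peakOrderWindow(order, s0, halfwidth)
  n <- max(16L, ceiling(2 * halfwidth / 0.01 * pointsPerPct)) + 1L
  seq(w[1], w[2], length.out = n)
}

# squared uniform-sphere form factor for subunit diameter D (nm):
# f(Z) = 3 (sin u - u cos u) / u^3 with u = pi Z D
sphereFormFactor2 <- function(Z, diameter) {
  u <- pi * Z * diameter
  f <- ifelse(abs(u) < 1e-8, 1, 3 * (sin(u) - u * cos(u)) / u^3)
  f^2
}

#' Meridional intensity from monomer positions
#'
#' For each filament with monomer axial positions z_j the meridional
#' amplitude is `A(Z) = sum_j f(Z) exp(2 pi i Z z_j)` and its intensity
#' `|A(Z)|^2`; the ensemble profile is the incoherent sum of the
#' per-filament intensities (no axial register between filaments is
#' assumed). Scatterers are points (`f = 1`) unless a subunit diameter is
#' given, in which case a uniform-sphere form factor is applied.
#'
#' @param positions a numeric vector (one filament), a matrix (monomers in
#'   rows, filaments in columns) or a list of numeric vectors
#' @param Z reciprocal axial grid, 1/nm, strictly increasing
#' @param mode only `"incoherent_filaments"`
#' @param subunitDiameter optional subunit diameter, nm, for the sphere form
#'   factor; `NULL` (default) for point scatterers
#' @return a \linkS4class{MeridionalProfile}
#' @examples
#' Z <- orderGrid(1)
#' p <- meridionalIntensity(uniformFilament(364, 2.73), Z)
#' max(p@intensity)    # 364^2 on the reflection
#' @export
meridionalIntensity <- function(positions, Z,
                                mode = "incoherent_filaments",
                                subunitDiameter = NULL) {
  mode <- match.arg(mode)
  if (is.numeric(positions) && is.null(dim(positions)))
    positions <- list(positions)
  if (is.matrix(positions))
    positions <- lapply(seq_len(ncol(positions)), function(i) positions[, i])
  if (!length(positions)) stop("need at least one filament")
  if (any(!vapply(positions, length, 1L))) stop("empty position set")
  Z <- as.numeric(Z)
  if (length(Z) > 1 && any(diff(Z) <= 0)) stop("Z grid must be strictly increasing")
  ff2 <- if (is.null(subunitDiameter)) numeric(0) else
    sphereFormFactor2(Z, subunitDiameter)
  # evaluate per maximal uniform chunk so the fast phase recurrence applies
  chunks <- uniformChunks(Z)
  I <- numeric(length(Z))
  for (ch in chunks) {
    f2 <- if (length(ff2)) ff2[ch] else numeric(0)
    I[ch] <- cxx_meridional_intensity(positions, Z[ch], f2)
  }
  meridionalProfile(Z, I, metadata = list(
    nFilaments = length(positions), mode = mode,
    formFactor = if (is.null(subunitDiameter)) "point" else
      paste0("sphere:", subunitDiameter), beam = FALSE))
}

# split indices of Z into maximal runs of uniform step
uniformChunks <- function(Z) {
  n <- length(Z)
  if (n < 3) return(list(seq_len(n)))
  d <- diff(Z)
  brk <- which(abs(diff(d)) > 1e-9 * stats::median(d))
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n - 1L)
  mapply(function(s, e) s:(e + 1L), starts, ends, SIMPLIFY = FALSE)
}

#' Convolve a profile with the beam axial profile
#'
#' Discrete convolution with a unit-area Gaussian kernel of the beam's FWHM;
#' total integrated intensity is conserved (peaks get lower and wider). The
#' grid must resolve the kernel: spacing < fwhm / 5.
#'
#' @param profile a \linkS4class{MeridionalProfile} on a uniform grid
#' @param beam a \linkS4class{BeamModel}
#' @return the convolved \linkS4class{MeridionalProfile}
#' @export
convolveBeam <- function(profile, beam) {
  validObject(beam)
  Z <- profile@Z
  dZ <- diff(Z)
  if (max(dZ) - min(dZ) > 1e-9 * stats::median(dZ))
    stop("convolveBeam needs a uniform grid; convolve each window separately")
  dZ <- stats::median(dZ)
  if (dZ >= beam@fwhm / 5)
    stop(sprintf("grid too coarse for the beam: spacing %.3g >= fwhm/5 = %.3g",
                 dZ, beam@fwhm / 5))
  sigma <- beam@fwhm / (2 * sqrt(2 * log(2)))
  r <- ceiling(6 * sigma / dZ)
  kern <- stats::dnorm(seq(-r, r) * dZ, sd = sigma)
  kern <- kern / sum(kern)
  x <- profile@intensity
  n <- length(x)
  pad <- function(v) c(rep(0, r), v, rep(0, r))
  win <- (r + 1):(r + n)
  # per-source renormalization at the window edges keeps the integrated
  # intensity exactly conserved
  cov <- as.numeric(stats::filter(pad(rep(1, n)), kern, sides = 2)[win])
  y <- stats::filter(pad(x / cov), kern, sides = 2)[win]
  md <- profile@metadata
  md$beam <- TRUE
  md$beamFwhm <- beam@fwhm
  meridionalProfile(Z, as.numeric(y), md)
}
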