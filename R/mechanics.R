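# Quasi-static mechanical equilibrium of the extensible-filament spring
# network, crossbridge strains, and spacing/tension profiles.

# net nodal forces for the current configuration, used both as a solver
# guard and in force-balance assertions
latticeResidual <- function(lattice) {
  g <- lattice@geometry; e <- lattice@elastic
  s0 <- g@monomerSpacing
  ka <- e@Ka / s0
  km <- e@Km / g@crownSpacing
  kb0 <- e@Km / lattice@bareLength
  az <- lattice@actinZ; my <- lattice@myosinZ
  nm <- nrow(az); nc <- nrow(my)
  fThin <- matrix(0, nm, ncol(az))
  ten <- ka * (az[-1, , drop = FALSE] - az[-nm, , drop = FALSE] - s0)
  fThin[-nm, ] <- fThin[-nm, ] + ten
  fThin[-1, ] <- fThin[-1, ] - ten
  fThick <- matrix(0, nc, ncol(my))
  fThick[1, ] <- kb0 * (lattice@anchorZ - my[1, ] - lattice@bareLength)
  tenM <- km * (my[-nc, , drop = FALSE] - my[-1, , drop = FALSE] -
                  g@crownSpacing)
  fThick[-1, ] <- fThick[-1, ] + tenM
  fThick[-nc, ] <- fThick[-nc, ] - tenM
  tip0 <- lattice@anchorZ - lattice@bareLength - (nc - 1) * g@crownSpacing
  fThick[nc, ] <- fThick[nc, ] - e@titinStiffness * (my[nc, ] - tip0)
  att <- lattice@attachments
  if (nrow(att)) {
    xs <- crossbridgeGeometry(lattice)
    for (i in seq_len(nrow(att))) {
      fThin[att$monomer[i], att$thin[i]] <-
        fThin[att$monomer[i], att$thin[i]] + xs$force[i]
      fThick[xs$crown[i], xs$thick[i]] <-
        fThick[xs$crown[i], xs$thick[i]] - xs$force[i]
    }
  }
  max(abs(fThin[-1, ]), abs(fThick))
}

crossbridgeGeometry <- function(lattice, strokeD = 10.5) {
  att <- lattice@attachments
  info <- headInfo(att$head, lattice@geometry)
  y <- lattice@myosinZ[cbind(info$crown, info$thick)]
  z <- lattice@actinZ[cbind(att$monomer, att$thin)]
  off <- ifelse(att$state == 3L, strokeD, 0)
  x <- y - z
  data.frame(head = att$head, thick = info$thick, crown = info$crown,
             thin = att$thin, monomer = att$monomer, state = att$state,
             x = x, force = lattice@elastic@kappaXb * (x + off))
}

#' Solve the elastic equilibrium of the lattice
#'
#' Finds node positions at which the net force on every free node (all actin
#' monomers except the Z-disc anchor, all myosin crowns) is below `tol`.
#' Thin and thick chains are solved exactly (tridiagonal) in alternation
#' until the coupled system converges; the stiffness matrix is symmetric
#' positive definite under the isometric boundary conditions (Z-disc end of
#' each thin filament and M-band anchor of each thick filament fixed), so
#' the iteration is guaranteed to converge.
#'
#' @param lattice a \linkS4class{HalfSarcomereLattice}
#' @param tol force tolerance, pN (default 1e-6)
#' @param maxit maximum sweeps
#' @param strokeD power stroke distance used as the state-3 zero-strain
#'   offset, nm
#' @return the lattice with updated node positions; attributes `iterations`
#'   and `residual` report solver effort.
#' @export
solveEquilibrium <- function(lattice, tol = 1e-6, maxit = 2000,
                             strokeD = 10.5) {
  if (tol <= 0) stop("tol must be > 0")
  res <- cxx_solve_equilibrium(latticeToList(lattice), strokeD, tol,
                               as.integer(maxit))
  lattice@actinZ <- res$actinZ
  lattice@myosinZ <- res$myosinZ
  attr(lattice, "iterations") <- res$iterations
  attr(lattice, "residual") <- res$residual
  lattice
}

#' Crossbridge strains and forces
#'
#' For every attachment, the strain `x = crown position - monomer position`
#' and the axial force `kappa * (x + offset)` transmitted to the actin
#' filament (positive toward the M-band), where the offset is 0 in state 2
#' and the power stroke distance d in state 3. Requires a solved lattice.
#'
#' @param lattice a solved \linkS4class{HalfSarcomereLattice}
#' @param strokeD power stroke distance, nm
#' @param checkTol error if the residual net nodal force exceeds this (pN);
#'   set to `Inf` to skip the guard
#' @return data.frame with head, thin, monomer, state, `x` (nm), `force` (pN)
#' @export
crossbridgeStrains <- function(lattice, strokeD = 10.5, checkTol = 0.1) {
  if (!nrow(lattice@attachments))
    return(crossbridgeGeometry(lattice, strokeD)[0, ])
  if (is.finite(checkTol) && latticeResidual(lattice) > checkTol)
    stop("lattice is not in mechanical equilibrium; call solveEquilibrium()")
  crossbridgeGeometry(lattice, strokeD)[
    , c("head", "thin", "monomer", "state", "x", "force")]
}

#' Tension and spacing profile along one thin filament
#'
#' The tension in segment j (between monomers j and j+1) is the sum of the
#' crossbridge axial forces applied at monomers above j; it is spatially
#' constant in the I-band (non-overlap) region and decays toward the tip.
#' The local spacing follows `s_j = s0 (1 + F_j / Ka)` segment-wise.
#'
#' @param lattice a solved \linkS4class{HalfSarcomereLattice}
#' @param filament thin filament index
#' @param strokeD power stroke distance, nm
#' @return data.frame with `position` (segment midpoint, nm from the
#'   Z-disc), `spacing` (nm) and `tension` (pN)
#' @export
filamentTensionProfile <- function(lattice, filament, strokeD = 10.5) {
  Tn <- ncol(lattice@actinZ)
  if (filament < 1 || filament > Tn) stop("invalid thin filament id")
  z <- lattice@actinZ[, filament]
  nm <- length(z)
  load <- numeric(nm)
  att <- lattice@attachments
  if (nrow(att)) {
    xs <- crossbridgeGeometry(lattice, strokeD)
    sel <- xs$thin == filament
    if (any(sel))
      load[xs$monomer[sel]] <- load[xs$monomer[sel]] + xs$force[sel]
  }
  # tension in segment j = sum of loads at monomer indices > j
  tension <- rev(cumsum(rev(load)))[-1]
  data.frame(position = (z[-nm] + z[-1]) / 2, spacing = diff(z),
             tension = tension)
}

#' Ensemble spacing statistics along the thin filament
#'
#' Pointwise mean and SD, across thin filaments, of the inter-monomer
#' spacing. Accepts either a lattice (single configuration) or a
#' \linkS4class{SimulationTrace}, in which case every (filament, plateau
#' snapshot) pair is an ensemble member, i.e. the statistics describe the
#' instantaneous filament-to-filament variability. The SD is also reported
#' relative to the maximum spacing change observed in the ensemble
#' (attribute `sdRelMax`).
#'
#' @param x a \linkS4class{HalfSarcomereLattice} or
#'   \linkS4class{SimulationTrace} with snapshots
#' @return data.frame with `position` (nm), `meanSpacing`, `sdSpacing` (nm);
#'   attributes `s0`, `maxChange` and `sdRelMax`.
#' @export
ensembleSpacingStats <- function(x) {
  if (is(x, "SimulationTrace")) {
    if (!length(x@snapshots)) stop("trace holds no snapshots")
    s0 <- x@lattice@geometry@monomerSpacing
    perFil <- do.call(cbind, lapply(x@snapshots, function(s)
      apply(s, 2, diff)))
    pos <- ((0:(nrow(perFil) - 1)) + 0.5) * s0
  } else if (is(x, "HalfSarcomereLattice")) {
    s0 <- x@geometry@monomerSpacing
    perFil <- apply(x@actinZ, 2, diff)
    pos <- ((0:(nrow(perFil) - 1)) + 0.5) * s0
  } else stop("x must be a HalfSarcomereLattice or SimulationTrace")
  if (ncol(perFil) < 2) stop("need at least 2 filaments in the ensemble")
  m <- rowMeans(perFil)
  sdv <- apply(perFil, 1, sd)
  out <- data.frame(position = pos, meanSpacing = m, sdSpacing = sdv)
  maxChange <- max(perFil - s0)
  attr(out, "s0") <- s0
  attr(out, "maxChange") <- maxChange
  attr(out, "sdRelMax") <- if (maxChange > 0) max(sdv) / maxChange else NA_real_
  out
}

# mean-to-plateau ratio g of a spacing-change profile: mean spacing change
# over the whole filament divided by its I-band plateau value
gRatioFromProfile <- function(stats, geometry) {
  s0 <- attr(stats, "s0")
  if (is.null(s0)) s0 <- geometry@monomerSpacing
  ob <- overlapBounds(geometry)
  ds <- stats$meanSpacing - s0
  iband <- stats$position < ob$zLo
  if (!any(iband)) stop("no I-band segments in the profile")
  plateau <- mean(ds[iband])
  if (plateau <= 0) return(NA_real_)
  mean(ds) / plateau
}
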