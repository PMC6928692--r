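# Half-sarcomere lattice construction: filament node chains, head wiring,
# overlap geometry. Frame: z = 0 at the Z-disc, increasing toward the M-band.

#' Relaxed filament node positions and overlap interval
#'
#' Computes the axial interval of the thin filament that is covered by myosin
#' crowns at the given sarcomere length. The thin filament occupies
#' `[0, nMonomers * s0]` nm; the thick filament hangs from the M-band at
#' `SL/2` with a bare zone before the first crown, crowns every 14.3 nm.
#' The I-band side non-overlap length is `thin length - overlap length`.
#'
#' @param geometry a \linkS4class{SarcomereGeometry}
#' @return list with `zLo`, `zHi` (nm, overlap interval on the thin
#'   filament), `overlapLength`, `nonOverlapLength` (nm) and the crown
#'   interval `crownLo`, `crownHi`.
#' @examples
#' ob <- overlapBounds(sarcomereGeometry())
#' ob$overlapLength            # ~634 nm at SL 2.3 um
#' @export
overlapBounds <- function(geometry) {
  validObject(geometry)
  halfSL <- geometry@sarcomereLength * 1000 / 2
  thinLen <- geometry@nMonomers * geometry@monomerSpacing
  halfThick <- geometry@thickLength * 1000 / 2
  crownSpan <- (geometry@nCrowns - 1L) * geometry@crownSpacing
  bare <- halfThick - crownSpan
  if (bare <= 0)
    stop("crown span exceeds the half-thick filament length")
  crownLo <- halfSL - halfThick      # Z-disc-most crown
  crownHi <- halfSL - bare           # M-band-most crown
  zLo <- max(0, crownLo)
  zHi <- min(thinLen, crownHi)
  ov <- zHi - zLo
  if (ov <= 0)
    stop("no thick-thin filament overlap at sarcomere length ",
         geometry@sarcomereLength, " um")
  list(zLo = zLo, zHi = zHi, overlapLength = ov,
       nonOverlapLength = thinLen - ov, crownLo = crownLo, crownHi = crownHi)
}

# global head index: head j (1..hpc) of crown c (1..nc) of thick f (1..F)
headIndex <- function(f, c, j, geometry) {
  nc <- geometry@nCrowns; hpc <- geometry@headsPerCrown
  (f - 1L) * nc * hpc + (c - 1L) * hpc + j
}

headInfo <- function(head, geometry) {
  nc <- geometry@nCrowns; hpc <- geometry@headsPerCrown
  perF <- nc * hpc
  h0 <- head - 1L
  list(thick = h0 %/% perF + 1L,
       crown = (h0 %% perF) %/% hpc + 1L,
       headInCrown = h0 %% hpc + 1L)
}

# Azimuthal wiring: thick filament f has six neighbouring thin filaments
# (2f-2 .. 2f+3, periodic); head j of crown c points to one of the six,
# cycling so even crowns serve directions {0,2,4} and odd crowns {1,3,5}.
# Periodic (toroidal) assignment avoids lattice edge effects and gives every
# thin filament exactly three facing thick filaments and 75 facing heads.
headThinWiring <- function(geometry, nThick) {
  nc <- geometry@nCrowns; hpc <- geometry@headsPerCrown
  Tn <- 2L * nThick
  H <- nThick * nc * hpc
  ht <- integer(H)
  for (f in seq_len(nThick)) {
    nb <- ((2L * (f - 1L) - 2L + 0:5) %% Tn) + 1L
    for (c in seq_len(nc)) {
      for (j in seq_len(hpc)) {
        k <- (2L * (j - 1L) + (c - 1L) %% 2L) %% 6L + 1L
        ht[headIndex(f, c, j, geometry)] <- nb[k]
      }
    }
  }
  ht
}

#' Build a relaxed half-sarcomere lattice
#'
#' Constructs the explicit half sarcomere: `nThick` thick filaments in a
#' periodic hexagonal arrangement, each surrounded by six thin filaments at
#' 2:1 thin:thick stoichiometry, with one node per actin monomer and one per
#' myosin crown. All monomers start at their relaxed positions `j * s0` and
#' there are no attachments.
#'
#' @param geometry a \linkS4class{SarcomereGeometry}
#' @param elastic an \linkS4class{ElasticParams}
#' @param nThick number of thick filaments (>= 1); thin filaments are
#'   `2 * nThick`
#' @param seed integer seed recorded in the lattice (construction itself is
#'   deterministic)
#' @return a \linkS4class{HalfSarcomereLattice}
#' @examples
#' lat <- buildHalfSarcomere(sarcomereGeometry(), elasticParams(), nThick = 2)
#' lat
#' @export
buildHalfSarcomere <- function(geometry = sarcomereGeometry(),
                               elastic = elasticParams(),
                               nThick = geometry@nThick, seed = 1L) {
  validObject(geometry); validObject(elastic)
  nThick <- as.integer(nThick)
  if (is.na(nThick) || nThick < 1L)
    stop("nThick must be >= 1 (empty lattice rejected)")
  ob <- overlapBounds(geometry)   # errors if no overlap / bad SL
  if (ob$crownLo < 0)
    stop("sarcomere too short: thick filament crosses the Z-disc")
  halfSL <- geometry@sarcomereLength * 1000 / 2
  thinLen <- geometry@nMonomers * geometry@monomerSpacing
  if (thinLen >= halfSL)
    stop("thin filament crosses the M-band at this sarcomere length")
  nm <- geometry@nMonomers; nc <- geometry@nCrowns
  Tn <- 2L * nThick
  actinZ <- matrix(rep((0:(nm - 1L)) * geometry@monomerSpacing, Tn),
                   nrow = nm, ncol = Tn)
  halfThick <- geometry@thickLength * 1000 / 2
  crownSpan <- (nc - 1L) * geometry@crownSpacing
  bare <- halfThick - crownSpan
  myosinZ <- matrix(rep(halfSL - bare - (0:(nc - 1L)) * geometry@crownSpacing,
                        nThick), nrow = nc, ncol = nThick)
  geo <- geometry
  geo@nThick <- nThick
  geo@nThin <- Tn
  new("HalfSarcomereLattice", geometry = geo, elastic = elastic,
      actinZ = actinZ, myosinZ = myosinZ, anchorZ = halfSL,
      bareLength = bare, headThin = headThinWiring(geometry, nThick),
      attachments = emptyAttachments(), seed = as.integer(seed))
}

emptyAttachments <- function() {
  data.frame(head = integer(), thin = integer(), monomer = integer(),
             state = integer())
}

# plain-list view consumed by the compiled core
latticeToList <- function(lattice) {
  list(actinZ = lattice@actinZ, myosinZ = lattice@myosinZ,
       anchorZ = lattice@anchorZ, bareLength = lattice@bareLength,
       s0 = lattice@geometry@monomerSpacing,
       crownSpacing = lattice@geometry@crownSpacing,
       headsPerCrown = lattice@geometry@headsPerCrown,
       headThin = lattice@headThin, attachments = lattice@attachments,
       Ka = lattice@elastic@Ka, Km = lattice@elastic@Km,
       kappaXb = lattice@elastic@kappaXb,
       titinStiffness = lattice@elastic@titinStiffness)
}

#' Candidate actin binding sites for a myosin head
#'
#' Returns the monomer sites on the head's reachable thin filament whose
#' axial offset `x = crown position - monomer position` (positive when the
#' site lies Z-disc-ward of the head) is within `reach`. Offsets are computed
#' from the current, possibly deformed, node positions.
#'
#' @param head global head index (1-based)
#' @param lattice a \linkS4class{HalfSarcomereLattice}
#' @param reach search half-width, nm (default 8)
#' @return data.frame with columns `thin`, `monomer`, `x` (nm) and
#'   `occupied`; zero rows when the head faces no overlap.
#' @export
candidateSites <- function(head, lattice, reach = 8) {
  H <- length(lattice@headThin)
  if (head < 1 || head > H) stop("head index out of range")
  info <- headInfo(head, lattice@geometry)
  y <- lattice@myosinZ[info$crown, info$thick]
  t <- lattice@headThin[head]
  z <- lattice@actinZ[, t]
  sel <- which(abs(y - z) <= reach)
  occ <- logical(length(sel))
  if (nrow(lattice@attachments)) {
    occ <- paste(t, sel) %in%
      paste(lattice@attachments$thin, lattice@attachments$monomer)
  }
  data.frame(thin = rep(t, length(sel)), monomer = sel, x = y - z[sel],
             occupied = occ)
}

#' Attach a crossbridge by hand
#'
#' Low-level constructor used in tests and worked examples: binds `head` to
#' `monomer` on its wired thin filament in the given state, without running
#' kinetics. The mechanical equilibrium is not re-solved; call
#' [solveEquilibrium()] afterwards.
#'
#' @param lattice a \linkS4class{HalfSarcomereLattice}
#' @param head global head index
#' @param monomer monomer index on the head's target thin filament
#' @param state 2 (weakly attached) or 3 (post-stroke)
#' @return the lattice with the attachment added
#' @export
attachHead <- function(lattice, head, monomer, state = 2L) {
  H <- length(lattice@headThin)
  if (head < 1 || head > H) stop("head index out of range")
  if (!state %in% c(2L, 3L)) stop("state must be 2 or 3")
  t <- lattice@headThin[head]
  if (monomer < 1 || monomer > nrow(lattice@actinZ))
    stop("monomer index out of range")
  att <- lattice@attachments
  if (any(att$head == head)) stop("head already attached")
  if (any(att$thin == t & att$monomer == monomer))
    stop("monomer site already occupied")
  lattice@attachments <- rbind(att, data.frame(
    head = as.integer(head), thin = t, monomer = as.integer(monomer),
    state = as.integer(state)))
  validObject(lattice)
  lattice
}
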