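# Independent oracles used in tests: a dense spring-network assembler and
# solver (base R, no shared code with the compiled solver), the finite
# lattice (Dirichlet kernel) closed form for uniform filaments, and the
# analytic stationary distribution of the three-state cycle.

# dense equilibrium: assemble the full stiffness system of a lattice and
# solve with base R
denseEquilibriumOracle <- function(lattice, strokeD = 10.5) {
  g <- lattice@geometry; e <- lattice@elastic
  nm <- nrow(lattice@actinZ); Tn <- ncol(lattice@actinZ)
  nc <- nrow(lattice@myosinZ); F <- ncol(lattice@myosinZ)
  s0 <- g@monomerSpacing; h <- g@crownSpacing
  ka <- e@Ka / s0; km <- e@Km / h; kb0 <- e@Km / lattice@bareLength
  tip0 <- lattice@anchorZ - lattice@bareLength - (nc - 1) * h

  # unknown indices: thin (t, j>=2) then thick (f, c)
  thinIdx <- function(t, j) (t - 1L) * (nm - 1L) + (j - 1L)
  nThinU <- Tn * (nm - 1L)
  thickIdx <- function(f, c) nThinU + (f - 1L) * nc + c
  nU <- nThinU + F * nc
  K <- matrix(0, nU, nU); b <- numeric(nU)

  # spring between lower node i1 and upper node i2 with rest r:
  # E = k/2 (z2 - z1 - r)^2. 0 index = fixed node with position `fixedPos`.
  addSpring <- function(i1, i2, k, r, fixedPos = 0) {
    if (i1 > 0 && i2 > 0) {
      K[i1, i1] <<- K[i1, i1] + k; K[i2, i2] <<- K[i2, i2] + k
      K[i1, i2] <<- K[i1, i2] - k; K[i2, i1] <<- K[i2, i1] - k
      b[i2] <<- b[i2] + k * r; b[i1] <<- b[i1] - k * r
    } else if (i2 > 0) {  # lower fixed
      K[i2, i2] <<- K[i2, i2] + k
      b[i2] <<- b[i2] + k * (fixedPos + r)
    } else {              # upper fixed
      K[i1, i1] <<- K[i1, i1] + k
      b[i1] <<- b[i1] + k * (fixedPos - r)
    }
  }
  for (t in seq_len(Tn)) {
    addSpring(0, thinIdx(t, 2), ka, s0, fixedPos = lattice@actinZ[1, t])
    for (j in 2:(nm - 1))
      addSpring(thinIdx(t, j), thinIdx(t, j + 1), ka, s0)
  }
  for (f in seq_len(F)) {
    addSpring(thickIdx(f, 1), 0, kb0, lattice@bareLength,
              fixedPos = lattice@anchorZ)
    if (nc > 1) for (c in 1:(nc - 1))
      addSpring(thickIdx(f, c + 1), thickIdx(f, c), km, h)
    if (e@titinStiffness > 0)
      addSpring(0, thickIdx(f, nc), e@titinStiffness, tip0, fixedPos = 0)
  }
  att <- lattice@attachments
  if (nrow(att)) {
    info <- sarcoXray:::headInfo(att$head, g)
    for (i in seq_len(nrow(att))) {
      off <- if (att$state[i] == 3L) strokeD else 0
      i1 <- if (att$monomer[i] == 1L) 0L else thinIdx(att$thin[i], att$monomer[i])
      addSpring(i1, thickIdx(info$thick[i], info$crown[i]),
                e@kappaXb, -off, fixedPos = lattice@actinZ[1, att$thin[i]])
    }
  }
  u <- solve(K, b)
  out <- lattice
  for (t in seq_len(Tn))
    out@actinZ[2:nm, t] <- u[thinIdx(t, 2:nm)]
  for (f in seq_len(F))
    out@myosinZ[, f] <- u[thickIdx(f, seq_len(nc))]
  out
}

# finite-lattice closed form for N point scatterers at uniform spacing h
dirichletIntensity <- function(N, h, Z) {
  den <- sin(pi * Z * h)
  ifelse(abs(den) < 1e-10, N^2, (sin(N * pi * Z * h) / den)^2)
}

# analytic stationary distribution of the three-state cycle at fixed strain
analyticStationary3 <- function(x, params = rateParams(), kappaXb = 1.3) {
  r <- transitionRates(x, params, kappaXb)
  Q <- matrix(c(-(r$k12 + r$k13), r$k12, r$k13,
                r$k21, -(r$k21 + r$k23), r$k23,
                r$k31, r$k32, -(r$k31 + r$k32)),
              nrow = 3, byrow = TRUE)
  A <- rbind(t(Q), rep(1, 3))
  pi <- qr.solve(A, c(0, 0, 0, 1))
  pmax(pi, 0) / sum(pmax(pi, 0))
}
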