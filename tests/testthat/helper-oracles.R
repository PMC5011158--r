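# Independent oracles, deliberately coded step by step and kept free of
# any package internals so they can disagree with the implementation.

# --- second implementation of the PEOE recurrence ------------------------
# parameters re-typed from the published polynomial table
.oracleGM <- function(element, hyb) {
  tab <- list(
    "H"     = c(7.17, 6.24, -0.56),
    "C sp3" = c(7.98, 9.18, 1.88),
    "C sp2" = c(8.79, 9.32, 1.51),
    "C sp"  = c(10.39, 9.45, 0.73),
    "N sp3" = c(11.54, 10.82, 1.36),
    "N sp2" = c(12.87, 11.15, 0.85),
    "N sp"  = c(15.68, 11.70, -0.27),
    "O sp3" = c(14.18, 12.92, 1.39),
    "O sp2" = c(17.07, 13.79, 0.47),
    "F sp3" = c(14.66, 13.85, 2.31),
    "Cl sp3" = c(11.00, 9.69, 1.35),
    "Br sp3" = c(10.08, 8.47, 1.16),
    "I sp3" = c(9.90, 7.96, 0.96),
    "S sp3" = c(10.14, 9.13, 1.38),
    "P sp3" = c(8.90, 8.24, 0.96))
  key <- if (element == "H") "H" else paste(element, hyb)
  tab[[key]]
}

# elements: character; hybs: character ("sp3"/"sp2"/"sp"); bonds: 2-col
# matrix; q0: starting charges. One damped charge transfer per bond per
# iteration, electronegativities frozen at the iteration start.
referencePeoe <- function(elements, hybs, bonds, q0 = NULL,
                          iterations = 6, damping = 0.5) {
  nat <- length(elements)
  if (is.null(q0)) q0 <- rep(0, nat)
  abc <- matrix(0, nat, 3)
  for (i in seq_len(nat)) abc[i, ] <- .oracleGM(elements[i], hybs[i])
  cation <- abc[, 1] + abc[, 2] + abc[, 3]
  cation[elements == "H"] <- 20.02
  q <- q0
  for (it in seq_len(iterations)) {
    chi <- numeric(nat)
    for (i in seq_len(nat))
      chi[i] <- abc[i, 1] + abc[i, 2] * q[i] + abc[i, 3] * q[i]^2
    delta <- rep(0, nat)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]
      j <- bonds[b, 2]
      if (chi[i] == chi[j]) next
      if (chi[i] < chi[j]) {
        donor <- i; acceptor <- j
      } else {
        donor <- j; acceptor <- i
      }
      moved <- (chi[acceptor] - chi[donor]) / cation[donor] * damping^it
      delta[donor] <- delta[donor] + moved
      delta[acceptor] <- delta[acceptor] - moved
    }
    q <- q + delta
  }
  q
}

# --- brute-force descriptor kernels --------------------------------------
bruteRdf <- function(coords, p, bin, B = 100, at = "midpoint") {
  r <- (bin - 1) * 0.1 + if (at == "midpoint") 0.05 else 0
  n <- nrow(coords)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      total <- total + p[i] * p[j] * exp(-B * (r - dij)^2)
    }
  }
  total
}

bruteAutocorr <- function(coords, p, bin) {
  n <- nrow(coords)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (dij >= bin && dij < bin + 1) total <- total + p[i] * p[j]
    }
  }
  total
}

# random proper rotation matrix from a QR decomposition
randomRotation <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# bare point-set molecule with a single property channel "p"
pointMolecule <- function(coords, p) {
  m <- Molecule3D("points",
                  atoms = data.frame(element = "C", charge = 0L,
                                     x = coords[, 1], y = coords[, 2],
                                     z = coords[, 3]))
  atomChannel(m, "p") <- p
  m
}

# quercetin, the reference flavonol used across chemistry tests
quercetinSmiles <- "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12 quercetin"

readQuercetin <- function() {
  readStructures(quercetinSmiles, format = "smiles", text = TRUE)[[1]]
}

# run the full selection cascade on a planted dataset, return selected names
runCascade <- function(d, pEnter = 0.05, pRemove = 0.10) {
  std <- standardizeDescriptors(datasetX(d))
  y <- datasetY(d)
  k1 <- correlationFilter(std$Z, y)
  Z1 <- std$Z[, k1, drop = FALSE]
  k2 <- redundancyFilter(Z1, y)
  Z2 <- Z1[, k2, drop = FALSE]
  stepwiseMLR(Z2, y, pEnter = pEnter, pRemove = pRemove)
}
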