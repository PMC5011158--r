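# Hueckel-type pi-charge model on the conjugated subgraph.
#
# Atoms carrying a double, triple or aromatic bond form the pi framework;
# lone-pair donors (N, O, S, halogens without a multiple bond) adjacent to
# a framework atom join it as two-electron contributors. Each connected
# component is solved as an independent Hueckel problem: the secular
# matrix has Coulomb terms h_X on the diagonal and resonance factors k_XY
# on bonds (in units of |beta|, alpha = 0 convention), electrons fill the
# highest eigenvalues two per orbital with degenerate shells shared
# equally, and the pi charge of an atom is its electron contribution minus
# its Mulliken pi population. Formal charges are accounted in the sigma
# start of PEOE, so contributions here are reduced accordingly and every
# system's pi charges sum to zero.

# Streitwieser-style Coulomb parameters by element and electron contribution
.huckelH <- function(el, nContrib) {
  key <- paste0(el, nContrib)
  h <- c(C1 = 0, C0 = 0, C2 = 0,
         N1 = 0.5, N2 = 1.5,
         O1 = 1.0, O2 = 2.0,
         S1 = 0.4, S2 = 1.3,
         F2 = 3.0, Cl2 = 2.0, Br2 = 1.5, I2 = 1.2,
         P1 = 0.2, P2 = 0.8)
  out <- h[key]
  if (anyNA(out))
    stop("no Hueckel Coulomb parameter for: ",
         paste(unique(key[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

# resonance factor for a bond: 1 between one-electron (sp2 framework)
# atoms, attenuated towards two-electron donors and heavy heteroatoms
.huckelK <- function(el1, n1, el2, n2) {
  att <- c(C = 1.0, N = 0.9, O = 0.8, S = 0.6, F = 0.7,
           Cl = 0.4, Br = 0.3, I = 0.25, P = 0.6)
  k1 <- if (n1 == 2L) att[el1] else if (el1 == "C") 1.0 else sqrt(att[el1])
  k2 <- if (n2 == 2L) att[el2] else if (el2 == "C") 1.0 else sqrt(att[el2])
  unname(sqrt(as.numeric(k1) * as.numeric(k2)))
}

# logical: atom participates in a multiple/aromatic bond
.piFramework <- function(mol) {
  n <- nAtoms(mol)
  b <- molBonds(mol)
  out <- logical(n)
  for (k in seq_len(nrow(b)))
    if (b$order[k] >= 2L) out[c(b$i[k], b$j[k])] <- TRUE
  out
}

# framework atoms plus adjacent lone-pair donors
.piSystemAtoms <- function(mol) {
  fw <- .piFramework(mol)
  el <- atomElements(mol)
  b <- molBonds(mol)
  donor <- logical(nAtoms(mol))
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (fw[i] && !fw[j] && el[j] %in% c("N", "O", "S", "F", "Cl", "Br", "I", "P"))
      donor[j] <- TRUE
    if (fw[j] && !fw[i] && el[i] %in% c("N", "O", "S", "F", "Cl", "Br", "I", "P"))
      donor[i] <- TRUE
  }
  fw | donor
}

#' Hueckel-type pi charges
#'
#' Computes per-atom pi charges on each conjugated system of the molecular
#' graph by a deterministic Hueckel calculation (see the model notes in the
#' package vignette). Atoms outside any conjugated system get 0; the pi
#' charges of each system sum to 0.
#'
#' @param mol a [Molecule3D-class].
#' @return numeric vector of pi charges (e), one per atom.
#' @examples
#' m <- readStructures("c1ccccc1 benzene", format = "smiles", text = TRUE)[[1]]
#' piCharges(m)  # six zeros on carbon, zeros on hydrogen
#' @export
piCharges <- function(mol) {
  .stopIfNot(is(mol, "Molecule3D"), "mol must be a Molecule3D")
  n <- nAtoms(mol)
  q <- numeric(n)
  fw <- .piFramework(mol)
  inPi <- .piSystemAtoms(mol)
  if (!any(inPi)) return(q)
  el <- atomElements(mol)
  chg <- mol@atoms$charge
  # electron contribution: 1 for framework atoms, 2 for lone-pair donors,
  # reduced by positive formal charge (clamped to [0, 2])
  contrib <- integer(n)
  contrib[fw] <- 1L
  contrib[inPi & !fw] <- 2L
  contrib <- pmin(pmax(contrib - chg * as.integer(inPi), 0L), 2L)
  b <- molBonds(mol)
  # connected components of the pi system (via bonds among member atoms)
  comp <- integer(n)
  nc <- 0L
  nb <- .graphNeighbours(n, b)
  for (s in which(inPi)) {
    if (comp[s]) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nb[[v]]) {
        if (inPi[w] && !comp[w]) { comp[w] <- nc; queue <- c(queue, w) }
      }
    }
  }
  for (cid in seq_len(nc)) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    idx <- match(seq_len(n), members)
    m <- length(members)
    M <- matrix(0, m, m)
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      if (!is.na(idx[i]) && !is.na(idx[j])) {
        kk <- .huckelK(el[i], contrib[i], el[j], contrib[j])
        M[idx[i], idx[j]] <- M[idx[j], idx[i]] <- kk
      }
    }
    diag(M) <- .huckelH(el[members], contrib[members])
    eg <- eigen(M, symmetric = TRUE)
    ne <- sum(contrib[members])
    # fill descending eigenvalues, 2 electrons per MO, degenerate shells
    # (|delta lambda| < 1e-9) occupied equally
    occ <- numeric(m)
    remaining <- ne
    lam <- eg$values
    i0 <- 1L
    while (remaining > 0 && i0 <= m) {
      shell <- which(abs(lam - lam[i0]) < 1e-9 & seq_len(m) >= i0)
      cap <- 2 * length(shell)
      fill <- min(remaining, cap)
      occ[shell] <- fill / length(shell)
      remaining <- remaining - fill
      i0 <- max(shell) + 1L
    }
    pop <- as.vector((eg$vectors^2) %*% occ)
    q[members] <- contrib[members] - pop
  }
  q
}
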