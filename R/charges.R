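# Gasteiger-Marsili electronegativity polynomial coefficients (a, b, c),
# chi(q) = a + b q + c q^2, eV-like units; keyed by element.hybridization.
# Values reproduce the classic PEOE parameterization (checked against an
# independent implementation on methane/water/ethanol to 5 decimals).
.gmParams <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F.sp3  = c(14.66, 13.85, 2.31),
  Cl.sp3 = c(11.00, 9.69, 1.35),
  Br.sp3 = c(10.08, 8.47, 1.16),
  I.sp3  = c(9.90, 7.96, 0.96),
  S.sp3  = c(10.14, 9.13, 1.38),
  P.sp3  = c(8.90, 8.24, 0.96)
)

# hybridization from the bond table: sp for a triple bond (or cumulated
# doubles), sp2 for any double/aromatic bond, sp3 otherwise
.hybridization <- function(mol) {
  n <- nAtoms(mol)
  b <- molBonds(mol)
  nDouble <- nTriple <- nArom <- integer(n)
  for (k in seq_len(nrow(b))) {
    idx <- c(b$i[k], b$j[k])
    if (b$order[k] == 2L) nDouble[idx] <- nDouble[idx] + 1L
    if (b$order[k] == 3L) nTriple[idx] <- nTriple[idx] + 1L
    if (b$order[k] == 4L) nArom[idx] <- nArom[idx] + 1L
  }
  ifelse(nTriple > 0L | nDouble >= 2L, "sp",
         ifelse(nDouble > 0L | nArom > 0L, "sp2", "sp3"))
}

.gmTable <- function(mol) {
  el <- atomElements(mol)
  hyb <- .hybridization(mol)
  key <- ifelse(el == "H", "H", paste(el, hyb, sep = "."))
  # halogens / S / P carry a single parameter set
  single <- el %in% c("F", "Cl", "Br", "I", "S", "P")
  key[single] <- paste(el[single], "sp3", sep = ".")
  bad <- !key %in% names(.gmParams)
  if (any(bad)) {
    w <- which(bad)[1L]
    stop("element '", el[w], "' (atom ", w,
         ") is outside the PEOE parameter set", call. = FALSE)
  }
  t(vapply(key, function(k) .gmParams[[k]], numeric(3)))
}

#' PEOE (Gasteiger-Marsili) sigma charges
#'
#' Iterative partial equalization of orbital electronegativity. Atom
#' electronegativity is the polynomial `chi(q) = a + b q + c q^2`; at each
#' iteration `k` the charge transferred across a bond is
#' `(chi_j - chi_i) / chi+_donor * damping^k`, where `chi+` is the cation
#' electronegativity (`a + b + c`) of the momentarily less electronegative
#' partner (20.02 for hydrogen). Charges start from the formal charges, so
#' the net molecular charge is conserved exactly.
#'
#' @param mol a [Molecule3D-class] with explicit hydrogens.
#' @param iterations number of equalization iterations (default 6).
#' @param damping attenuation base; iteration `k` is damped by `damping^k`.
#' @return numeric vector of sigma charges (e), one per atom.
#' @examples
#' m <- readStructures("C methane", format = "smiles", text = TRUE)[[1]]
#' q <- peoeSigma(m)
#' sum(q)  # 0 to machine precision
#' @export
peoeSigma <- function(mol, iterations = 6L, damping = 0.5) {
  .stopIfNot(is(mol, "Molecule3D"), "mol must be a Molecule3D")
  P <- .gmTable(mol)
  el <- atomElements(mol)
  b <- molBonds(mol)
  q <- as.numeric(mol@atoms$charge)
  chiplus <- P[, 1] + P[, 2] + P[, 3]
  chiplus[el == "H"] <- 20.02
  for (k in seq_len(iterations)) {
    chi <- P[, 1] + P[, 2] * q + P[, 3] * q^2
    dq <- numeric(length(q))
    f <- damping^k
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (lo == i) j else i
      d <- (chi[hi] - chi[lo]) / chiplus[lo] * f
      dq[lo] <- dq[lo] + d
      dq[hi] <- dq[hi] - d
    }
    q <- q + dq
  }
  unname(q)
}

# residual electronegativity chi(q) at given charges, all atoms
.residualEN <- function(mol, q) {
  P <- .gmTable(mol)
  unname(P[, 1] + P[, 2] * q + P[, 3] * q^2)
}

# elements that carry at least one lone pair in their usual valence state
.lonePairBearing <- function(mol) {
  el <- atomElements(mol)
  b <- molBonds(mol)
  deg <- integer(nAtoms(mol))
  for (k in seq_len(nrow(b))) {
    deg[b$i[k]] <- deg[b$i[k]] + 1L
    deg[b$j[k]] <- deg[b$j[k]] + 1L
  }
  ch <- mol@atoms$charge
  (el %in% c("O", "S") & ch <= 0L) |
    (el %in% c("N", "P") & deg <= 3L & ch <= 0L) |
    el %in% c("F", "Cl", "Br", "I")
}

#' Lone-pair electronegativities
#'
#' The PEOE residual electronegativity `chi(q) = a + b q + c q^2`
#' evaluated at the converged sigma charge, reported for lone-pair-bearing
#' atoms (N, O, S, P with a free valence; halogens) and 0 elsewhere.
#'
#' @param mol a [Molecule3D-class].
#' @param sigma optional precomputed [peoeSigma()] vector.
#' @return numeric vector (eV-like units), strictly positive where defined.
#' @export
lonePairEN <- function(mol, sigma = peoeSigma(mol)) {
  en <- .residualEN(mol, sigma)
  ifelse(.lonePairBearing(mol), en, 0)
}

#' Compute all per-atom property channels
#'
#' Populates the eight property channels used by the descriptor engine:
#' `SigChg` (PEOE sigma charges), `PiChg` (Hueckel-type pi charges),
#' `TotChg` (their sum), `LpEN` (lone-pair electronegativities), `SigEN`
#' (residual sigma electronegativity of every atom), `PiEN` (residual
#' electronegativity restricted to pi-system atoms; a documented
#' placeholder channel), `Polariz` (atomic polarizabilities, Angstrom^3),
#' and `Ident` (unit weights). Only the first four are used by the
#' published model; the remainder complete the 8-channel descriptor
#' registry.
#'
#' @param mol a [Molecule3D-class] with explicit hydrogens.
#' @param iterations,damping passed to [peoeSigma()].
#' @return the molecule with all channels attached.
#' @examples
#' m <- readStructures("c1ccccc1 benzene", format = "smiles", text = TRUE)[[1]]
#' m <- computeChannels(m)
#' channelNames(m)
#' @export
computeChannels <- function(mol, iterations = 6L, damping = 0.5) {
  sig <- peoeSigma(mol, iterations, damping)
  pic <- piCharges(mol)
  en <- .residualEN(mol, sig)
  pol <- .atomPolarizability[atomElements(mol)]
  if (anyNA(pol))
    stop("no polarizability value for element(s): ",
         paste(unique(atomElements(mol)[is.na(pol)]), collapse = ", "),
         call. = FALSE)
  piAtoms <- .piSystemAtoms(mol)
  mol@channels <- list(
    SigChg = sig,
    PiChg = pic,
    TotChg = sig + pic,
    LpEN = ifelse(.lonePairBearing(mol), en, 0),
    SigEN = en,
    PiEN = ifelse(piAtoms, en, 0),
    Polariz = unname(pol),
    Ident = rep(1, nAtoms(mol))
  )
  validObject(mol)
  mol
}

# static atomic (dipole) polarizabilities, Angstrom^3
.atomPolarizability <- c(H = 0.667, C = 1.76, N = 1.10, O = 0.802,
                         F = 0.557, P = 3.63, S = 2.90, Cl = 2.18,
                         Br = 3.05, I = 5.35)

#' Export per-atom channels as a tidy table
#'
#' @param mols a [Molecule3D-class] (with channels) or a list of them.
#' @param path optional CSV output path.
#' @return a `data.frame` with one row per atom: molecule id, atom index,
#'   element, and one column per channel; written to `path` when given.
#' @export
exportChannels <- function(mols, path = NULL) {
  if (is(mols, "Molecule3D")) mols <- list(mols)
  tabs <- lapply(mols, function(m) {
    .stopIfNot(length(m@channels) > 0,
               "molecule '", molId(m), "' has no channels; run computeChannels()")
    cbind(data.frame(molecule = molId(m), atom = seq_len(nAtoms(m)),
                     element = atomElements(m)),
          as.data.frame(m@channels))
  })
  out <- do.call(rbind, tabs)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
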