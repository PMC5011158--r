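# canonical channel order for the 8-property descriptor families
.channelOrder <- c("SigChg", "PiChg", "TotChg", "LpEN",
                   "SigEN", "PiEN", "Polariz", "Ident")

.pairData <- function(mol, property) {
  p <- if (is.character(property)) atomChannel(mol, property) else property
  .stopIfNot(length(p) == nAtoms(mol),
             "property vector length must equal the atom count")
  X <- atomCoords(mol)
  .stopIfNot(all(is.finite(X)), "molecule '", molId(mol),
             "' has no finite coordinates; run embed3d() first")
  n <- nrow(X)
  .stopIfNot(n >= 2L, "descriptor kernels need at least 2 atoms")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  d <- sqrt((X[i, 1] - X[j, 1])^2 + (X[i, 2] - X[j, 2])^2 +
            (X[i, 3] - X[j, 3])^2)
  list(d = d, w = p[i] * p[j])
}

#' Radial distribution function (RDF) descriptors
#'
#' Property-weighted RDF values
#' `g(r_k) = sum_{i<j} p_i p_j exp(-B (r_k - r_ij)^2)`, evaluated at the
#' representative radius of each named bin. Bin `k` covers the range
#' `[(k-1) * 0.1, k * 0.1)` Angstrom (so bin 86 is 8.5-8.6 A), with
#' `r_k` the bin midpoint by default.
#'
#' @param mol a [Molecule3D-class] with coordinates and channels.
#' @param property channel name (see [computeChannels()]) or a numeric
#'   per-atom vector.
#' @param bins integer bin indices in 1..128.
#' @param B Gaussian smoothing parameter (1/Angstrom^2), default 100.
#' @param at `"midpoint"` (default) or `"left"`: where in the bin the
#'   kernel is evaluated.
#' @return named numeric vector, one value per requested bin.
#' @examples
#' atoms <- data.frame(element = "C", charge = 0L,
#'                     x = c(0, 5.35), y = 0, z = 0)
#' m <- Molecule3D("pair", atoms)
#' rdfDescriptor(m, rep(1, 2), bins = 54)  # exactly 1 at the bin midpoint
#' @export
rdfDescriptor <- function(mol, property, bins = 1:128, B = 100,
                          at = c("midpoint", "left")) {
  at <- match.arg(at)
  bins <- as.integer(bins)
  if (any(bins < 1L | bins > 128L))
    stop("RDF bin index must be in 1..128", call. = FALSE)
  pd <- .pairData(mol, property)
  r <- (bins - 1L) * 0.1 + if (at == "midpoint") 0.05 else 0
  out <- vapply(r, function(rk) sum(pd$w * exp(-B * (rk - pd$d)^2)), 0)
  names(out) <- as.character(bins)
  out
}

#' 3D autocorrelation descriptors
#'
#' Unnormalized spatial autocorrelation (Moreau-Broto form):
#' `A(k) = sum_{i<j} p_i p_j` over atom pairs whose 3D distance falls in
#' `[k, k+1)` Angstrom. Bins are 1 Angstrom wide and start at 1 Angstrom,
#' so bin 9 covers 9-10 A; pairs closer than 1 A or at 13 A and beyond
#' contribute to no bin.
#'
#' @inheritParams rdfDescriptor
#' @param bins integer bin indices in 1..12.
#' @return named numeric vector, one value per requested bin.
#' @export
autocorr3dDescriptor <- function(mol, property, bins = 1:12) {
  bins <- as.integer(bins)
  if (any(bins < 1L | bins > 12L))
    stop("3D autocorrelation bin index must be in 1..12", call. = FALSE)
  pd <- .pairData(mol, property)
  out <- vapply(bins, function(k) sum(pd$w[pd$d >= k & pd$d < k + 1]), 0)
  names(out) <- as.character(bins)
  out
}

#' Distance range of a named descriptor bin
#'
#' @param k bin index.
#' @param family `"RDF"` (bins of 0.1 A) or `"3DACorr"` (bins of 1 A
#'   starting at 1 A).
#' @return numeric `c(lower, upper)` in Angstrom. For example
#'   `binRange(86, "RDF")` is 8.5-8.6 and `binRange(9, "3DACorr")` is 9-10.
#' @export
binRange <- function(k, family = c("RDF", "3DACorr")) {
  family <- match.arg(family)
  k <- as.integer(k)
  if (family == "RDF") {
    if (k < 1L || k > 128L) stop("RDF bin index must be in 1..128", call. = FALSE)
    c((k - 1L) * 0.1, k * 0.1)
  } else {
    if (k < 1L || k > 12L) stop("3DACorr bin index must be in 1..12", call. = FALSE)
    c(k, k + 1)
  }
}

#' Compute the full computable descriptor block for molecules
#'
#' Evaluates the two computable descriptor families — 1024 RDF values
#' (8 channels x 128 bins) and 96 3D autocorrelation values (8 channels x
#' 12 bins) — for one molecule or a list. Channels are computed on demand
#' with [computeChannels()] when absent. Descriptor names follow the
#' `FAMILY_PROPERTY_INDEX` convention (`RDF_PiChg_86`,
#' `3DACorr_TotChg_9`, ...).
#'
#' @param mols a [Molecule3D-class] or list of them (coordinates required).
#' @param B RDF smoothing parameter, see [rdfDescriptor()].
#' @param at RDF evaluation point within the bin, see [rdfDescriptor()].
#' @return numeric matrix, one row per molecule (rownames = molecule ids),
#'   1120 named columns.
#' @export
computeDescriptors <- function(mols, B = 100, at = c("midpoint", "left")) {
  at <- match.arg(at)
  if (is(mols, "Molecule3D")) mols <- list(mols)
  nms <- registryNames(computableOnly = TRUE)
  out <- matrix(NA_real_, nrow = length(mols), ncol = length(nms),
                dimnames = list(vapply(mols, molId, ""), nms))
  for (r in seq_along(mols)) {
    mol <- mols[[r]]
    if (!length(mol@channels)) mol <- computeChannels(mol)
    row <- numeric(0)
    for (ch in .channelOrder) {
      v <- rdfDescriptor(mol, ch, bins = 1:128, B = B, at = at)
      names(v) <- sprintf("RDF_%s_%d", ch, 1:128)
      row <- c(row, v)
    }
    for (ch in .channelOrder) {
      v <- autocorr3dDescriptor(mol, ch, bins = 1:12)
      names(v) <- sprintf("3DACorr_%s_%d", ch, 1:12)
      row <- c(row, v)
    }
    out[r, ] <- row[nms]
  }
  .stopIfNot(all(is.finite(out)), "non-finite descriptor values produced")
  out
}
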