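#' Molecule with 3D coordinates and per-atom property channels
#'
#' `Molecule3D` is the central container for a small molecule: atoms
#' (element symbol, formal charge, Cartesian coordinates in Angstrom),
#' bonds (atom index pair plus order, with aromatic bonds carried as a
#' distinct order flag `4`), and an arbitrary set of named per-atom scalar
#' property channels (filled in by [computeChannels()]).
#'
#' @slot id single character identifier.
#' @slot atoms `data.frame` with columns `element` (character),
#'   `charge` (integer formal charge, e), `x`, `y`, `z` (numeric, Angstrom).
#' @slot bonds `data.frame` with integer columns `i`, `j` (1-based atom
#'   indices, `i < j`) and `order` (1, 2, 3, or 4 for aromatic).
#' @slot channels named list of numeric vectors, one value per atom.
#' @slot needsEmbedding logical; `TRUE` when the record came from a
#'   connection-table-only source (e.g. SMILES) and coordinates are
#'   placeholders until [embed3d()] is run.
#'
#' @seealso [readStructures()], [embed3d()], [computeChannels()]
#' @export
setClass("Molecule3D",
  representation(
    id = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    channels = "list",
    needsEmbedding = "logical"
  ),
  prototype(
    id = NA_character_,
    atoms = data.frame(element = character(), charge = integer(),
                       x = numeric(), y = numeric(), z = numeric()),
    bonds = data.frame(i = integer(), j = integer(), order = integer()),
    channels = list(),
    needsEmbedding = FALSE
  )
)

setValidity("Molecule3D", function(object) {
  msgs <- character()
  a <- object@atoms
  b <- object@bonds
  if (!all(c("element", "charge", "x", "y", "z") %in% names(a)))
    msgs <- c(msgs, "atoms must have columns element, charge, x, y, z")
  if (!all(c("i", "j", "order") %in% names(b)))
    msgs <- c(msgs, "bonds must have columns i, j, order")
  if (length(msgs)) return(msgs)
  n <- nrow(a)
  if (nrow(b)) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      msgs <- c(msgs, "bond indices must reference existing atoms")
    if (any(b$i == b$j))
      msgs <- c(msgs, "self-bonds (i == j) are not allowed")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate bonds are not allowed")
    if (!all(b$order %in% 1:4))
      msgs <- c(msgs, "bond order must be 1, 2, 3, or 4 (aromatic)")
  }
  if (!object@needsEmbedding && n > 0 &&
      !all(is.finite(c(a$x, a$y, a$z))))
    msgs <- c(msgs, "coordinates must be finite unless flagged needsEmbedding")
  for (nm in names(object@channels)) {
    ch <- object@channels[[nm]]
    if (!is.numeric(ch) || length(ch) != n)
      msgs <- c(msgs, sprintf("channel '%s' must be numeric of length %d", nm, n))
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted QSAR regression model
#'
#' Holds a linear pFAR model on standardized (z-score) descriptors:
#' selected descriptor names, their coefficients (per standardized unit),
#' the intercept, the training-set standardization statistics, and the
#' fit/validation statistics (R, R2, adjusted R2, SEE, F, p, LOO q2).
#'
#' @slot descriptors character vector of selected descriptor names.
#' @slot coefficients numeric vector, one per descriptor (z-scale).
#' @slot intercept single numeric.
#' @slot means,sds numeric vectors of training means/SDs per descriptor
#'   (may be `NA` for models defined directly on z-scores, such as the
#'   published equation).
#' @slot n number of training compounds.
#' @slot stats named list of fit statistics.
#'
#' @seealso [stepwiseMLR()], [publishedEquation()], [validateModel()]
#' @export
setClass("QSARModel",
  representation(
    descriptors = "character",
    coefficients = "numeric",
    intercept = "numeric",
    means = "numeric",
    sds = "numeric",
    n = "integer",
    stats = "list"
  )
)

setValidity("QSARModel", function(object) {
  msgs <- character()
  k <- length(object@descriptors)
  if (length(object@coefficients) != k)
    msgs <- c(msgs, "number of coefficients must equal number of descriptors")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a single finite number")
  if (length(object@means) != k || length(object@sds) != k)
    msgs <- c(msgs, "means and sds must have one entry per descriptor")
  if (length(msgs)) msgs else TRUE
})

#' Descriptor-selection trace
#'
#' Records how many descriptors survive each stage of the selection
#' cascade (initial, after the marginal correlation filter, after the
#' pairwise redundancy filter, after stepwise regression) together with
#' the stepwise event log (descriptor, add/remove, partial F, p-value).
#'
#' @slot counts named integer vector with elements `initial`,
#'   `afterCorrelation`, `afterRedundancy`, `afterStepwise`.
#' @slot events `data.frame` with columns `step`, `action`, `descriptor`,
#'   `statistic`, `p`.
#'
#' @seealso [stepwiseMLR()], [runFullPipeline()]
#' @export
setClass("SelectionTrace",
  representation(counts = "integer", events = "data.frame")
)

setValidity("SelectionTrace", function(object) {
  need <- c("initial", "afterCorrelation", "afterRedundancy", "afterStepwise")
  if (!all(need %in% names(object@counts)))
    return("counts must contain initial, afterCorrelation, afterRedundancy, afterStepwise")
  ct <- object@counts[need]
  if (any(diff(ct) > 0L))
    return("stage counts must be non-increasing")
  TRUE
})

#' Planted synthetic descriptor dataset
#'
#' A seeded descriptor matrix with a known sparse linear signal:
#' `y = X[, trueIdx] %*% beta + eps`, `eps ~ N(0, noiseSd^2)`, plus
#' blocks of highly collinear nuisance columns. Used to exercise the
#' selection cascade against a known truth.
#'
#' @slot X numeric matrix (n x p) with column names.
#' @slot y numeric response vector.
#' @slot trueIdx integer indices of the signal columns.
#' @slot beta numeric true coefficients for the signal columns.
#' @slot noiseSd numeric noise standard deviation.
#' @slot blockSpec list describing the nuisance correlation blocks.
#' @slot seed integer seed the dataset was generated from.
#'
#' @seealso [genPlanted()], [genPaperlike()]
#' @export
setClass("PlantedDataset",
  representation(
    X = "matrix",
    y = "numeric",
    trueIdx = "integer",
    beta = "numeric",
    noiseSd = "numeric",
    blockSpec = "list",
    seed = "integer"
  )
)

setValidity("PlantedDataset", function(object) {
  msgs <- character()
  if (length(object@y) != nrow(object@X))
    msgs <- c(msgs, "length(y) must equal nrow(X)")
  if (length(object@trueIdx) != length(object@beta))
    msgs <- c(msgs, "trueIdx and beta must have equal length")
  if (any(object@trueIdx < 1L | object@trueIdx > ncol(object@X)))
    msgs <- c(msgs, "trueIdx out of range")
  if (length(msgs)) msgs else TRUE
})
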