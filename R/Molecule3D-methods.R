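#' Construct a Molecule3D
#'
#' @param id character identifier.
#' @param atoms `data.frame` with columns `element`, `charge`, `x`, `y`, `z`
#'   (charge defaults to 0 when absent).
#' @param bonds `data.frame` with columns `i`, `j`, `order`; empty allowed.
#' @param channels named list of per-atom numeric vectors.
#' @param needsEmbedding logical flag, see [embed3d()].
#' @return a validated [Molecule3D-class] object.
#' @examples
#' m <- Molecule3D("dimer",
#'   atoms = data.frame(element = c("C", "C"), charge = 0L,
#'                      x = c(0, 1.5), y = 0, z = 0),
#'   bonds = data.frame(i = 1L, j = 2L, order = 1L))
#' nAtoms(m)
#' @export
Molecule3D <- function(id, atoms, bonds = NULL, channels = list(),
                       needsEmbedding = FALSE) {
  if (is.null(bonds) || !nrow(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- data.frame(i = as.integer(pmin(bonds$i, bonds$j)),
                        j = as.integer(pmax(bonds$i, bonds$j)),
                        order = as.integer(bonds$order))
  }
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      x = as.numeric(atoms$x), y = as.numeric(atoms$y),
                      z = as.numeric(atoms$z))
  new("Molecule3D", id = as.character(id), atoms = atoms, bonds = bonds,
      channels = channels, needsEmbedding = needsEmbedding)
}

#' @rdname Molecule3D-accessors
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("molBonds", function(x) standardGeneric("molBonds"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomChannel", function(x, name) standardGeneric("atomChannel"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomChannel<-", function(x, name, value) standardGeneric("atomChannel<-"))

#' @rdname Molecule3D-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Accessors for Molecule3D
#'
#' @param x a [Molecule3D-class] object.
#' @param name channel name, e.g. `"SigChg"`.
#' @param value numeric vector with one entry per atom.
#' @return `molId` the identifier; `nAtoms` the atom count; `atomElements`
#'   the element symbols; `atomCoords` an n x 3 matrix (Angstrom);
#'   `molBonds` the bond table; `atomChannel` a per-atom numeric vector;
#'   `channelNames` the names of the populated property channels.
#' @name Molecule3D-accessors
NULL

#' @rdname Molecule3D-accessors
setMethod("molId", "Molecule3D", function(x) x@id)

#' @rdname Molecule3D-accessors
setMethod("nAtoms", "Molecule3D", function(x) nrow(x@atoms))

#' @rdname Molecule3D-accessors
setMethod("atomElements", "Molecule3D", function(x) x@atoms$element)

#' @rdname Molecule3D-accessors
setMethod("atomCoords", "Molecule3D", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
})

#' @rdname Molecule3D-accessors
setMethod("molBonds", "Molecule3D", function(x) x@bonds)

#' @rdname Molecule3D-accessors
setMethod("atomChannel", "Molecule3D", function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel '", name, "' not present in molecule '", x@id,
         "'; run computeChannels() first", call. = FALSE)
  x@channels[[name]]
})

#' @rdname Molecule3D-accessors
setMethod("atomChannel<-", "Molecule3D", function(x, name, value) {
  x@channels[[name]] <- value
  validObject(x)
  x
})

#' @rdname Molecule3D-accessors
setMethod("channelNames", "Molecule3D", function(x) names(x@channels))

setMethod("show", "Molecule3D", function(object) {
  heavy <- sum(object@atoms$element != "H")
  cat("Molecule3D '", object@id, "': ", nrow(object@atoms), " atoms (",
      heavy, " heavy), ", nrow(object@bonds), " bonds",
      if (object@needsEmbedding) " [needs 3D embedding]", "\n", sep = "")
  if (length(object@channels))
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "QSARModel", function(object) {
  cat("QSARModel with", length(object@descriptors), "descriptors (n =",
      object@n, ")\n")
  if (length(object@descriptors)) {
    terms <- sprintf("%+.3f(%s)", object@coefficients, object@descriptors)
    cat("  pFAR =", paste(terms, collapse = " "),
        sprintf("%+.3f", object@intercept), "\n")
  } else {
    cat("  pFAR =", sprintf("%.3f", object@intercept), "(intercept only)\n")
  }
  s <- object@stats
  if (length(s)) {
    fmt <- function(v) if (is.null(v) || !is.finite(v)) "NA" else sprintf("%.3f", v)
    cat("  R =", fmt(s$R), " R2 =", fmt(s$R2), " R2adj =", fmt(s$R2adj),
        " SEE =", fmt(s$SEE), " F =", fmt(s$F), " q2 =", fmt(s$q2), "\n")
  }
})

setMethod("show", "SelectionTrace", function(object) {
  ct <- object@counts
  cat("SelectionTrace:", ct["initial"], "->", ct["afterCorrelation"],
      "(|r| filter) ->", ct["afterRedundancy"], "(pairwise filter) ->",
      ct["afterStepwise"], "(stepwise)\n")
  if (nrow(object@events))
    cat("  stepwise events:", nrow(object@events), "(",
        sum(object@events$action == "add"), "add /",
        sum(object@events$action == "remove"), "remove )\n")
})

setMethod("show", "PlantedDataset", function(object) {
  cat("PlantedDataset:", nrow(object@X), "x", ncol(object@X),
      "descriptor matrix,", length(object@trueIdx),
      "planted predictors, noise SD", signif(object@noiseSd, 3),
      "(seed", paste0(object@seed, ")"), "\n")
})

#' @rdname PlantedDataset-accessors
#' @export
setGeneric("datasetX", function(x) standardGeneric("datasetX"))

#' @rdname PlantedDataset-accessors
#' @export
setGeneric("datasetY", function(x) standardGeneric("datasetY"))

#' @rdname PlantedDataset-accessors
#' @export
setGeneric("trueDescriptors", function(x) standardGeneric("trueDescriptors"))

#' Accessors for PlantedDataset
#'
#' @param x a [PlantedDataset-class].
#' @return `datasetX` the descriptor matrix, `datasetY` the response,
#'   `trueDescriptors` the column names of the planted predictors.
#' @name PlantedDataset-accessors
NULL

#' @rdname PlantedDataset-accessors
setMethod("datasetX", "PlantedDataset", function(x) x@X)

#' @rdname PlantedDataset-accessors
setMethod("datasetY", "PlantedDataset", function(x) x@y)

#' @rdname PlantedDataset-accessors
setMethod("trueDescriptors", "PlantedDataset", function(x) colnames(x@X)[x@trueIdx])
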