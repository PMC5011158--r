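#' The 1252-descriptor registry
#'
#' Declares the five descriptor families of the descriptor space this
#' package models: 8 global molecular descriptors, 88 2D autocorrelation
#' descriptors, 96 3D autocorrelation descriptors, 1024 property-weighted
#' RDF descriptors, and 36 surface-autocorrelation descriptors — 1252 in
#' total. Only the 3D autocorrelation and RDF families are computable by
#' this package (8 property channels x 12 and x 128 bins); the remaining
#' families are registry entries with names and counts only.
#'
#' @return `data.frame` with columns `family`, `count`, `computable`,
#'   `channels`, `bins`, `binWidth` (Angstrom; `NA` where not
#'   distance-binned).
#' @examples
#' registryTotal()          # 1252
#' subset(descriptorRegistry(), computable)
#' @export
descriptorRegistry <- function() {
  data.frame(
    family = c("Global", "2DACorr", "3DACorr", "RDF", "SurfACorr"),
    count = c(8L, 88L, 96L, 1024L, 36L),
    computable = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    channels = c(NA_integer_, 8L, 8L, 8L, 4L),
    bins = c(NA_integer_, 11L, 12L, 128L, 9L),
    binWidth = c(NA_real_, NA_real_, 1.0, 0.1, NA_real_)
  )
}

#' @rdname descriptorRegistry
#' @param registry a registry `data.frame`; defaults to the full registry.
#' @return `registryTotal`: the integer sum of the family counts.
#' @export
registryTotal <- function(registry = descriptorRegistry()) {
  if (!nrow(registry)) return(0L)
  sum(as.integer(registry$count))
}

#' Descriptor names declared by the registry
#'
#' @param computableOnly when `TRUE` (default) only the names of the
#'   computable families (RDF, 3DACorr) are returned, in the column order
#'   produced by [computeDescriptors()].
#' @return character vector of `FAMILY_PROPERTY_INDEX` names.
#' @export
registryNames <- function(computableOnly = TRUE) {
  rdf <- as.vector(t(outer(.channelOrder, 1:128,
                           function(ch, k) sprintf("RDF_%s_%d", ch, k))))
  aco <- as.vector(t(outer(.channelOrder, 1:12,
                           function(ch, k) sprintf("3DACorr_%s_%d", ch, k))))
  out <- c(rdf, aco)
  if (!computableOnly) {
    out <- c(sprintf("Global_%d", 1:8),
             as.vector(t(outer(.channelOrder, 0:10,
                               function(ch, k) sprintf("2DACorr_%s_%d", ch, k)))),
             out,
             as.vector(t(outer(c("ESP", "HBP", "PiEN", "SigEN"), 1:9,
                               function(ch, k) sprintf("SurfACorr_%s_%d", ch, k)))))
  }
  out
}
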