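#' Run the full QSAR modelling workflow
#'
#' End-to-end pipeline from structures (or a precomputed descriptor
#' matrix) and activities to a validated model: descriptor computation,
#' z-score standardization, marginal correlation filter, pairwise
#' redundancy filter, stepwise MLR with LOO q2, and the acceptance
#' checks of [validateModel()]. Stage counts are logged in the
#' `initial -> after filter 1 -> after filter 2 -> selected` style.
#'
#' @param activities `data.frame` with a `compound` column and either
#'   `far` (transformed internally via [farToPfar()]) or `pfar`.
#' @param structures optional list of [Molecule3D-class] (or a file path
#'   accepted by [readStructures()]); required when `descriptors` is
#'   missing. Molecules flagged as needing embedding are embedded with
#'   `embedSeed`.
#' @param descriptors optional precomputed descriptor matrix with
#'   rownames matching `activities$compound`.
#' @param corrThreshold,pairThreshold filter thresholds (defaults 0.1,
#'   0.85).
#' @param pEnter,pRemove stepwise significance levels (defaults 0.05,
#'   0.10).
#' @param B,at RDF kernel settings, see [rdfDescriptor()].
#' @param embedSeed seed for [embed3d()].
#' @return list with `model` ([QSARModel-class]), `trace`
#'   ([SelectionTrace-class]), `validation` (from [validateModel()]),
#'   `Z` (standardized retained descriptors), `y` (pFAR vector), and
#'   `config` (all tunables, echoed for provenance).
#' @export
runFullPipeline <- function(activities, structures = NULL,
                            descriptors = NULL, corrThreshold = 0.1,
                            pairThreshold = 0.85, pEnter = 0.05,
                            pRemove = 0.10, B = 100,
                            at = c("midpoint", "left"), embedSeed = 1L) {
  at <- match.arg(at)
  .stopIfNot(is.data.frame(activities) && "compound" %in% names(activities),
             "activities must be a data.frame with a 'compound' column")
  if (nrow(activities) < 8L)
    stop("at least 8 compounds are required: with fewer, the 3-6x ",
         "compounds-per-descriptor rule cannot hold for any multi-",
         "descriptor model", call. = FALSE)
  y <- if ("pfar" %in% names(activities)) activities$pfar else
    if ("far" %in% names(activities)) farToPfar(activities$far) else
      stop("activities needs a 'far' or 'pfar' column", call. = FALSE)
  if (is.null(descriptors)) {
    .stopIfNot(!is.null(structures),
               "either structures or descriptors must be given")
    if (is.character(structures)) structures <- readStructures(structures)
    structures <- lapply(structures, function(m)
      if (m@needsEmbedding) embed3d(m, seed = embedSeed) else m)
    structures <- lapply(structures, computeChannels)
    descriptors <- computeDescriptors(structures, B = B, at = at)
  }
  descriptors <- as.matrix(descriptors)
  idx <- match(as.character(activities$compound), rownames(descriptors))
  if (anyNA(idx))
    stop("no descriptors for compound(s): ",
         paste(activities$compound[is.na(idx)], collapse = ", "),
         call. = FALSE)
  X <- descriptors[idx, , drop = FALSE]
  std <- standardizeDescriptors(X)
  keep1 <- correlationFilter(std$Z, y, threshold = corrThreshold)
  Z1 <- std$Z[, keep1, drop = FALSE]
  keep2 <- redundancyFilter(Z1, y, threshold = pairThreshold)
  Z2 <- Z1[, keep2, drop = FALSE]
  message(sprintf(
    "descriptor selection: %d initial -> %d after |r| >= %.2f -> %d after pairwise |r| <= %.2f",
    ncol(std$Z), ncol(Z1), corrThreshold, ncol(Z2), pairThreshold))
  sw <- stepwiseMLR(Z2, y, pEnter = pEnter, pRemove = pRemove,
                    means = std$means, sds = std$sds,
                    stages = c(initial = ncol(std$Z),
                               afterCorrelation = ncol(Z1),
                               afterRedundancy = ncol(Z2)))
  message(sprintf("stepwise selected %d descriptor(s)",
                  length(sw$model@descriptors)))
  validation <- validateModel(sw$model)
  list(model = sw$model, trace = sw$trace, validation = validation,
       Z = Z2, y = y,
       config = list(corrThreshold = corrThreshold,
                     pairThreshold = pairThreshold, pEnter = pEnter,
                     pRemove = pRemove, B = B, at = at,
                     embedSeed = embedSeed))
}

#' Recompute everything the packaged fixtures support
#'
#' Desk-reproduces the published quantities that depend only on printed
#' data: the training-table refit statistics and residual consistency,
#' the external-set classification concordance, the published equation's
#' intercept evaluation, the pFAR transform endpoints, the descriptor
#' registry total, and the fixture correlation-matrix bound used by the
#' redundancy filter.
#'
#' @return `data.frame` with one row per check: `check`, `value`,
#'   `reference`, `ok`.
#' @examples
#' reproducePaper()
#' @export
reproducePaper <- function() {
  t3 <- table3Metrics()
  t4 <- qsarFixture("table4")
  conc <- concordance(classifyPfar(t4$calculated_pfar), t4$observed_class)
  t2 <- qsarFixture("table2")
  offdiag <- max(abs(t2[upper.tri(t2)]))
  row <- function(check, value, reference, ok)
    data.frame(check = check, value = value, reference = reference, ok = ok)
  rbind(
    row("training R2", t3$stats$R2, 0.927, abs(t3$stats$R2 - 0.927) <= 0.005),
    row("training R", t3$stats$R, 0.963, abs(t3$stats$R - 0.963) <= 0.005),
    row("training SEE", t3$stats$SEE, 0.197, abs(t3$stats$SEE - 0.197) <= 0.005),
    row("max residual inconsistency", t3$maxResidualError, 0.015,
        t3$residualsConsistent),
    row("external concordance / 11", conc$nCorrect, 7,
        conc$nCorrect == 7 && conc$nTotal == 11),
    row("equation at zero vector", predictPfar(rep(0, 6)), -0.416,
        predictPfar(rep(0, 6)) == -0.416),
    row("pFAR of FAR = 46.4", farToPfar(46.4), -1.67,
        round(farToPfar(46.4), 2) == -1.67),
    row("pFAR of FAR = 0.5", farToPfar(0.5), 0.30,
        round(farToPfar(0.5), 2) == 0.30),
    row("descriptor registry total", registryTotal(), 1252,
        registryTotal() == 1252L),
    row("fixture max off-diagonal |r|", offdiag, 0.85, offdiag < 0.85)
  )
}

#' Serialize a model to JSON
#'
#' Writes descriptor names, coefficients, intercept, standardization
#' statistics and fit statistics as schema-versioned JSON.
#'
#' @param model a [QSARModel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
exportModel <- function(model, path) {
  .stopIfNot(requireNamespace("jsonlite", quietly = TRUE),
             "exportModel requires the jsonlite package")
  obj <- list(schema = "flavoqsar-model/1",
              descriptors = model@descriptors,
              coefficients = model@coefficients,
              intercept = model@intercept,
              means = model@means, sds = model@sds,
              n = model@n, stats = model@stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
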