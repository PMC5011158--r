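# the six descriptors of the published equation, in equation order
.publishedDescriptors <- c("RDF_PiChg_86", "RDF_SigChg_76", "3DACorr_TotChg_9",
                           "RDF_LpEN_54", "3DACorr_PiChg_9", "RDF_SigChg_57")
.publishedCoefficients <- c(-0.613, 0.461, -0.283, 0.207, -0.284, -0.197)
.publishedIntercept <- -0.416

#' The published six-descriptor pFAR equation
#'
#' Returns the final reported QSAR model as an immutable
#' [QSARModel-class]:
#' `pFAR = -0.613 RDF_PiChg_86 + 0.461 RDF_SigChg_76 - 0.283 3DACorr_TotChg_9`
#' `+ 0.207 RDF_LpEN_54 - 0.284 3DACorr_PiChg_9 - 0.197 RDF_SigChg_57 - 0.416`,
#' with descriptors on the training z-score scale. The training means/SDs
#' of the original descriptor values were never published, so the model's
#' `means`/`sds` slots are `NA`: predictions require already-standardized
#' descriptor vectors (see [predictPfar()]). The stored statistics are the
#' values reported with the equation (n = 23, R = 0.963, R2 = 0.927,
#' R2adj = 0.900, SEE = 0.197, F = 33.849, q2 = 0.927).
#'
#' @return a [QSARModel-class].
#' @examples
#' predictPfar(rep(0, 6))  # the intercept, -0.416
#' @export
publishedEquation <- function() {
  new("QSARModel",
      descriptors = .publishedDescriptors,
      coefficients = .publishedCoefficients,
      intercept = .publishedIntercept,
      means = rep(NA_real_, 6L), sds = rep(NA_real_, 6L),
      n = 23L,
      stats = list(R = 0.963, R2 = 0.927, R2adj = 0.900, SEE = 0.197,
                   F = 33.849, p = 1e-3, q2 = 0.927, n = 23L, k = 6L,
                   reported = TRUE))
}

#' Predict pFAR from standardized descriptors
#'
#' Evaluates a linear QSAR model, `pFAR = sum(C_i z_i) + intercept`, on
#' one or more standardized descriptor vectors.
#'
#' @param z numeric vector (one compound, ordered like
#'   `model@descriptors`), or a matrix/data.frame with one row per
#'   compound whose columns either match the model's descriptor names or
#'   are positional.
#' @param model a [QSARModel-class]; default the published equation.
#' @return numeric vector of pFAR predictions.
#' @export
predictPfar <- function(z, model = publishedEquation()) {
  .stopIfNot(is(model, "QSARModel"), "model must be a QSARModel")
  k <- length(model@descriptors)
  if (is.null(dim(z))) {
    if (length(z) != k)
      stop("expected a standardized vector of length ", k, call. = FALSE)
    z <- matrix(z, nrow = 1)
  } else {
    z <- as.matrix(z)
    if (!is.null(colnames(z)) && all(model@descriptors %in% colnames(z)))
      z <- z[, model@descriptors, drop = FALSE]
    if (ncol(z) != k)
      stop("expected ", k, " descriptor columns", call. = FALSE)
  }
  .stopIfNot(all(is.finite(z)), "descriptor values must be finite")
  as.vector(z %*% model@coefficients) + model@intercept
}

#' Classify a pFAR value as P-gp inducer or inhibitor
#'
#' Applies the activity-class rule: `pFAR < -1` (FAR > 10) is a strong
#' (potent) inhibitor, `-1 <= pFAR < 0` (1 < FAR < 10) an active (weak)
#' inhibitor, and `pFAR >= 0` (FAR <= 1) an inducer. The boundary values
#' themselves are not assigned by the strict-inequality definition of the
#' classes; the default convention closes each boundary on its right
#' (`-1` is active, `0` is inducer) and can be overridden.
#'
#' @param pfar finite numeric vector.
#' @param strongBoundary,inducerBoundary class boundaries on the pFAR
#'   axis, defaults -1 and 0.
#' @return factor with levels `strong_inhibitor`, `active_inhibitor`,
#'   `inducer`.
#' @examples
#' classifyPfar(c(-1.32, -0.39, 0.42))
#' @export
classifyPfar <- function(pfar, strongBoundary = -1, inducerBoundary = 0) {
  if (!is.numeric(pfar) || any(!is.finite(pfar)))
    stop("pFAR values must be finite numbers", call. = FALSE)
  lev <- c("strong_inhibitor", "active_inhibitor", "inducer")
  out <- ifelse(pfar < strongBoundary, lev[1],
                ifelse(pfar < inducerBoundary, lev[2], lev[3]))
  factor(out, levels = lev)
}

#' Classification concordance
#'
#' @param predicted,observed equal-length vectors (factor or character) of
#'   activity classes.
#' @return list with `nCorrect` and `nTotal`.
#' @export
concordance <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed class vectors differ in length",
         call. = FALSE)
  list(nCorrect = sum(as.character(predicted) == as.character(observed)),
       nTotal = length(observed))
}

#' Load a packaged fixture table
#'
#' The package ships the printed data tables that accompany the published
#' equation: `"table2"` — the 6 x 6 intercorrelation matrix of the model
#' descriptors; `"table3"` — observed/predicted pFAR and residuals of the
#' 23 training flavonoids; `"table4"` — the 11-compound external test set
#' (inhibitory efficiency, observed class, calculated pFAR, predicted
#' class).
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`.
#' @return `table2`: a named numeric matrix; otherwise a `data.frame`.
#' @export
qsarFixture <- function(name = c("table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, switch(name,
    table2 = "_descriptor_correlations.csv",
    table3 = "_training_pfar.csv",
    table4 = "_external_set.csv")), package = "flavoqsar", mustWork = TRUE)
  if (name == "table2") {
    df <- read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    if (max(abs(m - t(m))) > 1e-12)
      stop("correlation fixture is not symmetric", call. = FALSE)
    return(m)
  }
  read.csv(path, check.names = FALSE)
}

#' Refit statistics on the printed training table
#'
#' Recomputes the regression quality statistics from the printed
#' observed/calculated pFAR pairs of the 23 training compounds (k = 6
#' descriptors), and checks that every printed residual equals
#' observed - predicted within rounding.
#'
#' @param residualTolerance allowed |printed residual - (obs - pred)|,
#'   default 0.015 (2-decimal rounding of the printed table).
#' @return list with `stats` (from [fitStats()]), `maxResidualError`, and
#'   `residualsConsistent`.
#' @examples
#' table3Metrics()$stats$R2  # about 0.927
#' @export
table3Metrics <- function(residualTolerance = 0.015) {
  t3 <- qsarFixture("table3")
  need <- c("observed_pfar", "predicted_pfar", "residual")
  if (!all(need %in% names(t3)) || nrow(t3) != 23L)
    stop("training fixture is corrupt", call. = FALSE)
  stats <- fitStats(t3$observed_pfar, t3$predicted_pfar, k = 6L)
  err <- max(abs(t3$residual - (t3$observed_pfar - t3$predicted_pfar)))
  list(stats = stats, maxResidualError = err,
       residualsConsistent = err <= residualTolerance)
}
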