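#' pFAR activity transform
#'
#' Converts fluorescence activity ratios (FAR) to `pFAR = -log10(FAR)`.
#' Negative pFAR denotes P-gp inhibition, positive pFAR induction.
#'
#' @param far positive numeric vector of FAR values.
#' @return numeric pFAR vector.
#' @examples
#' farToPfar(c(46.4, 1, 0.5))  # -1.67, 0, 0.30
#' @export
farToPfar <- function(far) {
  .stopIfNot(is.numeric(far) && all(is.finite(far)),
             "FAR values must be finite numbers")
  if (any(far <= 0)) stop("FAR must be > 0", call. = FALSE)
  -log10(far)
}

#' Standardize a descriptor matrix to z-scores
#'
#' Centres and scales each column to mean 0 and sample SD 1 (denominator
#' `n - 1`). Zero-variance columns cannot be standardized; they are
#' dropped and reported.
#'
#' @param X numeric matrix (compounds x descriptors) with column names.
#' @return list with `Z` (standardized matrix), `means`, `sds` (named, for
#'   the retained columns), and `dropped` (names of zero-variance columns).
#' @export
standardizeDescriptors <- function(X) {
  X <- as.matrix(X)
  .stopIfNot(nrow(X) >= 2L, "standardization needs at least 2 rows")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all descriptor columns are constant", call. = FALSE)
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance descriptor(s)")
  Z <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  list(Z = Z, means = mu[keep], sds = sdv[keep], dropped = dropped)
}

#' Marginal correlation filter
#'
#' Retains descriptors whose absolute Pearson correlation with the
#' activity is at least `threshold` (default 0.1); weakly correlated
#' descriptors are not carried into model building. Column order is
#' preserved.
#'
#' @param Z standardized descriptor matrix.
#' @param y activity vector (same length as `nrow(Z)`).
#' @param threshold minimum `|r|` to keep a column.
#' @param absolute use `|r|` (default) rather than signed `r`; the signed
#'   variant would discard strong negative correlates.
#' @return character vector of retained column names (or indices when `Z`
#'   has no column names), in original order.
#' @export
correlationFilter <- function(Z, y, threshold = 0.1, absolute = TRUE) {
  Z <- as.matrix(Z)
  .stopIfNot(length(y) == nrow(Z), "y length must match nrow(Z)")
  if (sd(y) == 0)
    stop("activity vector is constant; correlation undefined", call. = FALSE)
  r <- as.vector(cor(Z, y))
  keep <- if (absolute) abs(r) >= threshold else r >= threshold
  cn <- colnames(Z)
  if (is.null(cn)) which(keep) else cn[keep]
}

#' Pairwise redundancy filter
#'
#' Eliminates one descriptor of every pair whose absolute pairwise
#' correlation exceeds `threshold` (default 0.85), keeping the member with
#' the higher absolute correlation to the activity. Implemented as a
#' deterministic greedy pass in descending `|r(descriptor, y)|` order
#' (ties broken by column order): a descriptor is kept iff it is not
#' excessively correlated with any already-kept descriptor. No surviving
#' pair exceeds the threshold.
#'
#' @inheritParams correlationFilter
#' @param threshold maximum tolerated pairwise `|r|`.
#' @return retained column names (or indices), in original column order.
#' @export
redundancyFilter <- function(Z, y, threshold = 0.85) {
  Z <- as.matrix(Z)
  .stopIfNot(length(y) == nrow(Z), "y length must match nrow(Z)")
  p <- ncol(Z)
  if (p <= 1L) {
    cn <- colnames(Z)
    return(if (is.null(cn)) seq_len(p) else cn)
  }
  ry <- abs(as.vector(cor(Z, y)))
  ord <- order(-ry, seq_len(p))
  C <- abs(cor(Z))
  kept <- integer(0)
  for (jj in ord) {
    if (!length(kept) || all(C[jj, kept] <= threshold))
      kept <- c(kept, jj)
  }
  kept <- sort(kept)
  cn <- colnames(Z)
  if (is.null(cn)) kept else cn[kept]
}

#' Regression fit statistics
#'
#' Computes the standard MLR quality statistics from observed and
#' predicted activities: `R` (Pearson correlation of observed and
#' predicted), `R2 = 1 - SSE/SST`, adjusted R2, the standard error of
#' estimate `SEE = sqrt(SSE / (n - k - 1))`, and the Fisher statistic
#' `F = (SSR / k) / (SSE / (n - k - 1))` with its p-value.
#'
#' @param observed,predicted numeric vectors of equal length `n`.
#' @param k number of predictors in the model.
#' @return named list `R`, `R2`, `R2adj`, `SEE`, `F`, `p`, `n`, `k`.
#' @export
fitStats <- function(observed, predicted, k) {
  n <- length(observed)
  .stopIfNot(length(predicted) == n, "observed/predicted length mismatch")
  if (n <= k + 1L)
    stop("fit statistics need n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  ssr <- sst - sse
  r2 <- 1 - sse / sst
  list(
    R = if (sd(predicted) > 0) cor(observed, predicted) else NA_real_,
    R2 = r2,
    R2adj = 1 - (1 - r2) * (n - 1) / (n - k - 1),
    SEE = sqrt(sse / (n - k - 1)),
    F = (ssr / k) / (sse / (n - k - 1)),
    p = pf((ssr / k) / (sse / (n - k - 1)), k, n - k - 1, lower.tail = FALSE),
    n = n, k = k
  )
}

#' Leave-one-out cross-validated q2
#'
#' For each training compound, the regression is refit on the remaining
#' `n - 1` compounds with the same descriptor set and used to predict the
#' held-out compound. `q2 = 1 - PRESS / SST`, with `SST` about the
#' full-set mean activity.
#'
#' @param Z standardized descriptor matrix restricted to the selected
#'   descriptors.
#' @param y activity vector.
#' @return q2 (can be negative when LOO predictions are worse than the
#'   mean).
#' @export
looQ2 <- function(Z, y) {
  Z <- as.matrix(Z)
  n <- length(y)
  k <- ncol(Z)
  .stopIfNot(nrow(Z) == n, "Z/y dimension mismatch")
  if (n <= k + 2L)
    stop("LOO q2 needs n > k + 2", call. = FALSE)
  press <- 0
  for (i in seq_len(n)) {
    fit <- .lm.fit(cbind(1, Z[-i, , drop = FALSE]), y[-i])
    if (any(is.na(fit$coefficients)) || fit$rank < k + 1L)
      stop("singular refit when leaving out row ", i, call. = FALSE)
    pred <- sum(c(1, Z[i, ]) * fit$coefficients)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Model acceptance checks
#'
#' Applies the standard internal-validation criteria to a fitted
#' [QSARModel-class]: the compounds-per-descriptor ratio must lie in 3-6,
#' R2 must exceed 0.7 and LOO q2 must exceed 0.5. SEE and F carry no hard
#' thresholds (smaller/larger is better) and are echoed for inspection.
#'
#' @param model a [QSARModel-class] with populated statistics.
#' @param ratioRange allowed `n / k` range, default `c(3, 6)`.
#' @param minR2,minQ2 thresholds for R2 and q2.
#' @return list of per-criterion logicals (`ratio`, `R2`, `q2`), the
#'   echoed `SEE` and `F`, and `pass` (all criteria true).
#' @export
validateModel <- function(model, ratioRange = c(3, 6), minR2 = 0.7,
                          minQ2 = 0.5) {
  .stopIfNot(is(model, "QSARModel"), "model must be a QSARModel")
  s <- model@stats
  k <- length(model@descriptors)
  ratio <- if (k > 0) as.numeric(model@n) / k else Inf
  checks <- list(
    ratio = is.finite(ratio) && ratio >= ratioRange[1] && ratio <= ratioRange[2],
    R2 = isTRUE(s$R2 > minR2),
    q2 = isTRUE(s$q2 > minQ2)
  )
  c(checks,
    list(nPerDescriptor = ratio, SEE = s$SEE, F = s$F,
         pass = all(unlist(checks))))
}
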