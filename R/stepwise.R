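# residual sum of squares of OLS with intercept on selected columns;
# returns NA when the design is singular
.rssFor <- function(Z, y, cols) {
  if (!length(cols)) return(sum((y - mean(y))^2))
  fit <- .lm.fit(cbind(1, Z[, cols, drop = FALSE]), y)
  if (fit$rank < length(cols) + 1L) return(NA_real_)
  sum(fit$residuals^2)
}

#' Stepwise multiple linear regression
#'
#' Forward-entry / backward-removal variable selection driven by
#' partial-F significance tests, the procedure behind classic stepwise
#' MLR packages. Each forward step adds the candidate with the largest
#' partial F if its p-value is below `pEnter`; each backward step removes
#' the entered descriptor with the largest partial p-value if it exceeds
#' `pRemove`. The loop runs to stationarity; `pEnter < pRemove` is
#' enforced to exclude cycling, and entries stop while `n <= k + 2` so
#' the fit always keeps residual degrees of freedom.
#'
#' @param Z standardized descriptor matrix with column names.
#' @param y activity vector.
#' @param pEnter significance level to enter (default 0.05).
#' @param pRemove significance level to remove (default 0.10).
#' @param means,sds optional training standardization statistics (named by
#'   column) stored in the returned model for later prediction from raw
#'   descriptor values.
#' @param stages optional named integer vector (`initial`,
#'   `afterCorrelation`, `afterRedundancy`) recorded in the trace when the
#'   caller ran the filter cascade first.
#' @return list with `model` (a [QSARModel-class] including LOO q2) and
#'   `trace` (a [SelectionTrace-class] with the add/remove event log).
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(100 * 5), 100, 5,
#'             dimnames = list(NULL, paste0("d", 1:5)))
#' y <- 2 * Z[, 1] + rnorm(100, 0, 0.1)
#' stepwiseMLR(Z, y)$model
#' @export
stepwiseMLR <- function(Z, y, pEnter = 0.05, pRemove = 0.10,
                        means = NULL, sds = NULL, stages = NULL) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("V", seq_len(ncol(Z)))
  n <- length(y)
  .stopIfNot(nrow(Z) == n, "Z/y dimension mismatch")
  if (pEnter >= pRemove)
    stop("pEnter must be < pRemove (cycling risk)", call. = FALSE)
  sel <- integer(0)
  ev <- list()
  step <- 0L
  repeat {
    changed <- FALSE
    cand <- setdiff(seq_len(ncol(Z)), sel)
    if (length(cand) && n > length(sel) + 2L) {
      r0 <- .rssFor(Z, y, sel)
      df2 <- n - length(sel) - 2L
      Fv <- vapply(cand, function(jj) {
        r1 <- .rssFor(Z, y, c(sel, jj))
        if (is.na(r1)) return(-Inf)          # singular with this candidate
        if (r1 <= 0) return(Inf)
        (r0 - r1) / (r1 / df2)
      }, 0)
      best <- which.max(Fv)
      if (is.finite(Fv[best]) || is.infinite(Fv[best]) && Fv[best] > 0) {
        pv <- pf(Fv[best], 1, df2, lower.tail = FALSE)
        if (pv < pEnter) {
          sel <- c(sel, cand[best])
          step <- step + 1L
          ev[[length(ev) + 1L]] <- data.frame(
            step = step, action = "add",
            descriptor = colnames(Z)[cand[best]],
            statistic = Fv[best], p = pv)
          changed <- TRUE
        }
      }
    }
    if (length(sel)) {
      r1 <- .rssFor(Z, y, sel)
      df2 <- n - length(sel) - 1L
      pv <- vapply(seq_along(sel), function(m) {
        r0 <- .rssFor(Z, y, sel[-m])
        pf((r0 - r1) / (r1 / df2), 1, df2, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pv)
      if (pv[worst] > pRemove) {
        step <- step + 1L
        ev[[length(ev) + 1L]] <- data.frame(
          step = step, action = "remove",
          descriptor = colnames(Z)[sel[worst]],
          statistic = NA_real_, p = pv[worst])
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel <- sort(sel)
  selNames <- colnames(Z)[sel]
  if (length(sel)) {
    fit <- .lm.fit(cbind(1, Z[, sel, drop = FALSE]), y)
    if (fit$rank < length(sel) + 1L)
      stop("final design is singular in columns: ",
           paste(selNames, collapse = ", "), call. = FALSE)
    coefs <- fit$coefficients
    pred <- y - fit$residuals
    stats <- fitStats(y, pred, k = length(sel))
    stats$q2 <- if (n > length(sel) + 2L)
      looQ2(Z[, sel, drop = FALSE], y) else NA_real_
    intercept <- unname(coefs[1])
    beta <- unname(coefs[-1])
  } else {
    intercept <- mean(y)
    beta <- numeric(0)
    stats <- list(R = NA_real_, R2 = 0, R2adj = NA_real_,
                  SEE = sd(y), F = NA_real_, p = NA_real_, n = n, k = 0L,
                  q2 = NA_real_)
  }
  mm <- if (is.null(means)) rep(NA_real_, length(sel)) else
    unname(means[selNames])
  ss <- if (is.null(sds)) rep(NA_real_, length(sel)) else
    unname(sds[selNames])
  model <- new("QSARModel", descriptors = selNames, coefficients = beta,
               intercept = intercept, means = mm, sds = ss,
               n = as.integer(n), stats = stats)
  counts <- c(
    initial = if (!is.null(stages)) unname(stages["initial"]) else ncol(Z),
    afterCorrelation = if (!is.null(stages))
      unname(stages["afterCorrelation"]) else ncol(Z),
    afterRedundancy = if (!is.null(stages))
      unname(stages["afterRedundancy"]) else ncol(Z),
    afterStepwise = length(sel))
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(step = integer(), action = character(),
               descriptor = character(), statistic = numeric(),
               p = numeric())
  trace <- new("SelectionTrace",
               counts = setNames(as.integer(counts), names(counts)),
               events = events)
  list(model = model, trace = trace)
}
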