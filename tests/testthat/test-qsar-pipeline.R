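test_that("pFAR transform is -log10 with a guarded domain", {
  expect_equal(round(farToPfar(46.4), 2), -1.67)
  expect_equal(round(farToPfar(0.5), 2), 0.30)
  expect_identical(farToPfar(1), 0)
  expect_true(all(diff(farToPfar(c(0.5, 1, 10, 46.4))) < 0))  # decreasing
  expect_error(farToPfar(0), "> 0")
  expect_error(farToPfar(-2), "> 0")
})

test_that("standardization gives exact z-scores and handles degenerate columns", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  expect_message(std <- standardizeDescriptors(X), "zero-variance")
  expect_identical(std$dropped, "b")
  expect_equal(unname(std$Z[, "a"]), c(-1, 0, 1))  # sample SD (n - 1)
  again <- standardizeDescriptors(std$Z)
  expect_lt(max(abs(again$Z - std$Z)), 1e-12)      # idempotent
  expect_error(standardizeDescriptors(cbind(a = c(1, 1, 1))), "constant")
})

test_that("correlation filter keeps |r| >= threshold and matches a brute recount", {
  set.seed(11)
  n <- 200
  # signal columns share a latent factor so each carries a marginal
  # correlation well above the 0.1 cut
  f <- rnorm(n)
  signal <- sqrt(0.3) * f + sqrt(0.7) * matrix(rnorm(n * 50), n, 50)
  y <- rowSums(signal) + rnorm(n, 0, 2)
  noise <- matrix(rnorm(n * 950), n, 950)
  X <- cbind(signal, noise)
  colnames(X) <- sprintf("c%04d", 1:1000)
  Z <- standardizeDescriptors(X)$Z
  kept <- correlationFilter(Z, y, threshold = 0.1)
  expect_true(all(colnames(Z)[1:50] %in% kept))
  # independent recount
  rs <- apply(Z, 2, function(col) cor(col, y))
  expect_identical(kept, colnames(Z)[abs(rs) >= 0.1])
  # exact cases
  Z2 <- cbind(same = y, orth = residuals(lm(rnorm(n) ~ y)))
  Z2 <- standardizeDescriptors(Z2)$Z
  expect_identical(correlationFilter(Z2, y), "same")
  expect_error(correlationFilter(Z, rep(1, n)), "constant")
})

test_that("redundancy filter eliminates the weaker member of each collinear pair", {
  set.seed(1)
  y <- rnorm(60)
  a <- y + rnorm(60, 0, 0.5)
  Z <- standardizeDescriptors(cbind(dup1 = a, dup2 = a, weak = rnorm(60)))$Z
  kept <- redundancyFilter(Z, y, threshold = 0.85)
  expect_true(sum(c("dup1", "dup2") %in% kept) == 1L)
  expect_identical(kept[1], "dup1")  # tie broken by column order
  # sub-threshold pairs both survive
  set.seed(2)
  u <- rnorm(200); v <- 0.5 * u + sqrt(0.75) * rnorm(200)
  Zp <- standardizeDescriptors(cbind(u = u, v = v))$Z
  expect_identical(redundancyFilter(Zp, rnorm(200), threshold = 0.85),
                   c("u", "v"))
})

test_that("block-correlated matrices are pruned to each block's best y-correlate", {
  d <- genPlanted(n = 200, p = 50, kTrue = 0, beta = numeric(0),
                  noiseSd = 1, nBlocks = 5, rho = 0.95, seed = 4)
  X <- datasetX(d)
  set.seed(400)
  y <- rnorm(200)
  Z <- standardizeDescriptors(X)$Z
  kept <- redundancyFilter(Z, y, threshold = 0.85)
  C <- abs(cor(Z[, kept, drop = FALSE]))
  diag(C) <- 0
  expect_lt(max(C), 0.85)          # exhaustive pair check on survivors
  blocks <- rep(1:5, each = 10)
  ry <- abs(apply(Z, 2, cor, y))
  for (b in 1:5) {
    members <- colnames(Z)[blocks == b]
    surv <- intersect(kept, members)
    expect_length(surv, 1L)
    expect_identical(surv, members[which.max(ry[members])])
  }
})

test_that("stepwise recovers a single strong predictor with its coefficient", {
  set.seed(1)
  Z <- matrix(rnorm(100 * 11), 100, 11,
              dimnames = list(NULL, c("z1", sprintf("n%02d", 1:10))))
  Z <- standardizeDescriptors(Z)$Z
  y <- 2 * Z[, "z1"] + rnorm(100, 0, 0.01)
  sw <- stepwiseMLR(Z, y)
  expect_true("z1" %in% sw$model@descriptors)
  expect_equal(sw$model@coefficients[match("z1", sw$model@descriptors)],
               2, tolerance = 0.01)
  expect_gt(sw$model@stats$R2, 0.99)
})

test_that("stepwise false-entry rate under a pure-noise null matches pEnter", {
  # single candidate: entry probability is pEnter itself
  entered1 <- vapply(1:100, function(s) {
    set.seed(s)
    Z <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x"))
    y <- rnorm(50)
    length(stepwiseMLR(Z, y)$model@descriptors) > 0L
  }, NA)
  ci1 <- qbinom(c(0.005, 0.995), 100, 0.05)
  expect_gte(sum(entered1), ci1[1])
  expect_lte(sum(entered1), ci1[2])
  # ten candidates: family entry probability 1 - 0.95^10
  entered10 <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    Z <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(NULL, sprintf("x%02d", 1:10)))
    y <- rnorm(100)
    length(stepwiseMLR(Z, y)$model@descriptors) > 0L
  }, NA)
  ci10 <- qbinom(c(0.005, 0.995), 100, 1 - 0.95^10)
  expect_gte(sum(entered10), ci10[1])
  expect_lte(sum(entered10), ci10[2])
})

test_that("stepwise configuration and singularity guards fire", {
  Z <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(stepwiseMLR(Z, rnorm(20), pEnter = 0.1, pRemove = 0.05),
               "pEnter")
  # a duplicated column can never produce a singular final fit: the
  # forward step skips candidates that would break the design
  set.seed(3)
  y <- rnorm(30)
  x <- y + rnorm(30, 0, 0.1)
  Zs <- standardizeDescriptors(cbind(a = x, b = x))$Z  # identical columns
  sw <- stepwiseMLR(Zs, y)
  expect_identical(sw$model@descriptors, "a")
})

test_that("fit statistics follow their definitions", {
  t3 <- qsarFixture("table3")
  s <- fitStats(t3$observed_pfar, t3$predicted_pfar, k = 6)
  expect_equal(s$R2, 0.927, tolerance = 0.005)
  expect_equal(s$SEE, 0.197, tolerance = 0.005)
  perfect <- fitStats(t3$observed_pfar, t3$observed_pfar, k = 6)
  expect_identical(perfect$R2, 1)
  expect_identical(perfect$SEE, 0)
  expect_error(fitStats(1:5, 1:5, k = 4), "n > k")
  # R^2 via squared correlation equals 1 - SSE/SST for an OLS fit
  set.seed(8)
  Z <- matrix(rnorm(60 * 3), 60, 3)
  y <- Z %*% c(1, -1, 0.5) + rnorm(60)
  fit <- lm(y ~ Z)
  s2 <- fitStats(as.vector(y), fitted(fit), k = 3)
  expect_equal(s2$R2, s2$R^2, tolerance = 1e-10)
})

test_that("LOO q2 reaches 1 on noise-free data and <= 0 on unrelated predictors", {
  d <- genPlanted(n = 30, p = 3, kTrue = 3, beta = c(1, -2, 0.5),
                  noiseSd = 0, seed = 6)
  expect_equal(looQ2(scale(datasetX(d)), datasetY(d)), 1, tolerance = 1e-6)
  # an unrelated predictor makes LOO predictions worse than the mean in
  # nearly every replicate
  q2null <- vapply(1:50, function(s) {
    set.seed(s)
    looQ2(matrix(rnorm(30), 30, 1), rnorm(30))
  }, 0)
  expect_lt(median(q2null), 0)
  expect_gte(sum(q2null <= 0), 44L)
})

test_that("model acceptance checks implement the 3-6x / R2 / q2 rules", {
  mk <- function(n, k, R2, q2) {
    new("QSARModel", descriptors = sprintf("d%d", seq_len(k)),
        coefficients = rep(1, k), intercept = 0, means = rep(NA_real_, k),
        sds = rep(NA_real_, k), n = as.integer(n),
        stats = list(R2 = R2, q2 = q2, SEE = 0.2, F = 30))
  }
  good <- validateModel(mk(23, 6, 0.927, 0.927))
  expect_true(good$ratio && good$R2 && good$q2 && good$pass)
  expect_false(validateModel(mk(23, 10, 0.927, 0.927))$ratio)  # 2.3 < 3
  expect_false(validateModel(mk(23, 6, 0.65, 0.927))$R2)
  expect_false(validateModel(mk(23, 6, 0.927, 0.4))$q2)
})
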