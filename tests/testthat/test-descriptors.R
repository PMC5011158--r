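test_that("single pair at a bin midpoint gives exactly the property product", {
  coords <- cbind(c(0, 5.35), 0, 0)
  m <- pointMolecule(coords, c(1, 1))
  expect_identical(unname(rdfDescriptor(m, "p", bins = 54)), 1)
  m2 <- pointMolecule(coords, c(2, 3))
  expect_identical(unname(rdfDescriptor(m2, "p", bins = 54)), 6)
})

test_that("zero property channel annihilates every descriptor", {
  m <- genPointCloud(10, seed = 2)
  atomChannel(m, "zero") <- rep(0, 10)
  expect_identical(unname(rdfDescriptor(m, "zero")), rep(0, 128))
  expect_identical(unname(autocorr3dDescriptor(m, "zero")), rep(0, 12))
})

test_that("3D autocorrelation bins partition pairs with the 1-Angstrom convention", {
  m <- pointMolecule(cbind(c(0, 9.5), 0, 0), c(1, 1))
  v <- autocorr3dDescriptor(m, "p")
  expect_identical(unname(v["9"]), 1)
  expect_identical(sum(v), 1)
  close <- pointMolecule(cbind(c(0, 0.5), 0, 0), c(1, 1))
  expect_identical(sum(autocorr3dDescriptor(close, "p")), 0)
  # boundary: a pair at exactly 2.0 A belongs to bin 2, not bin 1
  edge <- pointMolecule(cbind(c(0, 2), 0, 0), c(1, 1))
  ve <- autocorr3dDescriptor(edge, "p")
  expect_identical(unname(ve["1"]), 0)
  expect_identical(unname(ve["2"]), 1)
})

test_that("kernels match the brute-force pair-sum oracle on random clouds", {
  for (seed in 1:30) {
    n <- 3 + (seed %% 18)
    m <- genPointCloud(n, seed = seed)
    coords <- atomCoords(m)
    p <- atomChannel(m, "SigChg")
    bins <- c(1, 12, 54, 57, 76, 86, 128)
    got <- rdfDescriptor(m, "SigChg", bins = bins)
    want <- vapply(bins, function(k) bruteRdf(coords, p, k), 0)
    expect_equal(unname(got), want, tolerance = 1e-12)
    gotA <- autocorr3dDescriptor(m, "SigChg")
    wantA <- vapply(1:12, function(k) bruteAutocorr(coords, p, k), 0)
    expect_equal(unname(gotA), wantA, tolerance = 1e-12)
  }
})

test_that("descriptors are invariant under rigid rotation and translation", {
  m <- genPointCloud(15, seed = 4)
  ref <- c(rdfDescriptor(m, "PiChg"), autocorr3dDescriptor(m, "PiChg"))
  for (seed in 1:5) {
    R <- randomRotation(seed)
    shift <- seed * c(3.1, -2.7, 11.9)
    moved <- m
    xyz <- sweep(atomCoords(m) %*% t(R), 2, -shift)
    moved@atoms$x <- xyz[, 1]; moved@atoms$y <- xyz[, 2]
    moved@atoms$z <- xyz[, 3]
    got <- c(rdfDescriptor(moved, "PiChg"), autocorr3dDescriptor(moved, "PiChg"))
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("descriptors are quadratic in the property channel", {
  m <- genPointCloud(12, seed = 9)
  p <- atomChannel(m, "TotChg")
  atomChannel(m, "scaled") <- 3 * p
  expect_equal(rdfDescriptor(m, "scaled", bins = 40:60),
               9 * rdfDescriptor(m, "TotChg", bins = 40:60),
               tolerance = 1e-12)
  expect_equal(autocorr3dDescriptor(m, "scaled"),
               9 * autocorr3dDescriptor(m, "TotChg"), tolerance = 1e-12)
})

test_that("bin names map to the documented distance ranges", {
  expect_equal(binRange(86, "RDF"), c(8.5, 8.6))
  expect_equal(binRange(76, "RDF"), c(7.5, 7.6))
  expect_equal(binRange(54, "RDF"), c(5.3, 5.4))
  expect_equal(binRange(57, "RDF"), c(5.6, 5.7))
  expect_equal(binRange(9, "3DACorr"), c(9, 10))
  expect_error(binRange(129, "RDF"), "1\\.\\.128")
  expect_error(rdfDescriptor(genPointCloud(3, seed = 1), "SigChg", bins = 0),
               "1\\.\\.128")
  expect_error(autocorr3dDescriptor(genPointCloud(3, seed = 1), "SigChg",
                                    bins = 13), "1\\.\\.12")
})

test_that("computeDescriptors yields the 1120 finite computable values", {
  q <- computeChannels(embed3d(readQuercetin(), seed = 1))
  v <- computeDescriptors(q)
  expect_identical(dim(v), c(1L, 1120L))
  expect_true(all(is.finite(v)))
  expect_true(all(c("RDF_PiChg_86", "RDF_SigChg_76", "3DACorr_TotChg_9",
                    "RDF_LpEN_54", "3DACorr_PiChg_9", "RDF_SigChg_57")
                  %in% colnames(v)))
  # translation leaves the whole vector unchanged
  shifted <- q
  shifted@atoms$x <- q@atoms$x + 10
  shifted@atoms$y <- q@atoms$y + 10
  shifted@atoms$z <- q@atoms$z + 10
  expect_lt(max(abs(computeDescriptors(shifted) - v)), 1e-10)
})

test_that("registry arithmetic matches the declared family sizes", {
  reg <- descriptorRegistry()
  expect_identical(registryTotal(reg), 1252L)
  expect_identical(registryTotal(reg[reg$family == "RDF", ]), 1024L)
  expect_identical(registryTotal(reg[0, ]), 0L)
  expect_identical(sum(reg$count[reg$computable]), 1120L)
  expect_length(registryNames(computableOnly = FALSE), 1252L)
  expect_length(registryNames(computableOnly = TRUE), 1120L)
})
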