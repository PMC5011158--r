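test_that("symmetric homonuclear pair carries zero sigma charges", {
  m <- Molecule3D("eth", atoms = data.frame(element = c("C", "C"),
                                            charge = 0L, x = c(0, 1.5),
                                            y = 0, z = 0),
                  bonds = data.frame(i = 1L, j = 2L, order = 1L))
  expect_identical(peoeSigma(m), c(0, 0))
})

test_that("PEOE sigma charges match the independent step-by-step reference", {
  cases <- list(
    methane = "C mol",
    water = "O mol",
    ethanol = "CCO mol",
    pyridine = "c1ccncc1 mol",
    chloroethane = "CCCl mol"
  )
  for (smi in cases) {
    m <- readStructures(smi, format = "smiles", text = TRUE)[[1]]
    hyb <- flavoqsar:::.hybridization(m)
    b <- molBonds(m)
    ref <- referencePeoe(atomElements(m), hyb, cbind(b$i, b$j),
                         q0 = as.numeric(m@atoms$charge))
    expect_equal(peoeSigma(m), ref, tolerance = 1e-12)
  }
  # methane: carbon balances its four hydrogens exactly
  meth <- readStructures("C mol", format = "smiles", text = TRUE)[[1]]
  q <- peoeSigma(meth)
  el <- atomElements(meth)
  expect_equal(q[el == "C"], -4 * q[el == "H"][1], tolerance = 1e-12)
})

test_that("sigma charges conserve the net molecular charge", {
  q <- peoeSigma(readQuercetin())
  expect_lt(abs(sum(q)), 1e-6)
  ion <- readStructures("C(C(=O)[O-])[NH3+] zwit", format = "smiles",
                        text = TRUE)[[1]]
  expect_lt(abs(sum(peoeSigma(ion)) - 0), 1e-6)
  anion <- readStructures("CC(=O)[O-] acetate", format = "smiles",
                          text = TRUE)[[1]]
  expect_lt(abs(sum(peoeSigma(anion)) - (-1)), 1e-6)
})

test_that("unparameterized elements are rejected with atom context", {
  m <- Molecule3D("sil", atoms = data.frame(element = c("Si", "H"),
                                            charge = 0L, x = c(0, 1.5),
                                            y = 0, z = 0),
                  bonds = data.frame(i = 1L, j = 2L, order = 1L))
  expect_error(peoeSigma(m), "Si.*atom 1")
})

test_that("all channels are equivariant under atom permutation and blind to coordinates", {
  m <- computeChannels(readQuercetin())
  perm <- rev(seq_len(nAtoms(m)))
  inv <- order(perm)
  b <- molBonds(m)
  permuted <- Molecule3D(molId(m),
                         atoms = m@atoms[perm, ],
                         bonds = data.frame(i = inv[b$i], j = inv[b$j],
                                            order = b$order))
  permuted <- computeChannels(permuted)
  for (ch in channelNames(m))
    expect_equal(atomChannel(permuted, ch), atomChannel(m, ch)[perm],
                 tolerance = 1e-12, label = ch)
  # charges are a graph property: embedding with different seeds changes
  # nothing
  e1 <- computeChannels(embed3d(readQuercetin(), seed = 1))
  e2 <- computeChannels(embed3d(readQuercetin(), seed = 2))
  expect_identical(atomChannel(e1, "SigChg"), atomChannel(e2, "SigChg"))
  expect_identical(atomChannel(e1, "PiChg"), atomChannel(e2, "PiChg"))
})

test_that("sigma charges are converged at the default iteration count", {
  # the damped series is geometric, so doubling the iterations at the
  # default damping must not move any charge perceptibly
  for (smi in c("CCO mol", quercetinSmiles)) {
    m <- readStructures(smi, format = "smiles", text = TRUE)[[1]]
    q6 <- peoeSigma(m, iterations = 6L, damping = 0.5)
    q12 <- peoeSigma(m, iterations = 12L, damping = 0.5)
    q24 <- peoeSigma(m, iterations = 24L, damping = 0.5)
    expect_lt(max(abs(q6 - q12)), 5e-3)
    # and the residual shrinks geometrically with the damping
    expect_lt(max(abs(q12 - q24)), max(abs(q6 - q12)) / 8)
  }
})

test_that("pi charges vanish on benzene and saturated molecules", {
  benzene <- readStructures("c1ccccc1 mol", format = "smiles", text = TRUE)[[1]]
  expect_equal(piCharges(benzene), rep(0, nAtoms(benzene)),
               tolerance = 1e-12)
  ethane <- readStructures("CC mol", format = "smiles", text = TRUE)[[1]]
  expect_identical(piCharges(ethane), rep(0, nAtoms(ethane)))
})

test_that("pyridine nitrogen draws negative pi charge, system sums to zero", {
  p <- readStructures("c1ccncc1 mol", format = "smiles", text = TRUE)[[1]]
  q <- piCharges(p)
  el <- atomElements(p)
  expect_lt(q[el == "N"], 0)
  expect_gt(sum(q[el == "C"]), 0)
  expect_lt(abs(sum(q)), 1e-10)
})

test_that("every conjugated system's pi charges sum to zero", {
  for (smi in c(quercetinSmiles, "O=c1ccocc1 pyranone",
                "c1ccc(-c2ccccc2)cc1 biphenyl")) {
    m <- readStructures(smi, format = "smiles", text = TRUE)[[1]]
    expect_lt(abs(sum(piCharges(m))), 1e-10)
  }
})

test_that("total charge channel is the sum of sigma and pi and conserves charge", {
  m <- computeChannels(readQuercetin())
  expect_equal(atomChannel(m, "TotChg"),
               atomChannel(m, "SigChg") + atomChannel(m, "PiChg"),
               tolerance = 1e-12)
  expect_lt(abs(sum(atomChannel(m, "TotChg"))), 1e-6)
})

test_that("lone-pair electronegativity is the PEOE polynomial at the converged charge", {
  w <- readStructures("O water", format = "smiles", text = TRUE)[[1]]
  q <- peoeSigma(w)
  lp <- lonePairEN(w)
  el <- atomElements(w)
  qO <- q[el == "O"]
  # hand evaluation of the O(sp3) polynomial a + b q + c q^2
  expect_equal(lp[el == "O"], 14.18 + 12.92 * qO + 1.39 * qO^2,
               tolerance = 1e-12)
  expect_identical(lp[el == "H"], c(0, 0))
  # alkanes carry no lone pairs at all
  hex <- readStructures("CCCCCC mol", format = "smiles", text = TRUE)[[1]]
  expect_identical(lonePairEN(hex), rep(0, nAtoms(hex)))
  # symmetry-equivalent oxygens get identical values
  glycol <- readStructures("OCCO mol", format = "smiles", text = TRUE)[[1]]
  lpg <- lonePairEN(glycol)
  ox <- which(atomElements(glycol) == "O")
  expect_equal(lpg[ox[1]], lpg[ox[2]], tolerance = 1e-12)
  expect_true(all(lpg[ox] > 0))
})
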