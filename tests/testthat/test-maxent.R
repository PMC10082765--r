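test_that("disjoint perfect matchings give uniform multilink probabilities", {
  fit <- fitConfigurationModel(symmetricMatchingNet())
  p <- multilinkProbabilities(fit, rep(1:3, each = 3), rep(1:3, 3))
  expect_equal(p$p10, rep(1 / 3, 9), tolerance = 1e-8)
  expect_equal(p$p01, rep(1 / 3, 9), tolerance = 1e-8)
  expect_equal(p$p00, rep(1 / 3, 9), tolerance = 1e-8)
  expect_equal(predictTransductive(fit, rep(1:3, each = 3), rep(1:3, 3)),
               rep(0.5, 9), tolerance = 1e-8)
})

test_that("empty network yields zero multipliers and certain non-annotation", {
  net <- DuplexNetwork(ligandIds = c("L1", "L2"), proteinIds = c("P1", "P2"))
  fit <- fitConfigurationModel(net)
  expect_true(all(fit@xPos == 0) && all(fit@yNeg == 0))
  p <- multilinkProbabilities(fit, 1, 2)
  expect_equal(unlist(p), c(p10 = 0, p01 = 0, p00 = 1))
  expect_error(predictTransductive(fit, 1, 1), "conditional undefined")
  expect_error(predictInductive(fit), "no annotations")
})

test_that("constraints are recovered within tolerance on random networks", {
  for (seed in 1:5) {
    net <- randomDuplex(50, 80, 400, seed = seed)
    fit <- fitConfigurationModel(net, tol = 1e-10)
    expect_lte(fit@maxResidual, 1e-10)
    m <- fitProbabilityMatrices(fit)
    deg <- multidegrees(net)
    lig <- deg[deg$side == "ligand", ]; prt <- deg[deg$side == "protein", ]
    expect_equal(rowSums(m$p10), lig$k_pos, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(rowSums(m$p01), lig$k_neg, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(colSums(m$p10), prt$k_pos, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(colSums(m$p01), prt$k_neg, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("multilink probabilities are normalized to machine precision", {
  net <- randomDuplex(40, 30, 250, seed = 9)
  fit <- fitConfigurationModel(net)
  idx <- withr::with_seed(1, cbind(sample.int(40, 1000, TRUE),
                                   sample.int(30, 1000, TRUE)))
  p <- multilinkProbabilities(fit, idx[, 1], idx[, 2])
  expect_lt(max(abs(p$p10 + p$p01 + p$p00 - 1)), 1e-12)
  expect_error(multilinkProbabilities(fit, 41, 1), "out of range")
})

test_that("semi-inductive conditional equals the degree ratio at the fit", {
  net <- randomDuplex(30, 40, 220, seed = 5)
  fit <- fitConfigurationModel(net)
  m <- fitProbabilityMatrices(fit)
  deg <- multidegrees(net)
  lig <- deg[deg$side == "ligand" & deg$k_total > 0, ]
  # averaging the multilink probabilities over the unseen side reproduces
  # rho for every annotated ligand
  for (r in seq_len(nrow(lig))) {
    i <- match(lig$node_id[r], ligandIds(net))
    avg <- mean(m$p10[i, ]) / (mean(m$p10[i, ]) + mean(m$p01[i, ]))
    expect_equal(avg, lig$rho[r], tolerance = 1e-8)
    expect_equal(predictSemiInductive(fit, lig$node_id[r]), lig$rho[r])
  }
  expect_error(predictSemiInductive(fit, "L-missing"), "unknown ligand")

  # the Fig-style worked example: one positive, two negative annotations
  toy <- fitConfigurationModel(toyAnnotationNetwork())
  expect_equal(predictSemiInductive(toy, "LIG-A"), 1 / 3)
})

test_that("inductive conditional equals the global positive fraction", {
  net <- randomDuplex(25, 35, 180, seed = 8)
  fit <- fitConfigurationModel(net)
  expected <- numPositive(net) / (numPositive(net) + numNegative(net))
  expect_equal(predictInductive(fit), expected)
  m <- fitProbabilityMatrices(fit)
  expect_equal(mean(m$p10) / (mean(m$p10) + mean(m$p01)), expected,
               tolerance = 1e-8)
})

test_that("homogeneous networks give the closed-form edge probability", {
  # 4 ligands x 4 proteins, every ligand (1 pos, 1 neg), cyclic wiring
  lig <- paste0("L", 1:4); prt <- paste0("P", 1:4)
  net <- DuplexNetwork(
    positiveEdges = data.frame(ligand = lig, protein = prt),
    negativeEdges = data.frame(ligand = lig, protein = prt[c(2:4, 1)]))
  fit <- fitConfigurationModel(net)
  m <- fitProbabilityMatrices(fit)
  expect_equal(m$p10, matrix(numPositive(net) / 16, 4, 4),
               tolerance = 1e-8)
})

test_that("fixed-point solver matches the convex-dual oracle", {
  nOk <- 0
  for (seed in 1:50) {
    dims <- withr::with_seed(seed,
        c(sample(3:6, 1), sample(3:6, 1), sample(6:12, 1)))
    inst <- solvableRandomDuplex(dims[1], dims[2], dims[3], seed = seed)
    m <- fitProbabilityMatrices(inst$fit)
    o <- dualOracleProbabilities(inst$net)
    expect_lt(max(abs(m$p10 - o$p10)), 1e-6)
    expect_lt(max(abs(m$p01 - o$p01)), 1e-6)
    expect_lt(max(abs(m$p00 - o$p00)), 1e-6)
    nOk <- nOk + 1
  }
  expect_equal(nOk, 50)
})

test_that("repeated fits agree regardless of damping (unique optimum)", {
  # only pair probabilities are identified (multipliers carry a per-layer
  # rescaling gauge), so agreement is asserted on the probabilities
  net <- randomDuplex(12, 15, 70, seed = 21)
  m1 <- fitProbabilityMatrices(fitConfigurationModel(net, damping = 0.5))
  m2 <- fitProbabilityMatrices(fitConfigurationModel(net, damping = 0.9))
  expect_equal(m1$p10, m2$p10, tolerance = 1e-7)
  expect_equal(m1$p01, m2$p01, tolerance = 1e-7)
})

test_that("structurally saturated nodes are flagged with a warning", {
  net <- DuplexNetwork(
    positiveEdges = data.frame(ligand = c("L1", "L2"),
                               protein = c("P1", "P2")),
    negativeEdges = data.frame(ligand = c("L1", "L2"),
                               protein = c("P2", "P1")))
  # every node annotates the whole opposite side: boundary solution
  expect_warning(fit <- fitConfigurationModel(net), "saturated")
  expect_setequal(fit@saturatedNodes, c("L1", "L2", "P1", "P2"))
})

test_that("predictPair routes each pair to the scenario of its endpoints", {
  net <- randomDuplex(20, 20, 120, seed = 31)
  fit <- fitConfigurationModel(net)
  pairs <- data.frame(
    ligand_id = c("L1", "L1", "Lnew", "Lnew"),
    protein_id = c("P1", "Pnew", "P1", "Pnew"))
  out <- predictPair(fit, pairs)
  expect_equal(out$scenario, c("transductive", "semi_inductive",
                               "semi_inductive", "inductive"))
  expect_equal(out$score[1], predictTransductive(fit, "L1", "P1"))
  expect_equal(out$score[2], predictSemiInductive(fit, "L1", "ligand"))
  expect_equal(out$score[3], predictSemiInductive(fit, "P1", "protein"))
  expect_equal(out$score[4], predictInductive(fit))
})
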