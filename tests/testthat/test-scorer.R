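# small synthetic training sets keep these unit tests fast; the full
# inductive-recovery experiment lives in test-acceptance.R

tinyWorld <- function(seed = 5, nLig = 30, nProt = 24, nAnn = 260) {
  genFeatureWorld(syntheticWorldConfig(nLigands = nLig, nProteins = nProt,
                                       nAnnotations = nAnn, seed = seed))
}

test_that("training separates a linear rule on the embeddings", {
  # labels from a fixed linear rule on the ligand embedding: learnable to
  # near-perfect training accuracy
  world <- tinyWorld()
  lp <- hashedLigandProvider(); pp <- hashedProteinProvider()
  pairs <- world$pairs
  EL <- embedStructures(lp, world$ligandStructures[pairs$ligand_id])
  wTrue <- withr::with_seed(8, stats::rnorm(ncol(EL)))
  z <- as.vector(EL %*% wTrue)
  # separable with a margin: drop the middle quintiles of the linear score
  keep <- z > stats::quantile(z, 0.6) | z < stats::quantile(z, 0.4)
  pairs <- pairs[keep, ]
  pairs$label <- ifelse(z[keep] > stats::median(z), "positive", "negative")
  model <- trainScorer(pairs, world$ligandStructures,
                       world$proteinSequences, lp, pp, patience = 80L,
                       seed = 3)
  sc <- predictPairsScore(model, pairs, world$ligandStructures,
                          world$proteinSequences, lp, pp)
  acc <- mean((sc > 0.5) == (pairs$label == "positive"))
  expect_gte(acc, 0.95)
})

test_that("training is reproducible under seed and rejects bad input", {
  world <- tinyWorld()
  lp <- hashedLigandProvider(); pp <- hashedProteinProvider()
  m1 <- trainScorer(world$pairs, world$ligandStructures,
                    world$proteinSequences, lp, pp, maxEpochs = 40L,
                    seed = 11)
  m2 <- trainScorer(world$pairs, world$ligandStructures,
                    world$proteinSequences, lp, pp, maxEpochs = 40L,
                    seed = 11)
  expect_identical(m1@lossTrace, m2@lossTrace)
  expect_identical(m1@weights, m2@weights)

  onlyPos <- world$pairs[world$pairs$label == "positive", ]
  expect_error(trainScorer(onlyPos, world$ligandStructures,
                           world$proteinSequences, lp, pp),
               "both classes")
  badPairs <- data.frame(ligand_id = "nope", protein_id = "PRT0001",
                         label = c("positive", "negative"))
  expect_error(trainScorer(badPairs, world$ligandStructures,
                           world$proteinSequences, lp, pp,
                           valPairs = badPairs),
               "missing structure")
})

test_that("permuted labels carry no inductive signal", {
  world <- tinyWorld(seed = 9)
  lig <- ligandIds(world$network); prt <- proteinIds(world$network)
  hold <- withr::with_seed(10, list(L = sample(lig, 8), P = sample(prt, 6)))
  tr <- subset(world$pairs, !(ligand_id %in% hold$L) &
                            !(protein_id %in% hold$P))
  tr$label <- withr::with_seed(12, sample(tr$label))
  te <- expand.grid(ligand_id = hold$L, protein_id = hold$P,
                    stringsAsFactors = FALSE)
  te$label <- world$labels[cbind(te$ligand_id, te$protein_id)]
  lp <- hashedLigandProvider(); pp <- hashedProteinProvider()
  model <- trainScorer(tr, world$ligandStructures, world$proteinSequences,
                       lp, pp, seed = 2)
  sc <- predictPairsScore(model, te, world$ligandStructures,
                          world$proteinSequences, lp, pp)
  expect_lt(abs(aurocScore(te$label, sc) - 0.5), 0.15)
})

test_that("forward pass matches hand-rolled matrix arithmetic", {
  # 2-unit toy network evaluated by hand
  w <- list(W1L = matrix(c(1, 0, 0, 1), 2, 2), b1L = c(0.1, -0.1),
            W1P = matrix(c(0, 1, 1, 0), 2, 2), b1P = c(0, 0),
            W2 = matrix(0.5, 5, 2), b2 = c(0, 0.2),
            W3 = matrix(c(1, -1), 2, 1), b3 = 0,
            W4 = matrix(2, 1, 1), b4 = -1)
  xl <- c(0.3, 0.4); xp <- c(0.6, 0.2)
  h1l <- xl + c(0.1, -0.1)              # identity branch + bias
  h1p <- c(xp[2], xp[1])                # swapped branch
  cr <- h1l[1] * h1p[1]                 # rank-1 interaction
  h1 <- c(h1l, h1p, cr)
  h2 <- pmax(colSums(h1 * matrix(0.5, 5, 2)) + c(0, 0.2), 0)
  h3 <- pmax(sum(h2 * c(1, -1)), 0)
  expected <- 1 / (1 + exp(-(2 * h3 - 1)))
  got <- bindnet:::.forward(w, matrix(xl, 1), matrix(xp, 1), rank = 1L)$out
  expect_equal(got, expected)
})

test_that("scores are deterministic and strictly inside (0, 1)", {
  world <- tinyWorld(seed = 3)
  lp <- hashedLigandProvider(); pp <- hashedProteinProvider()
  model <- trainScorer(world$pairs, world$ligandStructures,
                       world$proteinSequences, lp, pp, maxEpochs = 30L,
                       seed = 1)
  s1 <- predictScore(model, world$ligandStructures[1:5],
                     world$proteinSequences[1:5], lp, pp)
  s2 <- predictScore(model, world$ligandStructures[1:5],
                     world$proteinSequences[1:5], lp, pp)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("ensembles average their members", {
  world <- tinyWorld(seed = 7)
  lp <- hashedLigandProvider(); pp <- hashedProteinProvider()
  ens <- trainEnsemble(world$pairs, world$ligandStructures,
                       world$proteinSequences, lp, pp, nFolds = 3L,
                       maxEpochs = 25L, seed = 4)
  expect_length(ens@members, 3L)
  pairs <- world$pairs[1:10, ]
  S <- predictScore(ens, world$ligandStructures[pairs$ligand_id],
                    world$proteinSequences[pairs$protein_id], lp, pp,
                    memberScores = TRUE)
  expect_equal(dim(S), c(3L, 10L))
  mean_sc <- predictPairsScore(ens, pairs, world$ligandStructures,
                               world$proteinSequences, lp, pp)
  expect_equal(colMeans(S), mean_sc)

  # identical members collapse to any single member
  same <- new("ScorerEnsemble", members = list(ens@members[[1]],
                                            ens@members[[1]]))
  s <- predictPairsScore(same, pairs, world$ligandStructures,
                         world$proteinSequences, lp, pp)
  one <- predictPairsScore(ens@members[[1]], pairs, world$ligandStructures,
                           world$proteinSequences, lp, pp)
  expect_equal(s, one)
})
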