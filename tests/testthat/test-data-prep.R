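mkRecords <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(ligand_id = r[[1]], protein_id = r[[2]],
               constant_type = r[[3]], value_nM = as.numeric(r[[4]]),
               temperature_C = if (length(r) > 4) as.numeric(r[[5]])
                               else NA_real_,
               source = "test", stringsAsFactors = FALSE)))
}

test_that("temperature filter keeps the assay range and honours keepMissing", {
  rec <- mkRecords(list("L1", "P1", "Kd", 10, 37),
                   list("L2", "P1", "Kd", 10, 4),
                   list("L3", "P1", "Kd", 10, NA))
  expect_equal(filterTemperature(rec)$ligand_id, c("L1", "L3"))
  expect_equal(filterTemperature(rec, keepMissing = FALSE)$ligand_id, "L1")
  expect_equal(filterTemperature(rec, low = 0, high = 50)$ligand_id,
               c("L1", "L2", "L3"))
})

test_that("kinetic thresholding labels, aggregates and drops correctly", {
  out <- labelFromKinetics(mkRecords(list("L1", "P1", "Kd", 500)))
  expect_equal(out$pairs$label, "positive")

  out <- labelFromKinetics(mkRecords(list("L1", "P1", "Ki", 1e6)))
  expect_equal(out$pairs$label, "negative")  # boundary inclusive

  out <- labelFromKinetics(mkRecords(list("L1", "P1", "Kd", 1e4)))
  expect_equal(nrow(out$pairs), 0L)
  expect_equal(out$dropped$reason, "intermediate affinity")

  # conflicting evidence across the two thresholds drops the pair
  out <- labelFromKinetics(mkRecords(list("L1", "P1", "Kd", 100),
                                     list("L1", "P1", "IC50", 1e7)))
  expect_equal(out$dropped$reason, "conflicting evidence")

  # median aggregation within constant type: 10, 1e8 -> median per type
  out <- labelFromKinetics(mkRecords(list("L1", "P1", "Kd", 10),
                                     list("L1", "P1", "Kd", 20),
                                     list("L1", "P1", "Kd", 1e8)))
  expect_equal(out$pairs$label, "positive")  # median(10,20,1e8) = 20

  expect_error(labelFromKinetics(mkRecords(list("L1", "P1", "Kd", -5))),
               "positive")

  # monotonicity: lowering the positive threshold never creates positives
  rec <- withr::with_seed(4, mkRecords(
    list("L1", "P1", "Kd", 10^runif(1, 0, 8)),
    list("L2", "P1", "Kd", 10^runif(1, 0, 8)),
    list("L3", "P2", "Kd", 10^runif(1, 0, 8))))
  posAt <- function(thr) {
    p <- labelFromKinetics(rec, posMaxnM = thr)$pairs
    p[p$label == "positive", c("ligand_id", "protein_id")]
  }
  loose <- posAt(1e3); strict <- posAt(1e1)
  expect_true(all(paste(strict$ligand_id, strict$protein_id) %in%
                  paste(loose$ligand_id, loose$protein_id)))
})

test_that("curated positives merge unless contradicted by experiment", {
  experimental <- labelFromKinetics(mkRecords(
    list("L1", "P1", "Kd", 1e7),     # experimental negative
    list("L2", "P1", "Kd", 10)))$pairs
  curated <- data.frame(ligand_id = c("L1", "L2", "L3"),
                        protein_id = "P1")
  merged <- mergeCuratedPositives(curated, experimental)
  # L1 excluded entirely (negative kinetic evidence), L2 kept once as
  # experimental, L3 added as curated
  expect_equal(nrow(merged), 2L)
  expect_false("L1" %in% merged$ligand_id)
  expect_equal(merged$provenance[merged$ligand_id == "L2"], "experimental")
  expect_equal(merged$provenance[merged$ligand_id == "L3"],
               "curated_positive")
})

chainNet <- function() {
  # l1-p1-l2-p2-l3-p3-l4-p4 positive chain: distance(l1, p4) = 7
  DuplexNetwork(positiveEdges = data.frame(
    ligand = c("l1", "l2", "l2", "l3", "l3", "l4", "l4"),
    protein = c("p1", "p1", "p2", "p2", "p3", "p3", "p4")))
}

test_that("shortest-path distances are odd and match the chain example", {
  d <- shortestPathDistances(chainNet())
  expect_equal(d["l1", "p1"], 1)
  expect_equal(d["l1", "p4"], 7)
  expect_true(all(!is.finite(d) | d %% 2 == 1))
})

test_that("BFS distances equal the Floyd-Warshall oracle on random graphs", {
  for (seed in 1:5) {
    net <- randomDuplex(20, 20, 40, seed = seed, avoidSaturation = FALSE)
    expect_equal(shortestPathDistances(net), floydWarshallDistances(net),
                 ignore_attr = TRUE)
  }
})

test_that("training negatives sit at exactly the requested distance", {
  net <- chainNet()
  neg <- sampleNetworkNegatives(net, distance = 7, nSamples = 1, seed = 1)
  expect_equal(neg$ligand_id, "l1")
  expect_equal(neg$protein_id, "p4")
  expect_equal(neg$provenance, "network_derived")

  expect_warning(
    all7 <- sampleNetworkNegatives(net, distance = 7, nSamples = 10,
                                   seed = 1),
    "eligible")
  expect_true(isTRUE(attr(all7, "truncated")))

  # seeding contract on a larger pool
  big <- randomDuplex(30, 30, 55, seed = 2, avoidSaturation = FALSE)
  a <- sampleNetworkNegatives(big, 3, nSamples = 5, seed = 7)
  b <- sampleNetworkNegatives(big, 3, nSamples = 5, seed = 7)
  c <- sampleNetworkNegatives(big, 3, nSamples = 5, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # post-hoc verification against the independent oracle
  oracle <- floydWarshallDistances(big)
  expect_true(all(oracle[cbind(a$ligand_id, a$protein_id)] == 3))
})

test_that("evaluation negatives are finite, distant and train-disjoint", {
  # extend the chain so that an 11-hop pair exists
  net <- DuplexNetwork(positiveEdges = data.frame(
    ligand = c("l1", "l2", "l2", "l3", "l3", "l4", "l4", "l5", "l5",
               "l6", "l6"),
    protein = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p4", "p5",
                "p5", "p6")))
  ev <- buildEvalNegatives(net, minDistance = 11)
  oracle <- floydWarshallDistances(net)
  expect_true(all(oracle[cbind(ev$ligand_id, ev$protein_id)] >= 11))
  expect_true(all(is.finite(ev$distance)))
  expect_true(paste("l1", "p6") %in% paste(ev$ligand_id, ev$protein_id))

  # distance-9 pairs stay out
  expect_false(paste("l1", "p5") %in% paste(ev$ligand_id, ev$protein_id))

  # unreachable pairs are excluded even though they are "far"
  iso <- DuplexNetwork(
    positiveEdges = data.frame(ligand = "lA", protein = "pA"),
    ligandIds = c("lA", "lB"), proteinIds = c("pA", "pB"))
  expect_equal(nrow(buildEvalNegatives(iso, minDistance = 11)), 0L)

  # training overlap removal and absolute negatives
  ev2 <- buildEvalNegatives(net, minDistance = 11,
      absoluteNegatives = data.frame(ligand_id = "l9", protein_id = "p9"),
      trainPairs = data.frame(ligand_id = "l1", protein_id = "p6"))
  expect_false(paste("l1", "p6") %in% paste(ev2$ligand_id, ev2$protein_id))
  expect_true("l9" %in% ev2$ligand_id)
})

test_that("both-annotation filtering iterates to a fixed point", {
  pairs <- data.frame(
    ligand_id = c("l1", "l1", "l2", "l2"),
    protein_id = c("p1", "p2", "p1", "p2"),
    label = c("positive", "negative", "negative", "positive"))
  expect_equal(nrow(enforceBothAnnotations(pairs)), 4L)  # already balanced

  # node with only positives: all its pairs removed
  pairs2 <- rbind(pairs, data.frame(ligand_id = "l3", protein_id = "p1",
                                    label = "positive"))
  expect_false("l3" %in% enforceBothAnnotations(pairs2)$ligand_id)

  # cascade: dropping l3 leaves p3 single-signed, which must then go too
  cascade <- data.frame(
    ligand_id = c("l1", "l1", "l2", "l2", "l3", "l3"),
    protein_id = c("p1", "p2", "p1", "p2", "p2", "p3"),
    label = c("positive", "negative", "negative", "positive",
              "positive", "negative"))
  # single-pass oracle, repeated until stable
  singlePass <- function(p) {
    isPos <- p$label == "positive"
    bad <- function(ids) {
      kp <- tapply(isPos, ids, sum); kn <- tapply(!isPos, ids, sum)
      names(kp)[kp == 0 | kn == 0]
    }
    keep <- !(p$ligand_id %in% bad(p$ligand_id) |
              p$protein_id %in% bad(p$protein_id))
    p[keep, , drop = FALSE]
  }
  oracle <- cascade
  repeat {
    nxt <- singlePass(oracle)
    if (nrow(nxt) == nrow(oracle)) break
    oracle <- nxt
  }
  got <- enforceBothAnnotations(cascade)
  expect_equal(got[order(got$ligand_id, got$protein_id), ],
               oracle[order(oracle$ligand_id, oracle$protein_id), ],
               ignore_attr = TRUE)

  # fixed-point property: every surviving node carries both signs
  for (seed in 1:5) {
    p <- networkToPairs(randomDuplex(15, 15, 40, seed = seed,
                                     avoidSaturation = FALSE))
    surv <- enforceBothAnnotations(p)
    if (!nrow(surv)) next
    isPos <- surv$label == "positive"
    for (ids in list(surv$ligand_id, surv$protein_id)) {
      kp <- tapply(isPos, ids, sum); kn <- tapply(!isPos, ids, sum)
      expect_true(all(kp >= 1 & kn >= 1))
    }
  }
})

test_that("class balance report counts labels", {
  pairs <- data.frame(ligand_id = c("a", "b", "c"), protein_id = "p",
                      label = c("positive", "negative", "positive"))
  rep <- classBalanceReport(pairs)
  expect_equal(rep$n_pos, 2L)
  expect_equal(rep$n_neg, 1L)
  expect_equal(rep$imbalance, 2)
  expect_equal(classBalanceReport(pairs[pairs$label == "positive", ])$
                 imbalance, Inf)
})
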