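# fixtures and independent oracles shared across the test files

# random signed bipartite network; by default avoids structurally saturated
# nodes (layer/total degree filling the opposite side) so the configuration
# model has an interior solution
randomDuplex <- function(nLig, nProt, nEdges, seed,
                         avoidSaturation = TRUE) {
  withr::with_seed(seed, {
    repeat {
      i <- sample.int(nLig, nEdges, replace = TRUE)
      j <- sample.int(nProt, nEdges, replace = TRUE)
      keep <- !duplicated(paste(i, j))
      i <- i[keep]; j <- j[keep]
      sgn <- stats::runif(length(i)) < 0.5
      if (!avoidSaturation) break
      kp <- tabulate(i[sgn], nLig); kn <- tabulate(i[!sgn], nLig)
      tp <- tabulate(j[sgn], nProt); tn <- tabulate(j[!sgn], nProt)
      if (max(kp + kn) < nProt && max(tp + tn) < nLig &&
          any(sgn) && any(!sgn)) break
    }
    DuplexNetwork(
      positiveEdges = data.frame(ligand = paste0("L", i[sgn]),
                                 protein = paste0("P", j[sgn])),
      negativeEdges = data.frame(ligand = paste0("L", i[!sgn]),
                                 protein = paste0("P", j[!sgn])),
      ligandIds = paste0("L", seq_len(nLig)),
      proteinIds = paste0("P", seq_len(nProt)))
  })
}

# random instance with an interior configuration-model solution: boundary
# cases (degree sequences forcing some multilink probability to 1, where
# multipliers diverge in both the fixed point and the convex dual) are
# resampled deterministically, since the solver/oracle comparison is only
# well-posed on interior instances
solvableRandomDuplex <- function(nLig, nProt, nEdges, seed, tol = 1e-12) {
  for (offset in 0:20) {
    net <- randomDuplex(nLig, nProt, nEdges, seed + 1000L * offset)
    fit <- tryCatch(
      withCallingHandlers(
        fitConfigurationModel(net, tol = tol, maxIter = 1500L),
        warning = function(w) stop("saturated")),
      error = function(e) NULL)
    if (!is.null(fit)) return(list(net = net, fit = fit))
  }
  stop("no interior instance found")
}

# symmetric 3x3 fixture: the positive edges form one perfect matching, the
# negative edges a disjoint one; by symmetry every multilink probability
# must be exactly 1/3
symmetricMatchingNet <- function() {
  DuplexNetwork(
    positiveEdges = data.frame(ligand = c("L1", "L2", "L3"),
                               protein = c("P1", "P2", "P3")),
    negativeEdges = data.frame(ligand = c("L1", "L2", "L3"),
                               protein = c("P2", "P3", "P1")))
}

# independent convex-optimization oracle for the configuration model:
# minimizes the dual free energy over the Lagrange multipliers of all
# nonzero-degree node/layer families with L-BFGS-B, then returns the
# multilink probability matrices
dualOracleProbabilities <- function(net) {
  deg <- multidegrees(net)
  lig <- deg[deg$side == "ligand", ]; prt <- deg[deg$side == "protein", ]
  kPos <- lig$k_pos; kNeg <- lig$k_neg
  tPos <- prt$k_pos; tNeg <- prt$k_neg
  nL <- length(kPos); nT <- length(tPos)
  free <- list(xp = which(kPos > 0), xn = which(kNeg > 0),
               yp = which(tPos > 0), yn = which(tNeg > 0))
  lens <- lengths(free)
  offs <- cumsum(c(0, lens))
  unpack <- function(theta) {
    part <- function(k) theta[offs[k] + seq_len(lens[k])]
    mk <- function(idx, n, p) {
      v <- numeric(n); if (length(idx)) v[idx] <- exp(p); v
    }
    list(xPos = mk(free$xp, nL, part(1)), xNeg = mk(free$xn, nL, part(2)),
         yPos = mk(free$yp, nT, part(3)), yNeg = mk(free$yn, nT, part(4)))
  }
  # dual objective: log Z + sum(lambda * k); here theta = log x = -lambda
  obj <- function(theta) {
    w <- unpack(theta)
    D <- 1 + outer(w$xPos, w$yPos) + outer(w$xNeg, w$yNeg)
    sum(log(D)) -
      sum(log(w$xPos[free$xp]) * kPos[free$xp]) -
      sum(log(w$xNeg[free$xn]) * kNeg[free$xn]) -
      sum(log(w$yPos[free$yp]) * tPos[free$yp]) -
      sum(log(w$yNeg[free$yn]) * tNeg[free$yn])
  }
  grad <- function(theta) {
    w <- unpack(theta)
    D <- 1 + outer(w$xPos, w$yPos) + outer(w$xNeg, w$yNeg)
    P10 <- outer(w$xPos, w$yPos) / D
    P01 <- outer(w$xNeg, w$yNeg) / D
    c(rowSums(P10)[free$xp] - kPos[free$xp],
      rowSums(P01)[free$xn] - kNeg[free$xn],
      colSums(P10)[free$yp] - tPos[free$yp],
      colSums(P01)[free$yn] - tNeg[free$yn])
  }
  fit <- stats::optim(numeric(sum(lens)), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 2000, factr = 10))
  w <- unpack(fit$par)
  D <- 1 + outer(w$xPos, w$yPos) + outer(w$xNeg, w$yNeg)
  list(p10 = outer(w$xPos, w$yPos) / D, p01 = outer(w$xNeg, w$yNeg) / D,
       p00 = 1 / D, convergence = fit$convergence)
}

# multilink probability matrices of a fitted model (all pairs)
fitProbabilityMatrices <- function(fit) {
  net <- fit@network
  idx <- expand.grid(i = seq_len(nLigands(net)), j = seq_len(nProteins(net)))
  p <- multilinkProbabilities(fit, idx$i, idx$j)
  list(p10 = matrix(p$p10, nLigands(net)),
       p01 = matrix(p$p01, nLigands(net)),
       p00 = matrix(p$p00, nLigands(net)))
}

# Floyd-Warshall all-pairs shortest paths on the positive-only bipartite
# graph, as an O(n^3) oracle independent of igraph's BFS
floydWarshallDistances <- function(net) {
  lig <- ligandIds(net); prt <- proteinIds(net)
  ids <- c(paste0("L:", lig), paste0("P:", prt))
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  e <- positiveEdges(net)
  if (nrow(e)) {
    a <- match(paste0("L:", e$ligand), ids)
    b <- match(paste0("P:", e$protein), ids)
    d[cbind(a, b)] <- 1; d[cbind(b, a)] <- 1
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  out <- d[paste0("L:", lig), paste0("P:", prt), drop = FALSE]
  dimnames(out) <- list(lig, prt)
  out
}

# labeled-pair frame from a duplex network
networkToPairs <- function(net) {
  pos <- positiveEdges(net); neg <- negativeEdges(net)
  data.frame(
    ligand_id = c(pos$ligand, neg$ligand),
    protein_id = c(pos$protein, neg$protein),
    label = rep(c("positive", "negative"), c(nrow(pos), nrow(neg))),
    stringsAsFactors = FALSE)
}

# brute-force pairwise AUROC oracle: average over all positive-negative
# comparisons with ties counted 1/2
bruteForceAuroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive threshold-sweep PR oracle for average precision
bruteForceAuprc <- function(labels, scores) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  lastR <- 0; ap <- 0
  for (t in thr) {
    tp <- sum(labels == 1 & scores >= t)
    fp <- sum(labels == 0 & scores >= t)
    r <- tp / P
    ap <- ap + (r - lastR) * tp / (tp + fp)
    lastR <- r
  }
  ap
}
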