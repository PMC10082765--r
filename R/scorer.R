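# Feed-forward binding scorer over fixed molecular embeddings.
#
# Architecture: one dense branch per molecule type (ligandDim -> h,
# proteinDim -> h, linear), a bilinear interaction block formed by all
# pairwise products of the first `rank` channels of the two branches
# (binding is an interaction, so the head gets explicit cross terms
# between the molecule representations), concatenation of branch outputs
# and interaction block, two ReLU hidden layers (-> h -> h/2) and a
# logistic output. The first `rank` channels of each branch are
# initialized to the whitened principal directions of the training-side
# embedding matrix — an unsupervised pre-training step on the structure
# tables, before any binding label is seen — and remain trainable.
# Training is full-batch Adam on binary cross-entropy with early stopping
# on a validation split.

.relu <- function(z) pmax(z, 0)
# logits clamped at +-30 keep the output strictly inside (0, 1) in double
# precision even for saturated models
.sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

# whitened-PCA initialization of a branch: first `rank` columns project
# onto the leading principal directions (unit variance), remaining
# columns start near zero
.pcaBranchInit <- function(X, hidden, rank) {
    p <- stats::prcomp(X, center = TRUE)
    keep <- seq_len(min(rank, ncol(p$rotation), hidden))
    W <- p$rotation[, keep, drop = FALSE] %*%
        diag(1 / pmax(p$sdev[keep], 1e-8), length(keep))
    extra <- hidden - ncol(W)
    if (extra > 0)
        W <- cbind(W, matrix(stats::rnorm(nrow(W) * extra, 0, 0.05),
                             nrow(W)))
    list(W = W, b = c(as.vector(-p$center %*% W[, keep, drop = FALSE]),
                      numeric(extra)))
}

.initWeights <- function(XL, XP, hidden, rank, seed) {
    h2 <- max(hidden %/% 2L, 1L)
    he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                  sqrt(2 / nin)), nin, nout)
    withr::with_seed(seed, {
        iL <- .pcaBranchInit(XL, hidden, rank)
        iP <- .pcaBranchInit(XP, hidden, rank)
        list(W1L = iL$W, b1L = iL$b, W1P = iP$W, b1P = iP$b,
             W2 = he(2L * hidden + rank * rank, hidden),
             b2 = numeric(hidden),
             W3 = he(hidden, h2), b3 = numeric(h2),
             W4 = he(h2, 1L), b4 = numeric(1L))
    })
}

.crossIdx <- function(rank) as.matrix(expand.grid(a = seq_len(rank),
                                                  b = seq_len(rank)))

.forward <- function(w, XL, XP, rank) {
    ci <- .crossIdx(rank)
    H1L <- sweep(XL %*% w$W1L, 2, w$b1L, `+`)
    H1P <- sweep(XP %*% w$W1P, 2, w$b1P, `+`)
    CR <- H1L[, ci[, 1], drop = FALSE] * H1P[, ci[, 2], drop = FALSE]
    H1 <- cbind(H1L, H1P, CR)
    H2 <- .relu(sweep(H1 %*% w$W2, 2, w$b2, `+`))
    H3 <- .relu(sweep(H2 %*% w$W3, 2, w$b3, `+`))
    out <- .sigmoid(as.vector(H3 %*% w$W4) + w$b4)
    list(H1L = H1L, H1P = H1P, H1 = H1, H2 = H2, H3 = H3, out = out)
}

.bce <- function(p, y) {
    eps <- 1e-12
    -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

.gradients <- function(w, XL, XP, fw, y, rank) {
    ci <- .crossIdx(rank)
    n <- length(y)
    h <- ncol(fw$H1L)
    dOut <- matrix((fw$out - y) / n)              # dL/dlogit, n x 1
    g <- list()
    g$W4 <- crossprod(fw$H3, dOut); g$b4 <- sum(dOut)
    dH3 <- (dOut %*% t(w$W4)) * (fw$H3 > 0)
    g$W3 <- crossprod(fw$H2, dH3); g$b3 <- colSums(dH3)
    dH2 <- (dH3 %*% t(w$W3)) * (fw$H2 > 0)
    g$W2 <- crossprod(fw$H1, dH2); g$b2 <- colSums(dH2)
    dH1 <- dH2 %*% t(w$W2)
    dH1L <- dH1[, seq_len(h), drop = FALSE]
    dH1P <- dH1[, h + seq_len(h), drop = FALSE]
    dCR <- dH1[, 2L * h + seq_len(rank * rank), drop = FALSE]
    for (a in seq_len(rank)) {
        sel <- which(ci[, 1] == a)
        dH1L[, a] <- dH1L[, a] +
            rowSums(dCR[, sel, drop = FALSE] *
                    fw$H1P[, ci[sel, 2], drop = FALSE])
    }
    for (b in seq_len(rank)) {
        sel <- which(ci[, 2] == b)
        dH1P[, b] <- dH1P[, b] +
            rowSums(dCR[, sel, drop = FALSE] *
                    fw$H1L[, ci[sel, 1], drop = FALSE])
    }
    g$W1L <- crossprod(XL, dH1L); g$b1L <- colSums(dH1L)
    g$W1P <- crossprod(XP, dH1P); g$b1P <- colSums(dH1P)
    g
}

.pairEmbeddings <- function(pairs, ligandStructures, proteinSequences,
                            ligProvider, protProvider) {
    missL <- setdiff(unique(pairs$ligand_id), names(ligandStructures))
    missP <- setdiff(unique(pairs$protein_id), names(proteinSequences))
    if (length(missL) || length(missP))
        stop("missing structure(s) for: ",
             paste(c(missL, missP), collapse = ", "))
    uL <- unique(pairs$ligand_id); uP <- unique(pairs$protein_id)
    EL <- embedStructures(ligProvider, ligandStructures[uL])
    EP <- embedStructures(protProvider, proteinSequences[uP])
    list(XL = EL[match(pairs$ligand_id, uL), , drop = FALSE],
         XP = EP[match(pairs$protein_id, uP), , drop = FALSE])
}

#' Train the feed-forward binding scorer
#'
#' Minimizes binary cross-entropy with full-batch Adam. The branch layers
#' start from a whitened principal-component projection of the training
#' structures' embeddings (unsupervised, label-free); a bilinear
#' interaction block between the branches lets the head represent
#' interaction-driven binding directly. Training stops when the validation
#' loss has not improved for `patience` epochs (the best validation
#' weights are kept) or at `maxEpochs`. Given the same seed and data, the
#' loss trace and final weights are identical run to run.
#'
#' @param trainPairs labeled-pair data.frame (`ligand_id`, `protein_id`,
#'   `label` with both classes present).
#' @param ligandStructures named character, ligand id -> SMILES.
#' @param proteinSequences named character, protein id -> sequence.
#' @param ligProvider,protProvider [EmbeddingProvider-class] objects
#'   (defaults: hashed fallbacks at 300/100 dimensions).
#' @param hidden branch width (default 64).
#' @param rank interaction-block rank: channels per branch entering the
#'   bilinear block (default 16).
#' @param maxEpochs epoch budget (default 400).
#' @param lr Adam learning rate (default 2e-3).
#' @param patience early-stopping patience in epochs (default 25).
#' @param valFraction fraction of training pairs held out for validation
#'   (default 0.15); ignored when `valPairs` is given.
#' @param valPairs optional explicit validation pairs.
#' @param seed integer seed for the split and initialization.
#' @return a [BindingScorer-class].
#' @export
trainScorer <- function(trainPairs, ligandStructures, proteinSequences,
                        ligProvider = hashedLigandProvider(),
                        protProvider = hashedProteinProvider(),
                        hidden = 64L, rank = 16L, maxEpochs = 400L,
                        lr = 2e-3, patience = 25L, valFraction = 0.15,
                        valPairs = NULL, seed = 1L) {
    .assertPairFrame(trainPairs)
    rank <- min(as.integer(rank), as.integer(hidden))
    y <- .binaryLabel(trainPairs$label)
    if (length(unique(y)) < 2) stop("training set must contain both classes")
    if (is.null(valPairs)) {
        idx <- withr::with_seed(seed, sample.int(nrow(trainPairs)))
        nVal <- max(1L, round(valFraction * nrow(trainPairs)))
        valPairs <- trainPairs[idx[seq_len(nVal)], , drop = FALSE]
        trainPairs <- trainPairs[idx[-seq_len(nVal)], , drop = FALSE]
        y <- .binaryLabel(trainPairs$label)
        if (length(unique(y)) < 2)
            stop("training set must contain both classes after validation ",
                 "split")
    }
    yVal <- .binaryLabel(valPairs$label)
    tr <- .pairEmbeddings(trainPairs, ligandStructures, proteinSequences,
                          ligProvider, protProvider)
    va <- .pairEmbeddings(valPairs, ligandStructures, proteinSequences,
                          ligProvider, protProvider)
    w <- .initWeights(tr$XL, tr$XP, hidden, rank, seed)

    m <- lapply(w, function(x) x * 0); v <- m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lossTrace <- valTrace <- numeric(0)
    bestVal <- Inf; bestW <- w; wait <- 0L
    for (epoch in seq_len(maxEpochs)) {
        fw <- .forward(w, tr$XL, tr$XP, rank)
        g <- .gradients(w, tr$XL, tr$XP, fw, y, rank)
        for (nm in names(w)) {
            m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
            v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
            mh <- m[[nm]] / (1 - b1^epoch)
            vh <- v[[nm]] / (1 - b2^epoch)
            w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
        lossTrace <- c(lossTrace, .bce(fw$out, y))
        valLoss <- .bce(.forward(w, va$XL, va$XP, rank)$out, yVal)
        valTrace <- c(valTrace, valLoss)
        if (valLoss < bestVal - 1e-6) {
            bestVal <- valLoss; bestW <- w; wait <- 0L
        } else {
            wait <- wait + 1L
            if (wait >= patience) break
        }
    }
    new("BindingScorer", weights = bestW, ligandDim = ncol(tr$XL),
        proteinDim = ncol(tr$XP), hidden = as.integer(hidden),
        rank = rank, seed = as.integer(seed), lossTrace = lossTrace,
        valTrace = valTrace)
}

setMethod("show", "BindingScorer", function(object) {
    cat(sprintf(paste0("BindingScorer: %d+%d -> %d (interaction rank %d), ",
                       "%d epochs trained (best val loss %.4f)\n"),
                object@ligandDim, object@proteinDim, object@hidden,
                object@rank, length(object@lossTrace),
                min(object@valTrace)))
})

setMethod("show", "ScorerEnsemble", function(object) {
    cat(sprintf("ScorerEnsemble of %d fold scorers\n", length(object@members)))
})

#' Score ligand-protein pairs with a trained model
#'
#' Deterministic forward evaluation. A [ScorerEnsemble-class] returns the
#' arithmetic mean of its members' scores; per-member variability is
#' available via `memberScores`.
#'
#' @param model a [BindingScorer-class], a [ScorerEnsemble-class], or (for custom
#'   scorers, e.g. in perturbation studies) a
#'   function(ligandEmbeddingMatrix, proteinEmbeddingMatrix) -> scores.
#' @param smiles,sequences character vectors (recycled to equal length):
#'   ligand and protein structures of the pairs to score.
#' @param ligProvider,protProvider embedding providers.
#' @param memberScores if TRUE (ensembles only) return the member x pair
#'   score matrix instead of the mean.
#' @return numeric scores in (0, 1), or a matrix when `memberScores`.
#' @export
predictScore <- function(model, smiles, sequences,
                         ligProvider = hashedLigandProvider(),
                         protProvider = hashedProteinProvider(),
                         memberScores = FALSE) {
    n <- max(length(smiles), length(sequences))
    XL <- embedStructures(ligProvider, rep_len(smiles, n))
    XP <- embedStructures(protProvider, rep_len(sequences, n))
    .scoreEmbedded(model, XL, XP, memberScores)
}

.scoreEmbedded <- function(model, XL, XP, memberScores = FALSE) {
    if (is.function(model)) return(model(XL, XP))
    if (is(model, "BindingScorer"))
        return(.forward(model@weights, XL, XP, model@rank)$out)
    if (is(model, "ScorerEnsemble")) {
        S <- vapply(model@members,
                    function(mm) .forward(mm@weights, XL, XP, mm@rank)$out,
                    numeric(nrow(XL)))
        S <- matrix(S, nrow = nrow(XL))
        if (memberScores) return(t(S))
        return(rowMeans(S))
    }
    stop("unsupported model type")
}

#' Train a fold-ensemble of binding scorers
#'
#' Splits the training pairs into `nFolds` folds; member k is trained on
#' the other folds with fold k as its validation set. Ensemble predictions
#' average the members.
#'
#' @inheritParams trainScorer
#' @param nFolds number of folds / members (default 5).
#' @param ... passed on to [trainScorer()].
#' @return a [ScorerEnsemble-class].
#' @export
trainEnsemble <- function(trainPairs, ligandStructures, proteinSequences,
                          ligProvider = hashedLigandProvider(),
                          protProvider = hashedProteinProvider(),
                          nFolds = 5L, seed = 1L, ...) {
    .assertPairFrame(trainPairs)
    foldOf <- withr::with_seed(seed,
        sample(rep_len(seq_len(nFolds), nrow(trainPairs))))
    members <- lapply(seq_len(nFolds), function(f)
        trainScorer(trainPairs[foldOf != f, , drop = FALSE],
                    ligandStructures, proteinSequences,
                    ligProvider, protProvider,
                    valPairs = trainPairs[foldOf == f, , drop = FALSE],
                    seed = seed + f, ...))
    new("ScorerEnsemble", members = members)
}

#' Score labeled pairs by id
#'
#' Convenience wrapper resolving pair ids through the structure tables
#' before calling [predictScore()].
#'
#' @param model trained scorer or ensemble.
#' @param pairs data.frame `ligand_id`, `protein_id`.
#' @inheritParams trainScorer
#' @return numeric scores.
#' @export
predictPairsScore <- function(model, pairs, ligandStructures,
                              proteinSequences,
                              ligProvider = hashedLigandProvider(),
                              protProvider = hashedProteinProvider()) {
    .assertPairFrame(pairs)
    emb <- .pairEmbeddings(pairs, ligandStructures, proteinSequences,
                           ligProvider, protProvider)
    .scoreEmbedded(model, emb$XL, emb$XP)
}

#' Default trainer closure for [featureShuffleControl()]
#'
#' Returns a trainer function conforming to the shuffle-control contract,
#' wrapping [trainEnsemble()] with the given providers and hyperparameters.
#'
#' @inheritParams trainEnsemble
#' @return function(trainPairs, ligandStructures, proteinSequences, seed)
#'   -> function(pairs) -> scores.
#' @export
ensembleTrainer <- function(ligProvider = hashedLigandProvider(),
                          protProvider = hashedProteinProvider(),
                          nFolds = 5L, ...) {
    force(ligProvider); force(protProvider); force(nFolds)
    dots <- list(...)
    function(trainPairs, ligandStructures, proteinSequences, seed) {
        model <- do.call(trainEnsemble,
                         c(list(trainPairs, ligandStructures,
                                proteinSequences, ligProvider, protProvider,
                                nFolds = nFolds, seed = seed), dots))
        function(pairs) predictPairsScore(model, pairs, ligandStructures,
                                          proteinSequences, ligProvider,
                                          protProvider)
    }
}
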