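#' Fit the maximum-entropy duplex configuration model
#'
#' Solves the canonical (soft-constraint) configuration model for a signed
#' bipartite network: the maximum-entropy ensemble over duplex networks in
#' which every node's expected positive and negative multidegrees equal the
#' observed ones, with the joint binding/non-binding state forbidden. Pair
#' probabilities factorize as
#' `p+_ij = xPos_i*yPos_j / D_ij`, `p-_ij = xNeg_i*yNeg_j / D_ij`,
#' `D_ij = 1 + xPos_i*yPos_j + xNeg_i*yNeg_j`,
#' where the `x`/`y` are exponentiated negated Lagrange multipliers. The
#' dual problem is convex, so the solution is unique and independent of
#' initialization.
#'
#' The solver is a damped fixed-point iteration that alternates sides,
#' updating `x <- k / sum_j(y_j / D_ij)` per layer (and symmetrically for
#' `y`), with multiplicative damping. Multipliers of zero-degree node/layer
#' pairs are exactly zero. Multipliers are capped at `exp(30)`; nodes that
#' hit the cap (degree saturating the opposite side) are reported in
#' `saturatedNodes` with a warning and excluded from the residual.
#'
#' @param net a [DuplexNetwork-class] with at least one ligand and protein.
#' @param tol absolute tolerance on the worst expected-vs-observed
#'   multidegree gap (default 1e-10).
#' @param maxIter maximum fixed-point sweeps (default 5000).
#' @param damping multiplicative damping in (0, 1]; 1 is undamped.
#' @return a [MaxEntFit-class].
#' @examples
#' fit <- fitConfigurationModel(toyAnnotationNetwork())
#' fit
#' @export
fitConfigurationModel <- function(net, tol = 1e-10, maxIter = 5000L,
                                  damping = 0.5) {
    stopifnot(is(net, "DuplexNetwork"), tol > 0, maxIter >= 1,
              damping > 0, damping <= 1)
    if (nLigands(net) < 1 || nProteins(net) < 1)
        stop("network must have at least one ligand and one protein")
    deg <- multidegrees(net)
    lig <- deg[deg$side == "ligand", ]
    prt <- deg[deg$side == "protein", ]
    kPos <- lig$k_pos; kNeg <- lig$k_neg
    tPos <- prt$k_pos; tNeg <- prt$k_neg
    nL <- nLigands(net); nT <- nProteins(net)
    L10 <- numPositive(net); L01 <- numNegative(net)
    cap <- exp(30)

    # structurally saturated nodes: a layer degree (or the total degree)
    # equal to the opposite side size forces boundary probabilities and
    # divergent multipliers; cap them up front and keep them out of the
    # residual
    satLig <- kPos >= nT | kNeg >= nT | (kPos + kNeg) >= nT
    satPrt <- tPos >= nL | tNeg >= nL | (tPos + tNeg) >= nL
    satLig <- satLig & (kPos + kNeg) > 0
    satPrt <- satPrt & (tPos + tNeg) > 0

    xPos <- kPos / sqrt(L10 + 1); xNeg <- kNeg / sqrt(L01 + 1)
    yPos <- tPos / sqrt(L10 + 1); yNeg <- tNeg / sqrt(L01 + 1)
    xPos[satLig & kPos > 0] <- cap; xNeg[satLig & kNeg > 0] <- cap
    yPos[satPrt & tPos > 0] <- cap; yNeg[satPrt & tNeg > 0] <- cap

    damp <- function(old, new) {
        out <- ifelse(old > 0 & new > 0, old^(1 - damping) * new^damping, new)
        pmin(out, cap)
    }
    safeDiv <- function(k, s) ifelse(k > 0, k / pmax(s, 1e-300), 0)

    freeze <- function() {
        xPos[satLig & kPos > 0] <<- cap; xNeg[satLig & kNeg > 0] <<- cap
        yPos[satPrt & tPos > 0] <<- cap; yNeg[satPrt & tNeg > 0] <<- cap
    }
    it <- 0L; res <- Inf
    repeat {
        it <- it + 1L
        Dinv <- 1 / (1 + outer(xPos, yPos) + outer(xNeg, yNeg))
        xPos <- damp(xPos, safeDiv(kPos, as.vector(Dinv %*% yPos)))
        xNeg <- damp(xNeg, safeDiv(kNeg, as.vector(Dinv %*% yNeg)))
        freeze()
        Dinv <- 1 / (1 + outer(xPos, yPos) + outer(xNeg, yNeg))
        yPos <- damp(yPos, safeDiv(tPos, colSums(Dinv * xPos)))
        yNeg <- damp(yNeg, safeDiv(tNeg, colSums(Dinv * xNeg)))
        freeze()

        Dinv <- 1 / (1 + outer(xPos, yPos) + outer(xNeg, yNeg))
        P10 <- outer(xPos, yPos) * Dinv
        P01 <- outer(xNeg, yNeg) * Dinv
        satLig <- satLig | xPos >= cap | xNeg >= cap
        satPrt <- satPrt | yPos >= cap | yNeg >= cap
        gaps <- c(abs(rowSums(P10) - kPos)[!satLig],
                  abs(rowSums(P01) - kNeg)[!satLig],
                  abs(colSums(P10) - tPos)[!satPrt],
                  abs(colSums(P01) - tNeg)[!satPrt])
        res <- if (length(gaps)) max(gaps) else 0
        if (res <= tol || it >= maxIter) break
    }
    saturated <- c(lig$node_id[satLig], prt$node_id[satPrt])
    if (length(saturated))
        warning("saturated multipliers capped for node(s): ",
                paste(saturated, collapse = ", "))
    if (res > tol)
        stop(sprintf(paste0("configuration model did not converge in %d ",
                            "iterations (residual %.3e > tol %.3e)"),
                     it, res, tol))
    logZ <- sum(-log(pmax(Dinv, 1e-300)))
    new("MaxEntFit", network = net,
        xPos = stats::setNames(xPos, lig$node_id),
        xNeg = stats::setNames(xNeg, lig$node_id),
        yPos = stats::setNames(yPos, prt$node_id),
        yNeg = stats::setNames(yNeg, prt$node_id),
        iterations = it, maxResidual = res, converged = TRUE,
        saturatedNodes = as.character(saturated), logPartition = logZ)
}

setMethod("show", "MaxEntFit", function(object) {
    cat("MaxEntFit on", nLigands(object@network), "x",
        nProteins(object@network), "duplex network\n")
    cat(sprintf("  converged in %d iterations, max residual %.2e\n",
                object@iterations, object@maxResidual))
    if (length(object@saturatedNodes))
        cat("  saturated nodes:",
            paste(object@saturatedNodes, collapse = ", "), "\n")
})

.resolveIndex <- function(ids, pool, what) {
    if (is.character(ids)) ids <- match(ids, pool)
    ids <- as.integer(ids)
    if (anyNA(ids) || any(ids < 1L) || any(ids > length(pool)))
        stop(what, " index out of range")
    ids
}

#' Multilink probabilities of a fitted configuration model
#'
#' Evaluates, for ligand-protein pairs, the ensemble probabilities of a
#' positive annotation, a negative annotation, and no annotation. The three
#' always sum to 1.
#'
#' @param fit a [MaxEntFit-class].
#' @param i ligand indices or ids; recycled against `j`.
#' @param j protein indices or ids.
#' @return data.frame with columns `p10` (positive), `p01` (negative),
#'   `p00` (unannotated).
#' @export
multilinkProbabilities <- function(fit, i, j) {
    stopifnot(is(fit, "MaxEntFit"))
    i <- .resolveIndex(i, ligandIds(fit@network), "ligand")
    j <- .resolveIndex(j, proteinIds(fit@network), "protein")
    wPos <- fit@xPos[i] * fit@yPos[j]
    wNeg <- fit@xNeg[i] * fit@yNeg[j]
    D <- 1 + wPos + wNeg
    data.frame(p10 = wPos / D, p01 = wNeg / D, p00 = 1 / D,
               row.names = NULL)
}

#' Conditional binding predictors of the configuration model
#'
#' Three conditional predictors, by how much of the pair is known to the
#' fitted model:
#' \describe{
#'   \item{`predictTransductive`}{both nodes known: `p+ / (p+ + p-)` for the
#'     pair.}
#'   \item{`predictSemiInductive`}{one node known, its partner unseen: the
#'     known node's degree ratio rho, which at the solution equals the
#'     conditional averaged over the unseen side.}
#'   \item{`predictInductive`}{both nodes unseen: the global positive
#'     fraction `L+ / (L+ + L-)`, identical for every pair.}
#' }
#'
#' @param fit a [MaxEntFit-class] (for `predictInductive`, a fit or a
#'   [DuplexNetwork-class]).
#' @param i,j ligand/protein indices or ids (recycled).
#' @return numeric score(s) in \[0, 1\].
#' @export
predictTransductive <- function(fit, i, j) {
    p <- multilinkProbabilities(fit, i, j)
    tot <- p$p10 + p$p01
    if (any(tot == 0))
        stop("conditional undefined (p10 + p01 = 0): both nodes lack ",
             "annotations in one layer")
    p$p10 / tot
}

#' @param nodeId identifier of the known node.
#' @param side `"ligand"` or `"protein"`; the protein route (known protein,
#'   unseen ligand) is the symmetric extension of the unseen-target
#'   formula and is flagged as such in [predictPair()] output.
#' @rdname predictTransductive
#' @export
predictSemiInductive <- function(fit, nodeId, side = c("ligand", "protein")) {
    stopifnot(is(fit, "MaxEntFit"))
    side <- match.arg(side)
    deg <- multidegrees(fit@network)
    deg <- deg[deg$side == side, ]
    hit <- match(nodeId, deg$node_id)
    if (anyNA(hit)) stop("unknown ", side, " id: ",
                         paste(nodeId[is.na(hit)], collapse = ", "))
    degreeRatio(deg$k_pos[hit], deg$k_neg[hit])
}

#' @rdname predictTransductive
#' @export
predictInductive <- function(fit) {
    net <- if (is(fit, "MaxEntFit")) fit@network else fit
    stopifnot(is(net, "DuplexNetwork"))
    tot <- numPositive(net) + numNegative(net)
    if (tot == 0) stop("network has no annotations")
    numPositive(net) / tot
}

#' Route a pair to the appropriate conditional predictor
#'
#' Chooses the transductive, semi-inductive or inductive predictor for each
#' pair according to whether its endpoints belong to the training node
#' sets, and evaluates it. Vectorized over pairs.
#'
#' @param fit a [MaxEntFit-class] fitted on the training network.
#' @param pairs data.frame with columns `ligand_id`, `protein_id`.
#' @param trainLigands,trainProteins character sets of training node ids;
#'   default: all nodes of the fitted network.
#' @return data.frame `ligand_id`, `protein_id`, `score`, `scenario`
#'   (one of `"transductive"`, `"semi_inductive"`, `"inductive"`).
#' @export
predictPair <- function(fit, pairs,
                        trainLigands = ligandIds(fit@network),
                        trainProteins = proteinIds(fit@network)) {
    stopifnot(is(fit, "MaxEntFit"))
    .assertPairFrame(pairs)
    ligKnown <- pairs$ligand_id %in% trainLigands
    prtKnown <- pairs$protein_id %in% trainProteins
    scenario <- ifelse(ligKnown & prtKnown, "transductive",
                ifelse(ligKnown | prtKnown, "semi_inductive", "inductive"))
    score <- numeric(nrow(pairs))
    tr <- which(ligKnown & prtKnown)
    if (length(tr))
        score[tr] <- predictTransductive(fit, pairs$ligand_id[tr],
                                         pairs$protein_id[tr])
    siL <- which(ligKnown & !prtKnown)
    if (length(siL))
        score[siL] <- predictSemiInductive(fit, pairs$ligand_id[siL], "ligand")
    siP <- which(!ligKnown & prtKnown)
    if (length(siP))
        score[siP] <- predictSemiInductive(fit, pairs$protein_id[siP],
                                           "protein")
    ind <- which(!ligKnown & !prtKnown)
    if (length(ind)) score[ind] <- predictInductive(fit)
    data.frame(ligand_id = pairs$ligand_id, protein_id = pairs$protein_id,
               score = score, scenario = scenario, stringsAsFactors = FALSE)
}

#' Serialize / restore a fitted configuration model
#'
#' Writes the per-node exponentiated multipliers as a TSV
#' (`node_id`, `side`, `x_pos`, `x_neg`) next to a JSON convergence header.
#'
#' @param fit a [MaxEntFit-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeMaxEntFit <- function(fit, dir) {
    stopifnot(is(fit, "MaxEntFit"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tab <- rbind(
        data.frame(node_id = names(fit@xPos), side = "ligand",
                   x_pos = unname(fit@xPos), x_neg = unname(fit@xNeg)),
        data.frame(node_id = names(fit@yPos), side = "protein",
                   x_pos = unname(fit@yPos), x_neg = unname(fit@yNeg)))
    utils::write.table(tab, file.path(dir, "multipliers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hdr <- list(iterations = fit@iterations, max_residual = fit@maxResidual,
                converged = fit@converged, log_partition = fit@logPartition,
                saturated_nodes = fit@saturatedNodes)
    jsonlite::write_json(hdr, file.path(dir, "convergence.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
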