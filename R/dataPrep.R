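#' Read kinetic interaction records
#'
#' TSV with columns `ligand_id`, `protein_id`, `constant_type` (one of
#' Ki, Kd, IC50, EC50), `value_nM` (positive, nanomolar), optional
#' `temperature_C` and `source`.
#'
#' @param path file path.
#' @return data.frame of interaction records.
#' @export
readKineticTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("ligand_id", "protein_id", "constant_type", "value_nM")
    if (!all(need %in% names(d)))
        stop("expected columns ", paste(need, collapse = ", "), " in ", path)
    if (!"temperature_C" %in% names(d)) d$temperature_C <- NA_real_
    if (!"source" %in% names(d)) d$source <- ""
    .checkRecords(d)
    d
}

.KINETIC_TYPES <- c("Ki", "Kd", "IC50", "EC50")

.checkRecords <- function(records) {
    if (!all(records$constant_type %in% .KINETIC_TYPES))
        stop("constant_type must be one of ",
             paste(.KINETIC_TYPES, collapse = ", "))
    if (any(!is.finite(records$value_nM) | records$value_nM <= 0))
        stop("kinetic values must be positive (nM)")
    invisible(records)
}

#' Filter kinetic records by assay temperature
#'
#' Removes records whose stated temperature falls outside the accepted
#' physiological assay range; records without a temperature are kept by
#' default (curated annotations typically carry none).
#'
#' @param records data.frame of interaction records (see [readKineticTsv()]).
#' @param low,high accepted range in degrees Celsius (default 20-45).
#' @param keepMissing keep records with missing temperature? (default TRUE)
#' @return the filtered records.
#' @export
filterTemperature <- function(records, low = 20, high = 45,
                              keepMissing = TRUE) {
    t <- records$temperature_C
    miss <- is.na(t)
    keep <- (!miss & t >= low & t <= high) | (miss & keepMissing)
    records[keep, , drop = FALSE]
}

#' Threshold kinetic measurements into signed annotations
#'
#' Aggregates measurements per (ligand, protein) pair by the median within
#' each kinetic constant type, then labels the pair positive (binding) if
#' any aggregated value is at most `posMaxnM` and none is at least
#' `negMinnM`; negative (non-binding) in the mirrored case. Pairs with
#' conflicting evidence, or with only intermediate values, are dropped with
#' a stated reason.
#'
#' @param records data.frame of interaction records.
#' @param posMaxnM binding threshold in nM (default 1e3, inclusive).
#' @param negMinnM non-binding threshold in nM (default 1e6, inclusive).
#' @return list with `pairs` (data.frame `ligand_id`, `protein_id`, `label`,
#'   `provenance` = "experimental") and `dropped` (adds `reason`).
#' @export
labelFromKinetics <- function(records, posMaxnM = 1e3, negMinnM = 1e6) {
    stopifnot(posMaxnM < negMinnM)
    .checkRecords(records)
    if (!nrow(records)) {
        empty <- data.frame(ligand_id = character(0),
                            protein_id = character(0),
                            label = character(0), provenance = character(0))
        return(list(pairs = empty,
                    dropped = cbind(empty[1:2], reason = character(0))))
    }
    agg <- stats::aggregate(
        value_nM ~ ligand_id + protein_id + constant_type,
        data = records, FUN = stats::median)
    key <- .pairKey(agg$ligand_id, agg$protein_id)
    hasPos <- tapply(agg$value_nM <= posMaxnM, key, any)
    hasNeg <- tapply(agg$value_nM >= negMinnM, key, any)
    ids <- do.call(rbind, strsplit(names(hasPos), "\r", fixed = TRUE))
    out <- data.frame(ligand_id = ids[, 1], protein_id = ids[, 2],
                      stringsAsFactors = FALSE)
    lab <- ifelse(hasPos & !hasNeg, "positive",
           ifelse(hasNeg & !hasPos, "negative", NA))
    reason <- ifelse(hasPos & hasNeg, "conflicting evidence",
              ifelse(!hasPos & !hasNeg, "intermediate affinity", ""))
    keep <- !is.na(lab)
    pairs <- out[keep, , drop = FALSE]
    pairs$label <- as.character(lab[keep])
    pairs$provenance <- rep("experimental", nrow(pairs))
    dropped <- out[!keep, , drop = FALSE]
    dropped$reason <- as.character(reason[!keep])
    rownames(pairs) <- rownames(dropped) <- NULL
    list(pairs = pairs, dropped = dropped)
}

#' Merge curated binding annotations with experimental labels
#'
#' Curated positives (e.g. approved drug-target links) are added with
#' provenance `curated_positive`, except that a pair carrying experimental
#' non-binding evidence is excluded entirely — negative kinetic evidence
#' overrides a curated binding claim. Duplicates collapse to a single entry
#' (experimental provenance wins).
#'
#' @param curated data.frame with columns `ligand_id`, `protein_id`.
#' @param experimental labeled pairs from [labelFromKinetics()].
#' @return combined labeled-pair data.frame.
#' @export
mergeCuratedPositives <- function(curated, experimental) {
    .assertPairFrame(curated)
    expKey <- .pairKey(experimental$ligand_id, experimental$protein_id)
    curKey <- unique(.pairKey(curated$ligand_id, curated$protein_id))
    negKey <- expKey[experimental$label == "negative"]
    # a curated positive contradicted by experimental non-binding evidence
    # removes the pair entirely, from both sources
    conflict <- intersect(curKey, negKey)
    experimental <- experimental[!(expKey %in% conflict), , drop = FALSE]
    curKey <- setdiff(curKey, c(negKey, expKey))
    ids <- if (length(curKey))
        do.call(rbind, strsplit(curKey, "\r", fixed = TRUE))
    else matrix(character(0), 0, 2)
    add <- data.frame(ligand_id = ids[, 1], protein_id = ids[, 2],
                      label = "positive", provenance = "curated_positive",
                      stringsAsFactors = FALSE)
    out <- rbind(experimental[, c("ligand_id", "protein_id", "label",
                                  "provenance")], add)
    rownames(out) <- NULL
    out
}

.positiveGraph <- function(net) {
    lig <- paste0("L\r", ligandIds(net))
    prt <- paste0("P\r", proteinIds(net))
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(lig) + length(prt),
                              name = c(lig, prt))
    e <- positiveEdges(net)
    if (nrow(e))
        g <- igraph::add_edges(g, rbind(paste0("L\r", e$ligand),
                                        paste0("P\r", e$protein)))
    g
}

#' Shortest-path distances on the positive-only network
#'
#' Breadth-first (unweighted) shortest-path hop counts between ligands and
#' proteins, computed on the bipartite graph of binding annotations only.
#' Ligand-protein distances are odd or infinite; distance 1 means a direct
#' binding annotation.
#'
#' @param net a [DuplexNetwork-class]; only its positive layer is used.
#' @param sources optional character vector of ligand ids (default: all).
#' @return numeric matrix (sources x proteins) of hop counts, `Inf` where
#'   unreachable.
#' @export
shortestPathDistances <- function(net, sources = NULL) {
    stopifnot(is(net, "DuplexNetwork"))
    if (is.null(sources)) sources <- ligandIds(net)
    g <- .positiveGraph(net)
    d <- igraph::distances(g, v = paste0("L\r", sources),
                           to = paste0("P\r", proteinIds(net)))
    dimnames(d) <- list(sources, proteinIds(net))
    d
}

#' Sample network-derived negative pairs
#'
#' Draws unannotated ligand-protein pairs whose shortest-path distance on
#' the positive-only network is exactly `distance` (default 7 hops, the
#' regime where expected affinities exceed the non-binding threshold), as
#' training negatives. Sampling is uniform without replacement and
#' reproducible under `seed`; every returned pair is re-verified to the
#' requested distance.
#'
#' @param net a [DuplexNetwork-class].
#' @param distance odd hop count (default 7).
#' @param nSamples number of pairs requested.
#' @param seed integer seed.
#' @param minOnly if TRUE, accept any finite distance `>= distance`.
#' @return data.frame `ligand_id`, `protein_id`, `label` = "negative",
#'   `provenance` = "network_derived", `distance`; if fewer eligible pairs
#'   than requested exist, all are returned and the result carries
#'   `attr(, "truncated") = TRUE` with a warning.
#' @export
sampleNetworkNegatives <- function(net, distance = 7L, nSamples, seed = 1L,
                                   minOnly = FALSE) {
    stopifnot(nSamples >= 1)
    if (distance %% 2 == 0) stop("ligand-protein distances are odd")
    d <- shortestPathDistances(net)
    sel <- if (minOnly) is.finite(d) & d >= distance else d == distance
    idx <- which(sel, arr.ind = TRUE)
    pool <- data.frame(ligand_id = rownames(d)[idx[, 1]],
                       protein_id = colnames(d)[idx[, 2]],
                       distance = d[idx], stringsAsFactors = FALSE)
    truncated <- nrow(pool) < nSamples
    take <- if (truncated) seq_len(nrow(pool)) else
        withr::with_seed(seed, sample.int(nrow(pool), nSamples))
    out <- pool[take, , drop = FALSE]
    stopifnot(all(is.finite(out$distance)),
              all(if (minOnly) out$distance >= distance
                  else out$distance == distance))
    out <- data.frame(ligand_id = out$ligand_id, protein_id = out$protein_id,
                      label = rep("negative", nrow(out)),
                      provenance = rep("network_derived", nrow(out)),
                      distance = out$distance, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (truncated) {
        warning(sprintf("only %d eligible pairs at distance %s (requested %d)",
                        nrow(out), if (minOnly) paste0(">=", distance)
                               else distance, nSamples))
        attr(out, "truncated") <- TRUE
    }
    out
}

#' Build the evaluation negative set
#'
#' Evaluation/validation negatives are the union of (a) unannotated pairs at
#' finite shortest-path distance of at least `minDistance` (default 11 hops)
#' on the positive-only network and (b) experimentally determined absolute
#' negatives. Pairs overlapping the training set are removed; unreachable
#' (infinite-distance) pairs are excluded.
#'
#' @param net a [DuplexNetwork-class].
#' @param minDistance odd minimum hop count (default 11).
#' @param absoluteNegatives optional labeled-pair data.frame of experimental
#'   negatives.
#' @param trainPairs optional data.frame of training pairs to exclude.
#' @return labeled-pair data.frame.
#' @export
buildEvalNegatives <- function(net, minDistance = 11L,
                               absoluteNegatives = NULL, trainPairs = NULL) {
    if (minDistance %% 2 == 0) stop("minDistance must be odd")
    d <- shortestPathDistances(net)
    idx <- which(is.finite(d) & d >= minDistance, arr.ind = TRUE)
    n <- nrow(idx)
    out <- data.frame(ligand_id = rownames(d)[idx[, 1]],
                      protein_id = colnames(d)[idx[, 2]],
                      label = rep("negative", n),
                      provenance = rep("network_derived", n),
                      distance = d[idx], stringsAsFactors = FALSE)
    if (!is.null(absoluteNegatives) && nrow(absoluteNegatives)) {
        abs <- data.frame(ligand_id = absoluteNegatives$ligand_id,
                          protein_id = absoluteNegatives$protein_id,
                          label = "negative", provenance = "experimental",
                          distance = NA_real_, stringsAsFactors = FALSE)
        out <- rbind(out, abs)
    }
    out <- out[!duplicated(.pairKey(out$ligand_id, out$protein_id)), ,
               drop = FALSE]
    if (!is.null(trainPairs) && nrow(trainPairs)) {
        drop <- .pairKey(out$ligand_id, out$protein_id) %in%
            .pairKey(trainPairs$ligand_id, trainPairs$protein_id)
        out <- out[!drop, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Keep only nodes with both positive and negative annotations
#'
#' Iteratively removes every pair incident to a node whose remaining
#' annotations are single-signed, until a fixed point is reached: every
#' surviving node has at least one positive and one negative annotation.
#' (A single pass can leave neighbours newly single-signed, so the removal
#' is iterated.)
#'
#' @param pairs labeled-pair data.frame with columns `ligand_id`,
#'   `protein_id`, `label`.
#' @return the surviving pairs.
#' @export
enforceBothAnnotations <- function(pairs) {
    .assertPairFrame(pairs)
    repeat {
        if (!nrow(pairs)) break
        isPos <- pairs$label %in% c("positive", "1") | pairs$label == 1
        badNode <- function(ids) {
            kp <- tapply(isPos, ids, sum)
            kn <- tapply(!isPos, ids, sum)
            names(kp)[kp == 0 | kn == 0]
        }
        bad <- c(paste0("L", badNode(pairs$ligand_id)),
                 paste0("P", badNode(pairs$protein_id)))
        if (!length(bad)) break
        keep <- !(paste0("L", pairs$ligand_id) %in% bad |
                  paste0("P", pairs$protein_id) %in% bad)
        if (all(keep)) break
        pairs <- pairs[keep, , drop = FALSE]
    }
    rownames(pairs) <- NULL
    pairs
}

#' Class balance of a labeled pair set
#'
#' @param pairs labeled-pair data.frame.
#' @return list `n_pos`, `n_neg`, `imbalance` (= n_pos / n_neg, `Inf` when
#'   no negatives exist).
#' @export
classBalanceReport <- function(pairs) {
    isPos <- pairs$label %in% c("positive", "1") | pairs$label == 1
    nPos <- sum(isPos); nNeg <- sum(!isPos)
    list(n_pos = nPos, n_neg = nNeg,
         imbalance = if (nNeg == 0) Inf else nPos / nNeg)
}

#' Write labeled pairs as TSV
#'
#' @param pairs labeled-pair data.frame.
#' @param path file path.
#' @export
writeLabeledPairsTsv <- function(pairs, path) {
    utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeLabeledPairsTsv
#' @export
readLabeledPairsTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    .assertPairFrame(d)
    d
}
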