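#' Construct a signed bipartite (duplex) annotation network
#'
#' Builds a [DuplexNetwork-class] from positive (binding) and negative
#' (non-binding) edge lists. Node registries default to the identifiers
#' appearing in the edges (first-appearance order, positives first); isolated
#' nodes can be registered by passing `ligandIds`/`proteinIds` explicitly.
#'
#' @param positiveEdges,negativeEdges data.frame (or 2-column matrix) with
#'   columns `ligand`, `protein`. Duplicated rows within a layer are
#'   collapsed; a pair present in both layers is an error (the
#'   binding/non-binding joint state is forbidden).
#' @param ligandIds,proteinIds optional character vectors of node
#'   identifiers; must cover every edge endpoint.
#' @return A validated [DuplexNetwork-class].
#' @examples
#' net <- DuplexNetwork(
#'     positiveEdges = data.frame(ligand = "L1", protein = "P1"),
#'     negativeEdges = data.frame(ligand = "L1", protein = c("P2", "P3")))
#' net
#' @export
DuplexNetwork <- function(positiveEdges = NULL, negativeEdges = NULL,
                          ligandIds = NULL, proteinIds = NULL) {
    canon <- function(e) {
        if (is.null(e)) return(.emptyEdges())
        e <- as.data.frame(e, stringsAsFactors = FALSE)
        if (ncol(e) < 2) stop("edge tables need columns ligand, protein")
        if (!all(c("ligand", "protein") %in% names(e)))
            names(e)[1:2] <- c("ligand", "protein")
        e <- data.frame(ligand = as.character(e$ligand),
                        protein = as.character(e$protein),
                        stringsAsFactors = FALSE)
        unique(e)
    }
    pos <- canon(positiveEdges)
    neg <- canon(negativeEdges)
    if (is.null(ligandIds))
        ligandIds <- unique(c(pos$ligand, neg$ligand))
    if (is.null(proteinIds))
        proteinIds <- unique(c(pos$protein, neg$protein))
    new("DuplexNetwork", ligandIds = as.character(ligandIds),
        proteinIds = as.character(proteinIds),
        positiveEdges = pos, negativeEdges = neg)
}

#' @describeIn DuplexNetwork-class ligand identifiers
#' @param x,object a `DuplexNetwork`
#' @export
ligandIds <- function(x) x@ligandIds

#' @describeIn DuplexNetwork-class protein identifiers
#' @export
proteinIds <- function(x) x@proteinIds

#' @describeIn DuplexNetwork-class positive (binding) edge table
#' @export
positiveEdges <- function(x) x@positiveEdges

#' @describeIn DuplexNetwork-class negative (non-binding) edge table
#' @export
negativeEdges <- function(x) x@negativeEdges

#' @describeIn DuplexNetwork-class number of ligands
#' @export
nLigands <- function(x) length(x@ligandIds)

#' @describeIn DuplexNetwork-class number of proteins
#' @export
nProteins <- function(x) length(x@proteinIds)

#' @describeIn DuplexNetwork-class number of positive annotations (L^+)
#' @export
numPositive <- function(x) nrow(x@positiveEdges)

#' @describeIn DuplexNetwork-class number of negative annotations (L^-)
#' @export
numNegative <- function(x) nrow(x@negativeEdges)

setMethod("show", "DuplexNetwork", function(object) {
    cat("DuplexNetwork:", nLigands(object), "ligands x",
        nProteins(object), "proteins\n")
    cat("  annotations:", numPositive(object), "positive,",
        numNegative(object), "negative\n")
})

#' Per-node multidegrees and degree ratios
#'
#' Counts, for every registered node, its positive and negative annotations
#' (the multidegrees k+ and k-) and the degree ratio
#' rho = k+ / (k+ + k-), the per-node measure of annotation imbalance.
#' `rho` is `NA` for nodes without annotations.
#'
#' @param net a [DuplexNetwork-class].
#' @return data.frame with columns `node_id`, `side` ("ligand"/"protein"),
#'   `k_pos`, `k_neg`, `k_total`, `rho`; one row per node, ligands first.
#' @examples
#' multidegrees(toyAnnotationNetwork())
#' @export
multidegrees <- function(net) {
    stopifnot(is(net, "DuplexNetwork"))
    count <- function(ids, col) {
        kp <- table(factor(net@positiveEdges[[col]], levels = ids))
        kn <- table(factor(net@negativeEdges[[col]], levels = ids))
        data.frame(node_id = ids, k_pos = as.integer(kp),
                   k_neg = as.integer(kn), stringsAsFactors = FALSE)
    }
    lig <- count(net@ligandIds, "ligand")
    prt <- count(net@proteinIds, "protein")
    lig$side <- rep("ligand", nrow(lig))
    prt$side <- rep("protein", nrow(prt))
    out <- rbind(lig, prt)
    if (!nrow(out))
        return(data.frame(node_id = character(0), side = character(0),
                          k_pos = integer(0), k_neg = integer(0),
                          k_total = integer(0), rho = numeric(0)))
    out$k_total <- out$k_pos + out$k_neg
    out$rho <- ifelse(out$k_total > 0, out$k_pos / out$k_total, NA_real_)
    rownames(out) <- NULL
    out[, c("node_id", "side", "k_pos", "k_neg", "k_total", "rho")]
}

#' Degree ratio of a node
#'
#' The fraction of a node's annotations that are positive,
#' `rho = kPos / (kPos + kNeg)`. Undefined (an error) for isolated nodes.
#' Vectorized over `kPos`/`kNeg`.
#'
#' @param kPos,kNeg non-negative integer counts of positive and negative
#'   annotations.
#' @return numeric in \[0, 1\].
#' @examples
#' degreeRatio(1, 2)   # 0.333...
#' @export
degreeRatio <- function(kPos, kNeg) {
    if (any(kPos < 0) || any(kNeg < 0))
        stop("multidegrees must be non-negative")
    tot <- kPos + kNeg
    if (any(tot == 0))
        stop("degree ratio undefined for isolated nodes (k_pos + k_neg = 0)")
    kPos / tot
}

#' Maximum-likelihood (Hill) power-law exponent
#'
#' Continuous-approximation MLE for the exponent of a power-law degree
#' distribution, `gamma = 1 + n / sum(log(k / (kMin - 0.5)))` over degrees
#' `>= kMin`. Intended as a diagnostic of fat-tailed annotation counts, not
#' as an inferential fit.
#'
#' @param degrees positive integer degrees.
#' @param kMin lower cutoff of the fitted tail (default 1).
#' @return list with `gamma`, `k_min`, `n_tail`.
#' @examples
#' set.seed(1)
#' fitPowerLawExponent(rPowerLaw(5000, 2.8))$gamma
#' @export
fitPowerLawExponent <- function(degrees, kMin = 1L) {
    stopifnot(kMin >= 1)
    degrees <- degrees[is.finite(degrees)]
    if (any(degrees < 1)) stop("degrees must be positive integers")
    tail <- degrees[degrees >= kMin]
    if (length(tail) < 10)
        stop("need at least 10 observations >= kMin")
    if (length(unique(tail)) < 2)
        stop("all tail degrees identical; exponent undefined")
    gamma <- 1 + length(tail) / sum(log(tail / (kMin - 0.5)))
    list(gamma = gamma, k_min = as.integer(kMin), n_tail = length(tail))
}

#' Sample a discrete power law
#'
#' Inverse-CDF sampler for a discrete power law `P(k) ~ k^-gamma`, `k >= kMin`,
#' via the rounded continuous approximation matched to the
#' [fitPowerLawExponent()] estimator's continuity correction.
#'
#' @param n number of draws.
#' @param gamma exponent (> 1).
#' @param kMin minimum degree.
#' @return integer vector of length `n`.
#' @export
rPowerLaw <- function(n, gamma, kMin = 1L) {
    stopifnot(gamma > 1, kMin >= 1)
    u <- stats::runif(n)
    as.integer(floor((kMin - 0.5) * (1 - u)^(-1 / (gamma - 1)) + 0.5))
}

#' Read / write a signed edge-list TSV
#'
#' The on-disk format is a UTF-8 TSV with header
#' `ligand_id<TAB>protein_id<TAB>label`, where label 1 marks a binding and
#' 0 a non-binding annotation. Reading rejects conflicting duplicate rows
#' (the forbidden joint state) and malformed rows, reporting line numbers.
#'
#' @param path file path.
#' @return `readDuplexTsv` returns a [DuplexNetwork-class];
#'   `writeDuplexTsv` invisibly returns `path`.
#' @export
readDuplexTsv <- function(path) {
    d <- utils::read.delim(path, colClasses = "character")
    need <- c("ligand_id", "protein_id", "label")
    if (!all(need %in% names(d)))
        stop("expected columns ligand_id, protein_id, label in ", path)
    if (!nrow(d)) return(DuplexNetwork())
    lab <- suppressWarnings(as.integer(d$label))
    bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)) |
                 d$ligand_id == "" | d$protein_id == "")
    if (length(bad))
        stop(sprintf("malformed row(s) at line %s of %s",
                     paste(bad + 1L, collapse = ", "), path))
    key <- .pairKey(d$ligand_id, d$protein_id)
    conf <- unique(key[key %in% key[lab == 1] & key %in% key[lab == 0]])
    if (length(conf))
        stop("forbidden multilink: pair(s) listed with both labels: ",
             paste(gsub("\r", "/", conf), collapse = ", "))
    mk <- function(keep) data.frame(ligand = d$ligand_id[keep],
                                    protein = d$protein_id[keep],
                                    stringsAsFactors = FALSE)
    DuplexNetwork(positiveEdges = mk(lab == 1), negativeEdges = mk(lab == 0))
}

#' @param net a [DuplexNetwork-class].
#' @rdname readDuplexTsv
#' @export
writeDuplexTsv <- function(net, path) {
    stopifnot(is(net, "DuplexNetwork"))
    pos <- net@positiveEdges
    neg <- net@negativeEdges
    d <- data.frame(
        ligand_id = c(pos$ligand, neg$ligand),
        protein_id = c(pos$protein, neg$protein),
        label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
        stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}
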