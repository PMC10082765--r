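#' Configuration for the synthetic generators
#'
#' Bundles the parameters of the two seeded generators. The defaults
#' emulate the statistical regime diagnosed in real drug-target annotation
#' data: fat-tailed degree distributions with exponents near 2.9 (ligands)
#' and 2.8 (proteins), an anti-correlation between node degree and the
#' dissociation-constant scale, and the resulting annotation imbalance.
#'
#' The planted affinity model is
#' `log10 Kd(i,j) = kdIntercept - kdSlope * log10(k_i * k_j) + noise`,
#' so hub-hub pairs sit well below the binding threshold (1e3 nM) and
#' low-degree pairs above the non-binding threshold (1e6 nM);
#' `kdSlope >= 0` guarantees the planted anti-correlation.
#'
#' @param nLigands,nProteins node counts.
#' @param gammaLigand,gammaProtein target degree exponents (defaults 2.94
#'   and 2.84).
#' @param kdIntercept,kdSlope,kdNoiseSd affinity model parameters on the
#'   log10-nM scale (defaults 5.5, 2.5, 1.5): low-degree pairs sit near or
#'   above the 1e6 nM non-binding threshold while hub-hub pairs fall below
#'   the 1e3 nM binding threshold, reproducing hub-positive annotation
#'   imbalance.
#' @param latentDim latent feature dimension of the feature world
#'   (default 8).
#' @param linkNoise label-flip probability in \[0, 0.5) (default 0.05).
#' @param nAnnotations number of observed annotated pairs in the feature
#'   world (default: 15% of all pairs).
#' @param seed integer seed.
#' @return a list of class `SyntheticWorldConfig`.
#' @export
syntheticWorldConfig <- function(nLigands = 150L, nProteins = 100L,
                                 gammaLigand = 2.94, gammaProtein = 2.84,
                                 kdIntercept = 5.5, kdSlope = 2.5,
                                 kdNoiseSd = 1.5, latentDim = 8L,
                                 linkNoise = 0.05, nAnnotations = NULL,
                                 seed = 1L) {
    stopifnot(nLigands >= 1, nProteins >= 1, gammaLigand > 1,
              gammaProtein > 1, kdSlope >= 0, kdNoiseSd >= 0,
              latentDim >= 1, linkNoise >= 0, linkNoise < 0.5)
    if (is.null(nAnnotations))
        nAnnotations <- ceiling(0.15 * nLigands * nProteins)
    structure(list(nLigands = as.integer(nLigands),
                   nProteins = as.integer(nProteins),
                   gammaLigand = gammaLigand, gammaProtein = gammaProtein,
                   kdIntercept = kdIntercept, kdSlope = kdSlope,
                   kdNoiseSd = kdNoiseSd, latentDim = as.integer(latentDim),
                   linkNoise = linkNoise,
                   nAnnotations = as.integer(nAnnotations),
                   seed = as.integer(seed)),
              class = "SyntheticWorldConfig")
}

.ligNames <- function(n) sprintf("LIG%04d", seq_len(n))
.prtNames <- function(n) sprintf("PRT%04d", seq_len(n))

#' Generate an imbalanced signed annotation network
#'
#' Draws ligand and protein degree sequences from discrete power laws,
#' wires them by bipartite stub matching (multi-edges collapsed), assigns
#' each surviving edge a dissociation constant from the planted
#' degree-dependent affinity model, and labels edges by the 1e3 / 1e6 nM
#' thresholds. Edges with intermediate affinity stay unannotated, so hubs
#' end up with predominantly positive annotations — the annotation
#' imbalance that enables topological shortcut learning.
#'
#' @param config a [syntheticWorldConfig()].
#' @return list with `network` (a [DuplexNetwork-class]) and `records`
#'   (kinetic interaction records for every wired edge, including
#'   intermediate ones).
#' @export
genImbalancedDuplex <- function(config = syntheticWorldConfig()) {
    stopifnot(inherits(config, "SyntheticWorldConfig"))
    withr::with_seed(config$seed, {
        nL <- config$nLigands; nT <- config$nProteins
        kL <- pmin(rPowerLaw(nL, config$gammaLigand), nT)
        kT <- pmin(rPowerLaw(nT, config$gammaProtein), nL)
        if (sum(kL) > nL * nT / 2 || sum(kT) > nL * nT / 2)
            stop("degenerate config: expected edges exceed half the pairs")
        ligStubs <- sample(rep.int(seq_len(nL), kL))
        prtStubs <- sample(rep.int(seq_len(nT), kT))
        m <- min(length(ligStubs), length(prtStubs))
        edges <- unique(data.frame(i = ligStubs[seq_len(m)],
                                   j = prtStubs[seq_len(m)]))
        ki <- tabulate(edges$i, nL)[edges$i]
        kj <- tabulate(edges$j, nT)[edges$j]
        log10Kd <- config$kdIntercept -
            config$kdSlope * log10(ki * kj) +
            stats::rnorm(nrow(edges), 0, config$kdNoiseSd)
        records <- data.frame(
            ligand_id = .ligNames(nL)[edges$i],
            protein_id = .prtNames(nT)[edges$j],
            constant_type = "Kd",
            value_nM = 10^log10Kd,
            temperature_C = NA_real_,
            source = "synthetic",
            stringsAsFactors = FALSE)
        pos <- records$value_nM <= 1e3
        neg <- records$value_nM >= 1e6
        net <- DuplexNetwork(
            positiveEdges = data.frame(ligand = records$ligand_id[pos],
                                       protein = records$protein_id[pos]),
            negativeEdges = data.frame(ligand = records$ligand_id[neg],
                                       protein = records$protein_id[neg]),
            ligandIds = .ligNames(nL), proteinIds = .prtNames(nT))
        list(network = net, records = records)
    })
}

# token vocabularies for the feature world: one token per (latent dim, sign)
.ligandToken <- function(idx) {
    a <- c("C", "N", "O", "S", "P", "F", "B", "I")
    paste0(a[idx %% 8 + 1], a[(idx %/% 8) %% 8 + 1], a[(idx * 3) %% 8 + 1])
}

.proteinToken <- function(idx) {
    aa <- .AA_LETTERS
    paste0(aa[idx %% 20 + 1], aa[(idx * 7 + 3) %% 20 + 1],
           aa[(idx * 13 + 5) %% 20 + 1])
}

.latentString <- function(u, tokenFun, prefix, scale = 6, cap = 24L) {
    reps <- pmin(round(scale * pmax(c(u, -u), 0)), cap)
    idx <- seq_along(reps) - 1L
    paste0(prefix, paste(rep(vapply(idx, tokenFun, character(1)), reps),
                         collapse = ""))
}

#' Generate a latent-feature binding world
#'
#' A ground truth in which binding is fully determined by molecular
#' features: every node carries a latent Gaussian vector, a pair binds iff
#' the logistic of the latent inner product exceeds 1/2 (labels flipped
#' with probability `linkNoise`), and each node's observable "structure" is
#' a synthetic string built from per-dimension tokens repeated in
#' proportion to the rectified latent coordinates — so the hashed fallback
#' embeddings are noisy (rectified-linear) images of the latents. A subset
#' of pairs is sampled as the observed annotation network.
#'
#' Because annotations carry no information beyond the features, inductive
#' generalization to held-out nodes is possible exactly insofar as a model
#' reads the structures; a topology-only model is blind on such splits.
#'
#' @param config a [syntheticWorldConfig()].
#' @return list with `network` (observed annotations as a
#'   [DuplexNetwork-class]), `pairs` (observed labeled pairs),
#'   `ligandStructures`, `proteinSequences` (named character),
#'   `labels` (full ground-truth 0/1 matrix, ligands x proteins),
#'   `ligandLatents`, `proteinLatents`.
#' @export
genFeatureWorld <- function(config = syntheticWorldConfig()) {
    stopifnot(inherits(config, "SyntheticWorldConfig"))
    withr::with_seed(config$seed, {
        nL <- config$nLigands; nT <- config$nProteins
        ld <- config$latentDim
        U <- matrix(stats::rnorm(nL * ld), nL, ld)
        V <- matrix(stats::rnorm(nT * ld), nT, ld)
        S <- U %*% t(V) / sqrt(ld)
        truth <- S > 0
        flip <- matrix(stats::runif(nL * nT) < config$linkNoise, nL, nT)
        labels <- (truth != flip) + 0L
        dimnames(labels) <- list(.ligNames(nL), .prtNames(nT))
        ligStr <- stats::setNames(
            vapply(seq_len(nL), function(i)
                .latentString(U[i, ], .ligandToken, "CC"), character(1)),
            .ligNames(nL))
        protStr <- stats::setNames(
            vapply(seq_len(nT), function(j)
                .latentString(V[j, ], .proteinToken, "MKT"), character(1)),
            .prtNames(nT))
        nAnn <- min(config$nAnnotations, nL * nT)
        obs <- sample.int(nL * nT, nAnn)
        oi <- ((obs - 1L) %% nL) + 1L
        oj <- ((obs - 1L) %/% nL) + 1L
        pairs <- data.frame(
            ligand_id = .ligNames(nL)[oi], protein_id = .prtNames(nT)[oj],
            label = ifelse(labels[cbind(oi, oj)] == 1L, "positive",
                           "negative"),
            provenance = "experimental", stringsAsFactors = FALSE)
        isPos <- pairs$label == "positive"
        net <- DuplexNetwork(
            positiveEdges = data.frame(ligand = pairs$ligand_id[isPos],
                                       protein = pairs$protein_id[isPos]),
            negativeEdges = data.frame(ligand = pairs$ligand_id[!isPos],
                                       protein = pairs$protein_id[!isPos]),
            ligandIds = .ligNames(nL), proteinIds = .prtNames(nT))
        list(network = net, pairs = pairs, ligandStructures = ligStr,
             proteinSequences = protStr, labels = labels,
             ligandLatents = U, proteinLatents = V)
    })
}

#' Worked-example toy network
#'
#' A 4x4 signed network whose first ligand has one positive and two
#' negative annotations (degree ratio 1/3), embedded in just enough
#' surrounding annotations that every node carries both signs, no node
#' annotates the whole opposite side, and the configuration model has an
#' interior solution.
#'
#' @return a [DuplexNetwork-class].
#' @examples
#' multidegrees(toyAnnotationNetwork())
#' @export
toyAnnotationNetwork <- function() {
    DuplexNetwork(
        positiveEdges = data.frame(
            ligand = c("LIG-A", "LIG-B", "LIG-C", "LIG-D"),
            protein = c("PRT-1", "PRT-2", "PRT-3", "PRT-4")),
        negativeEdges = data.frame(
            ligand = c("LIG-A", "LIG-A", "LIG-B", "LIG-C", "LIG-D"),
            protein = c("PRT-2", "PRT-3", "PRT-1", "PRT-4", "PRT-1")))
}

#' Write the synthetic feature world to disk
#'
#' Emits the standard file formats consumed by the rest of the package:
#' the observed annotations as a signed edge-list TSV, ligand structures as
#' a SMILES table, protein sequences as FASTA, and ground-truth labels as a
#' TSV.
#'
#' @param world output of [genFeatureWorld()].
#' @param dir output directory.
#' @export
writeFeatureWorld <- function(world, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeDuplexTsv(world$network, file.path(dir, "annotations.tsv"))
    utils::write.table(
        data.frame(ligand_id = names(world$ligandStructures),
                   smiles = unname(world$ligandStructures)),
        file.path(dir, "ligands.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeLines(paste0(">", names(world$proteinSequences), "\n",
                      unname(world$proteinSequences)),
               file.path(dir, "proteins.fasta"))
    lab <- as.data.frame(as.table(world$labels), stringsAsFactors = FALSE)
    names(lab) <- c("ligand_id", "protein_id", "label")
    utils::write.table(lab, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}
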