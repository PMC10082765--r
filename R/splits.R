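#' Scenario-aware cross-validation splits
#'
#' Builds train/test splits for the three evaluation scenarios that
#' distinguish genuine generalization from topological shortcut learning:
#' \describe{
#'   \item{transductive}{unseen edges: pairs are partitioned into folds;
#'     every test node still appears in the training pairs.}
#'   \item{semi_inductive}{unseen targets: proteins are partitioned into
#'     folds; test pairs touch a held-out protein and a seen ligand.}
#'   \item{inductive}{unseen nodes: disjoint ligand and protein subsets are
#'     held out per fold; only pairs with BOTH endpoints held out are
#'     tested, and cross pairs (one seen, one unseen endpoint) are
#'     discarded from that fold.}
#' }
#'
#' @param pairs labeled-pair data.frame (`ligand_id`, `protein_id`,
#'   `label`).
#' @param scenario one of `"transductive"`, `"semi_inductive"`,
#'   `"inductive"`.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed; splits are reproducible under it.
#' @return list of splits; each split is a list with elements `scenario`,
#'   `fold`, `train_pairs`, `test_pairs`, `train_ligands`,
#'   `train_proteins`, `seed`.
#' @export
makeScenarioSplits <- function(pairs,
                               scenario = c("transductive", "semi_inductive",
                                            "inductive"),
                               nFolds = 5L, seed = 1L) {
    scenario <- match.arg(scenario)
    .assertPairFrame(pairs)
    n <- nrow(pairs)
    if (n < nFolds) stop("fewer pairs than folds")
    mkSplit <- function(fold, trainIdx, testIdx) {
        tr <- pairs[trainIdx, , drop = FALSE]
        te <- pairs[testIdx, , drop = FALSE]
        trL <- unique(tr$ligand_id); trP <- unique(tr$protein_id)
        te <- switch(scenario,
            transductive = te[te$ligand_id %in% trL &
                              te$protein_id %in% trP, , drop = FALSE],
            semi_inductive = te[te$ligand_id %in% trL &
                                !(te$protein_id %in% trP), , drop = FALSE],
            inductive = te[!(te$ligand_id %in% trL) &
                           !(te$protein_id %in% trP), , drop = FALSE])
        if (!nrow(tr) || !nrow(te))
            stop("infeasible holdout: empty train or test set in fold ", fold)
        rownames(tr) <- rownames(te) <- NULL
        list(scenario = scenario, fold = fold, train_pairs = tr,
             test_pairs = te, train_ligands = trL, train_proteins = trP,
             seed = seed)
    }
    withr::with_seed(seed, {
        if (scenario == "transductive") {
            foldOf <- sample(rep_len(seq_len(nFolds), n))
            lapply(seq_len(nFolds), function(f)
                mkSplit(f, which(foldOf != f), which(foldOf == f)))
        } else if (scenario == "semi_inductive") {
            prots <- unique(pairs$protein_id)
            if (length(prots) < nFolds) stop("fewer proteins than folds")
            foldOf <- sample(rep_len(seq_len(nFolds), length(prots)))
            lapply(seq_len(nFolds), function(f) {
                held <- prots[foldOf == f]
                mkSplit(f, which(!(pairs$protein_id %in% held)),
                        which(pairs$protein_id %in% held))
            })
        } else {
            ligs <- unique(pairs$ligand_id)
            prots <- unique(pairs$protein_id)
            if (length(ligs) < nFolds || length(prots) < nFolds)
                stop("fewer nodes than folds")
            ligFold <- sample(rep_len(seq_len(nFolds), length(ligs)))
            prtFold <- sample(rep_len(seq_len(nFolds), length(prots)))
            lapply(seq_len(nFolds), function(f) {
                heldL <- ligs[ligFold == f]; heldP <- prots[prtFold == f]
                trainIdx <- which(!(pairs$ligand_id %in% heldL) &
                                  !(pairs$protein_id %in% heldP))
                testIdx <- which(pairs$ligand_id %in% heldL &
                                 pairs$protein_id %in% heldP)
                mkSplit(f, trainIdx, testIdx)
            })
        }
    })
}

#' Build the training network of a split
#'
#' @param split one element of [makeScenarioSplits()] output.
#' @return a [DuplexNetwork-class] of the split's training pairs.
#' @export
splitTrainNetwork <- function(split) {
    tr <- split$train_pairs
    isPos <- .binaryLabel(tr$label) == 1L
    DuplexNetwork(
        positiveEdges = data.frame(ligand = tr$ligand_id[isPos],
                                   protein = tr$protein_id[isPos]),
        negativeEdges = data.frame(ligand = tr$ligand_id[!isPos],
                                   protein = tr$protein_id[!isPos]),
        ligandIds = split$train_ligands, proteinIds = split$train_proteins)
}

#' Topological-shortcut diagnostics
#'
#' Quantifies how strongly a model's predictions track network quantities
#' rather than molecular features: the Spearman correlation between each
#' protein's training degree ratio and its mean predicted score (and the
#' same for ligands), plus, when kinetic records are supplied, the
#' degree-vs-mean-affinity correlation per side (fat-tailed annotation data
#' typically show the anti-correlation that seeds the shortcut).
#'
#' @param netTrain training [DuplexNetwork-class].
#' @param predictions data.frame `ligand_id`, `protein_id`, `score`.
#' @param records optional kinetic records (`value_nM` column) for the
#'   degree-affinity diagnostic.
#' @return list with `rho_protein_vs_prediction`,
#'   `rho_ligand_vs_prediction`, and (with records)
#'   `degree_vs_affinity_protein`, `degree_vs_affinity_ligand`.
#' @export
shortcutDiagnostics <- function(netTrain, predictions, records = NULL) {
    .assertPairFrame(predictions)
    deg <- multidegrees(netTrain)
    corSide <- function(side, col) {
        d <- deg[deg$side == side & deg$k_total > 0, ]
        mean_pred <- tapply(predictions$score, predictions[[col]], mean)
        common <- intersect(d$node_id, names(mean_pred))
        if (length(common) < 3) return(NA_real_)
        # constant predictions (or constant rho) leave the correlation
        # undefined; report NA rather than fail the whole diagnostic
        tryCatch(
            spearmanRho(d$rho[match(common, d$node_id)], mean_pred[common]),
            error = function(e) NA_real_)
    }
    out <- list(
        rho_protein_vs_prediction = corSide("protein", "protein_id"),
        rho_ligand_vs_prediction = corSide("ligand", "ligand_id"))
    if (!is.null(records) && nrow(records)) {
        # the degree-vs-affinity diagnostic: rank correlation, over
        # measurement records, between the record count of the node the
        # record stems from and the kinetic value (ranks are unaffected by
        # taking logs, so this is robust to the lognormal affinity scale)
        degAff <- function(col) {
            k <- table(records[[col]])
            kOfRecord <- as.numeric(k[records[[col]]])
            if (length(unique(kOfRecord)) < 2) return(NA_real_)
            spearmanRho(kOfRecord, records$value_nM)
        }
        out$degree_vs_affinity_protein <- degAff("protein_id")
        out$degree_vs_affinity_ligand <- degAff("ligand_id")
    }
    out
}

#' Structure-shuffle control for feature-based models
#'
#' Re-assigns the ligand structure table and the protein sequence table
#' uniformly at random across node ids (annotations unchanged), retrains
#' the supplied model, and reports the metric bundle before and after. A
#' model that genuinely reads molecular features collapses to chance under
#' the shuffle; a model riding topological shortcuts is unaffected.
#'
#' @param trainPairs,testPairs labeled-pair data.frames.
#' @param ligandStructures named character vector, ligand id -> SMILES.
#' @param proteinSequences named character vector, protein id -> sequence.
#' @param trainer function(trainPairs, ligandStructures, proteinSequences,
#'   seed) returning a prediction function(pairs) -> numeric scores.
#' @param seed integer seed used for the permutation and both trainings.
#' @param permutation optional explicit permutation (for controls); the
#'   identity permutation reproduces the original metrics.
#' @return list with `original` and `shuffled` metric bundles
#'   ([metricsReport()]).
#' @export
featureShuffleControl <- function(trainPairs, testPairs, ligandStructures,
                                  proteinSequences, trainer, seed = 1L,
                                  permutation = NULL) {
    evalModel <- function(ligStr, protStr, s) {
        predictFun <- trainer(trainPairs, ligStr, protStr, s)
        metricsReport(testPairs$label, predictFun(testPairs))
    }
    shuffle <- function(x, perm) stats::setNames(unname(x)[perm], names(x))
    perms <- withr::with_seed(seed, list(
        lig = sample(seq_along(ligandStructures)),
        prot = sample(seq_along(proteinSequences))))
    if (!is.null(permutation)) perms <- permutation
    list(original = evalModel(ligandStructures, proteinSequences, seed),
         shuffled = evalModel(shuffle(ligandStructures, perms$lig),
                              shuffle(proteinSequences, perms$prot), seed))
}
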