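#' Tie-aware ranking and threshold metrics
#'
#' `aurocScore` is the Mann-Whitney rank formulation of the area under the
#' ROC curve: the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, with ties counted 1/2 (midranks). It is
#' invariant under strictly monotone transforms of the scores; constant
#' scores give exactly 0.5.
#'
#' `auprcScore` is average precision computed by a non-interpolated sweep
#' over the distinct score values in decreasing order:
#' `sum over thresholds of (recall step) * precision`. Constant scores give
#' exactly the test-set prevalence; a perfect ranking gives 1.
#'
#' @param labels binary vector (0/1 or "positive"/"negative").
#' @param scores numeric scores, higher = more likely binding.
#' @return a scalar metric value.
#' @examples
#' aurocScore(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))   # 1
#' auprcScore(c(1, 0, 1, 0), rep(0.5, 4))             # prevalence 0.5
#' @export
aurocScore <- function(labels, scores) {
    lab <- .binaryLabel(labels)
    stopifnot(length(lab) == length(scores))
    n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
    if (n1 == 0 || n0 == 0)
        stop("AUROC requires both classes in the labels")
    r <- rank(scores)  # midranks
    (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname aurocScore
#' @export
auprcScore <- function(labels, scores) {
    lab <- .binaryLabel(labels)
    stopifnot(length(lab) == length(scores))
    P <- sum(lab == 1L)
    if (P == 0) stop("AUPRC requires at least one positive")
    thr <- sort(unique(scores), decreasing = TRUE)
    tp <- fp <- 0; lastRecall <- 0; ap <- 0
    for (t in thr) {
        sel <- scores == t
        tp <- tp + sum(lab[sel] == 1L)
        fp <- fp + sum(lab[sel] == 0L)
        recall <- tp / P
        precision <- tp / (tp + fp)
        ap <- ap + (recall - lastRecall) * precision
        lastRecall <- recall
    }
    ap
}

#' F1-optimal decision threshold
#'
#' Sweeps the observed score values as candidate thresholds (predict
#' positive when `score >= threshold`) and returns the threshold maximizing
#' the F1 score; ties are broken toward the lowest threshold.
#'
#' @inheritParams aurocScore
#' @return list with `threshold` and `f1`.
#' @export
optimalF1Threshold <- function(labels, scores) {
    lab <- .binaryLabel(labels)
    if (length(unique(lab)) < 2)
        stop("threshold selection requires both classes")
    thr <- sort(unique(scores))
    f1s <- vapply(thr, function(t) {
        tp <- sum(lab == 1L & scores >= t)
        fp <- sum(lab == 0L & scores >= t)
        fn <- sum(lab == 1L & scores < t)
        if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    best <- which.max(f1s)  # which.max returns the first (lowest) maximizer
    list(threshold = thr[best], f1 = f1s[best])
}

#' Confusion matrix and derived metrics at a threshold
#'
#' Scores at or above the threshold are predicted positive. `sensitivity`
#' is tp / (tp + fn); `precision` (tp / (tp + fp)) is also reported so both
#' readings of "fraction of predicted binders that truly bind" are
#' available, labeled unambiguously.
#'
#' @inheritParams aurocScore
#' @param threshold decision threshold.
#' @return list `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `precision`, `f1`.
#' @export
confusionAtThreshold <- function(labels, scores, threshold) {
    lab <- .binaryLabel(labels)
    pred <- scores >= threshold
    tp <- sum(pred & lab == 1L); fp <- sum(pred & lab == 0L)
    tn <- sum(!pred & lab == 0L); fn <- sum(!pred & lab == 1L)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, precision = prec, f1 = f1)
}

#' Full metric bundle for a scored test set
#'
#' Computes AUROC, AUPRC, the F1-optimal threshold and the confusion matrix
#' at that threshold.
#'
#' @inheritParams aurocScore
#' @return list with `auroc`, `auprc`, `threshold`, `f1`, `sensitivity`,
#'   `precision`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
metricsReport <- function(labels, scores) {
    opt <- optimalF1Threshold(labels, scores)
    conf <- confusionAtThreshold(labels, scores, opt$threshold)
    c(list(auroc = aurocScore(labels, scores),
           auprc = auprcScore(labels, scores)),
      conf[c("threshold", "f1", "sensitivity", "precision",
             "tp", "fp", "tn", "fn")],
      list(n = length(scores)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (delegates to [stats::cor()] with
#' `method = "spearman"`), with the argument checks the diagnostics need.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in \[-1, 1\].
#' @export
spearmanRho <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("rank correlation undefined for constant input")
    stats::cor(x, y, method = "spearman")
}

#' Binarize external affinities and score predictions against them
#'
#' Generic hook for comparing binding scores with an external per-pair
#' affinity table (e.g. docking energies in kcal/mol): affinities at or
#' below `affinityThreshold` (default -1.75 kcal/mol) define the positive
#' labels, and the scored predictions are summarized by [metricsReport()].
#'
#' @param predictions data.frame `ligand_id`, `protein_id`, `score`.
#' @param affinities data.frame `ligand_id`, `protein_id`, `affinity`.
#' @param affinityThreshold binding threshold on the affinity (default
#'   -1.75).
#' @return list as [metricsReport()].
#' @export
evaluateAgainstAffinities <- function(predictions, affinities,
                                      affinityThreshold = -1.75) {
    .assertPairFrame(predictions)
    .assertPairFrame(affinities)
    m <- merge(predictions, affinities, by = c("ligand_id", "protein_id"))
    if (!nrow(m)) stop("no overlapping pairs between predictions and ",
                       "affinities")
    labels <- as.integer(m$affinity <= affinityThreshold)
    metricsReport(labels, m$score)
}
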