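#' Trigram-perturbation binding probability profile
#'
#' Scores a ligand against every single-trigram perturbation of a protein
#' sequence: for each trigram start position p (1-based), the protein
#' embedding is recomputed with that one trigram occurrence's count
#' decremented (all other trigram counts untouched, then re-normalized) and
#' the model re-scored. Positions where the score drops well below the
#' unperturbed baseline — valleys — mark trigrams the model relies on,
#' candidate active binding sites.
#'
#' The perturbation operates on the hashed trigram count vector, so the
#' protein provider must be a hashed-trigram provider
#' ([hashedProteinProvider()]).
#'
#' @param model trained scorer, ensemble, or scoring function (see
#'   [predictScore()]).
#' @param proteinSequence amino acid sequence (length >= 3).
#' @param ligandSmiles ligand structure string.
#' @param ligProvider,protProvider embedding providers.
#' @param proteinId,ligandId optional identifiers stored in the profile.
#' @return a [BindingProfile-class] with `values[p]` the perturbed score at
#'   trigram start p and `baseline` the unperturbed score.
#' @export
perturbationProfile <- function(model, proteinSequence, ligandSmiles,
                                ligProvider = hashedLigandProvider(),
                                protProvider = hashedProteinProvider(),
                                proteinId = "protein", ligandId = "ligand") {
    stopifnot(is(protProvider, "EmbeddingProvider"))
    if (protProvider@kind != "hashed_trigram")
        stop("perturbation profiles require a hashed-trigram protein ",
             "provider")
    tokens <- .proteinTrigrams(proteinSequence)
    dim <- protProvider@dimension
    buckets <- .hashBucket(tokens, dim, protProvider@hashSeed)
    counts <- numeric(dim)
    tb <- table(buckets)
    counts[as.integer(names(tb))] <- as.numeric(tb)
    normalize <- function(v) {
        nrm <- sqrt(sum(v^2))
        if (nrm > 0) v / nrm else v
    }
    XL <- embedStructures(ligProvider, ligandSmiles)
    baseEmb <- normalize(counts)
    baseline <- .scoreEmbedded(model, XL, matrix(baseEmb, nrow = 1))

    # perturbed embeddings: one row per trigram position; decrementing one
    # occurrence subtracts 1 from that trigram's bucket before normalization
    P <- matrix(rep(counts, each = length(tokens)), nrow = length(tokens))
    P[cbind(seq_along(tokens), buckets)] <-
        P[cbind(seq_along(tokens), buckets)] - 1
    P <- t(apply(P, 1, normalize))
    XLrep <- XL[rep(1, length(tokens)), , drop = FALSE]
    values <- .scoreEmbedded(model, XLrep, P)
    new("BindingProfile", proteinId = proteinId, ligandId = ligandId,
        sequence = proteinSequence, baseline = baseline,
        values = as.numeric(values),
        deltas = baseline - as.numeric(values))
}

setMethod("show", "BindingProfile", function(object) {
    cat(sprintf(paste0("BindingProfile %s x %s: %d positions, baseline ",
                       "%.4f, max drop %.4f\n"),
                object@ligandId, object@proteinId, length(object@values),
                object@baseline, max(c(object@deltas, 0))))
})

#' @describeIn BindingProfile-class perturbed scores per trigram start
#' @param object a `BindingProfile`
#' @export
profileValues <- function(object) object@values

#' @describeIn BindingProfile-class baseline (unperturbed) score
#' @export
profileBaseline <- function(object) object@baseline

.movingAverage <- function(x, window) {
    if (window <= 1) return(x)
    half <- (window - 1) %/% 2
    n <- length(x)
    vapply(seq_len(n), function(i) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        mean(x[lo:hi])
    }, numeric(1))
}

#' Detect valleys in a binding probability profile
#'
#' Smooths the profile with a centered moving average, flags positions
#' whose smoothed value falls below `mean - depthFactor * sd` of the
#' smoothed profile, and merges flagged runs separated by gaps of at most
#' `mergeGap` positions into single valleys. Valley depth is the baseline
#' minus the minimum raw value inside the valley. The detection is
#' invariant under adding a constant to the whole profile.
#'
#' @param profile a [BindingProfile-class].
#' @param smoothWindow moving-average window (default 5); shrunk with a
#'   warning if the profile is shorter.
#' @param depthFactor detection threshold in smoothed-profile standard
#'   deviations (default 0.5).
#' @param mergeGap maximum gap between merged candidate runs (default 2).
#' @return data.frame with columns `start`, `end` (1-based trigram start
#'   positions, closed interval), `depth`; zero rows when the profile is
#'   flat.
#' @export
detectValleys <- function(profile, smoothWindow = 5L, depthFactor = 0.5,
                          mergeGap = 2L) {
    stopifnot(is(profile, "BindingProfile"))
    x <- profile@values
    if (!length(x)) stop("empty profile")
    if (smoothWindow > length(x)) {
        warning("smoothing window shrunk to profile length")
        smoothWindow <- length(x)
    }
    sm <- .movingAverage(x, smoothWindow)
    sdev <- stats::sd(sm)
    empty <- data.frame(start = integer(0), end = integer(0),
                        depth = numeric(0))
    if (!is.finite(sdev) || sdev == 0) return(empty)
    cand <- which(sm < mean(sm) - depthFactor * sdev)
    if (!length(cand)) return(empty)
    breaks <- which(diff(cand) > mergeGap + 1L)
    starts <- cand[c(1L, breaks + 1L)]
    ends <- cand[c(breaks, length(cand))]
    depth <- vapply(seq_along(starts), function(k)
        profile@baseline - min(x[starts[k]:ends[k]]), numeric(1))
    keep <- depth > 0
    data.frame(start = starts[keep], end = ends[keep], depth = depth[keep])
}

#' Prioritize valleys by secondary structure
#'
#' Annotates each valley with the fraction of its residues labeled as
#' alpha-helix and drops helix-dominated valleys (fraction > `helixMax`):
#' helices pack into non-solvent-accessible environments and disfavour
#' ligand binding, whereas beta-sheets and coils provide accessible binding
#' opportunities. Survivors are ranked by depth.
#'
#' A valley spanning trigram starts `[start, end]` covers residues
#' `start .. end + 2`.
#'
#' @param valleys data.frame from [detectValleys()].
#' @param secondaryStructure per-residue string over H (helix), E (sheet),
#'   C (coil), aligned to the profiled sequence.
#' @param helixMax maximum tolerated helix fraction (default 0.5).
#' @return the retained valleys with an added `ss_fraction_helix` column,
#'   ordered by decreasing depth.
#' @export
prioritizeValleys <- function(valleys, secondaryStructure, helixMax = 0.5) {
    ss <- strsplit(secondaryStructure, "")[[1]]
    if (!all(ss %in% c("H", "E", "C")))
        stop("secondary structure must use letters H, E, C")
    if (nrow(valleys) &&
        max(valleys$end) + 2L > length(ss))
        stop("secondary structure shorter than the profiled sequence")
    frac <- vapply(seq_len(nrow(valleys)), function(k) {
        res <- valleys$start[k]:(valleys$end[k] + 2L)
        mean(ss[res] == "H")
    }, numeric(1))
    valleys$ss_fraction_helix <- frac
    out <- valleys[frac <= helixMax, , drop = FALSE]
    out <- out[order(-out$depth), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a profile and its valleys as TSV
#'
#' The profile TSV has columns `position`, `perturbed_score`, `delta`; the
#' valley TSV is BED-like (`protein_id`, `start`, `end`, `depth`, and
#' `ss_fraction_helix` when present).
#'
#' @param profile a [BindingProfile-class].
#' @param path output file.
#' @export
writeProfileTsv <- function(profile, path) {
    d <- data.frame(position = seq_along(profile@values),
                    perturbed_score = profile@values,
                    delta = profile@deltas)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @param valleys valley data.frame.
#' @param proteinId protein identifier for the BED-like rows.
#' @rdname writeProfileTsv
#' @export
writeValleysTsv <- function(valleys, proteinId, path) {
    d <- cbind(protein_id = proteinId, valleys)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
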