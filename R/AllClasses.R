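#' @import methods
NULL

.emptyEdges <- function() {
    data.frame(ligand = character(0), protein = character(0),
               stringsAsFactors = FALSE)
}

#' DuplexNetwork: a signed bipartite annotation network
#'
#' A bipartite network over ligands and proteins with two mutually exclusive
#' link layers: positive (binding) and negative (non-binding) annotations.
#' A pair can carry at most one annotation; the joint state where a pair is
#' simultaneously binding and non-binding is forbidden.
#'
#' @slot ligandIds character vector of unique ligand identifiers
#'   (e.g. InChIKeys); opaque to the model.
#' @slot proteinIds character vector of unique protein identifiers
#'   (e.g. sequence accessions).
#' @slot positiveEdges data.frame with columns `ligand`, `protein`: the
#'   binding annotations.
#' @slot negativeEdges data.frame with columns `ligand`, `protein`: the
#'   non-binding annotations.
#'
#' @seealso [DuplexNetwork()], [multidegrees()], [fitConfigurationModel()]
#' @exportClass DuplexNetwork
setClass("DuplexNetwork",
    representation(ligandIds = "character",
                   proteinIds = "character",
                   positiveEdges = "data.frame",
                   negativeEdges = "data.frame"),
    prototype(ligandIds = character(0), proteinIds = character(0),
              positiveEdges = .emptyEdges(), negativeEdges = .emptyEdges()))

.edgeKeys <- function(edges) paste(edges$ligand, edges$protein, sep = "\r")

setValidity("DuplexNetwork", function(object) {
    msg <- character(0)
    if (anyDuplicated(object@ligandIds))
        msg <- c(msg, "duplicated ligand identifiers")
    if (anyDuplicated(object@proteinIds))
        msg <- c(msg, "duplicated protein identifiers")
    for (side in c("positiveEdges", "negativeEdges")) {
        e <- slot(object, side)
        if (!all(c("ligand", "protein") %in% names(e))) {
            msg <- c(msg, sprintf("%s must have columns ligand, protein", side))
            next
        }
        if (!all(e$ligand %in% object@ligandIds))
            msg <- c(msg, sprintf("%s contains unregistered ligands", side))
        if (!all(e$protein %in% object@proteinIds))
            msg <- c(msg, sprintf("%s contains unregistered proteins", side))
        if (anyDuplicated(.edgeKeys(e)))
            msg <- c(msg, sprintf("%s contains duplicated pairs", side))
    }
    both <- intersect(.edgeKeys(object@positiveEdges),
                      .edgeKeys(object@negativeEdges))
    if (length(both))
        msg <- c(msg, paste0("forbidden multilink: pair(s) annotated both ",
                             "positive and negative: ",
                             paste(gsub("\r", "/", both), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' MaxEntFit: fitted maximum-entropy duplex configuration model
#'
#' Holds the exponentiated (negated) Lagrange multipliers of the canonical
#' bipartite duplex ensemble that conserves, in expectation, every node's
#' positive and negative multidegree. `xPos[i]` etc. are the quantities
#' `exp(-lambda)` per ligand and layer, `yPos[j]` etc. per protein; a
#' multiplier is exactly zero iff the corresponding multidegree is zero.
#'
#' @slot network the [DuplexNetwork-class] the model was fitted to.
#' @slot xPos,xNeg named numeric, one entry per ligand.
#' @slot yPos,yNeg named numeric, one entry per protein.
#' @slot iterations integer, fixed-point sweeps used.
#' @slot maxResidual numeric, largest absolute gap between expected and
#'   observed multidegree over non-saturated nodes.
#' @slot converged logical.
#' @slot saturatedNodes character, nodes whose multipliers were capped.
#' @slot logPartition numeric, log Z of the ensemble.
#' @exportClass MaxEntFit
setClass("MaxEntFit",
    representation(network = "DuplexNetwork",
                   xPos = "numeric", xNeg = "numeric",
                   yPos = "numeric", yNeg = "numeric",
                   iterations = "integer", maxResidual = "numeric",
                   converged = "logical", saturatedNodes = "character",
                   logPartition = "numeric"))

#' EmbeddingProvider: deterministic structure-to-vector map
#'
#' Wraps a deterministic function mapping a structure string (a SMILES for
#' ligands, an amino acid sequence for proteins) to a fixed-dimension real
#' vector. Results are cached per input string.
#'
#' @slot side "ligand" or "protein".
#' @slot dimension embedding dimension (default 300 for ligands, 100 for
#'   proteins).
#' @slot fun function(character(1)) -> numeric(dimension).
#' @slot kind character tag ("hashed_ngram", "hashed_trigram", "table", ...).
#' @slot hashSeed integer seed mixed into the token hash (hashed providers).
#' @slot cache environment used for memoisation.
#' @exportClass EmbeddingProvider
setClass("EmbeddingProvider",
    representation(side = "character", dimension = "integer",
                   fun = "function", kind = "character",
                   hashSeed = "integer", cache = "environment"))

setValidity("EmbeddingProvider", function(object) {
    if (!object@side %in% c("ligand", "protein"))
        return("side must be 'ligand' or 'protein'")
    if (object@dimension < 1L) return("dimension must be positive")
    TRUE
})

#' BindingScorer: feed-forward binding scorer over paired embeddings
#'
#' A small feed-forward network scoring a (ligand embedding, protein
#' embedding) pair: one dense branch per molecule type, a bilinear
#' interaction block between the leading branch channels, concatenation,
#' two ReLU hidden layers and a logistic output in (0, 1).
#'
#' @slot weights list of weight matrices and bias vectors.
#' @slot ligandDim,proteinDim,hidden integer layer sizes.
#' @slot rank interaction-block rank (channels per branch entering the
#'   bilinear block).
#' @slot seed integer training seed.
#' @slot lossTrace numeric, training-loss trace (one entry per epoch).
#' @slot valTrace numeric, validation-loss trace.
#' @exportClass BindingScorer
setClass("BindingScorer",
    representation(weights = "list", ligandDim = "integer",
                   proteinDim = "integer", hidden = "integer",
                   rank = "integer", seed = "integer",
                   lossTrace = "numeric", valTrace = "numeric"))

#' ScorerEnsemble: fold-ensemble of BindingScorer members
#'
#' Scores are the arithmetic mean over the member scorers, one trained per
#' cross-validation fold.
#'
#' @slot members list of [BindingScorer-class] objects.
#' @exportClass ScorerEnsemble
setClass("ScorerEnsemble", representation(members = "list"))

setValidity("ScorerEnsemble", function(object) {
    if (!length(object@members)) return("ensemble has no members")
    if (!all(vapply(object@members, is, logical(1), "BindingScorer")))
        return("all members must be BindingScorer objects")
    TRUE
})

#' BindingProfile: trigram-perturbation binding probability profile
#'
#' For each overlapping amino acid trigram of a protein sequence, the model
#' score obtained after decrementing that trigram's count in the protein
#' embedding. Valleys (regions well below baseline) mark candidate active
#' binding sites.
#'
#' @slot proteinId,ligandId identifiers.
#' @slot sequence the protein sequence profiled.
#' @slot baseline unperturbed ensemble score.
#' @slot values perturbed score per trigram start (length = nchar - 2,
#'   1-based start positions).
#' @slot deltas baseline - values.
#' @exportClass BindingProfile
setClass("BindingProfile",
    representation(proteinId = "character", ligandId = "character",
                   sequence = "character", baseline = "numeric",
                   values = "numeric", deltas = "numeric"))

setValidity("BindingProfile", function(object) {
    n <- nchar(object@sequence)
    if (length(object@values) != max(n - 2L, 0L))
        return("values must have length nchar(sequence) - 2")
    TRUE
})
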