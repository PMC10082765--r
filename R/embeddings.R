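#' Hashed n-gram fallback embeddings
#'
#' Deterministic, self-contained stand-ins for pretrained molecular
#' embeddings, in the same word-based spirit: a structure string is
#' tokenized (character 2-4-grams for SMILES; overlapping amino acid
#' trigrams for sequences), token counts are hashed into a fixed number of
#' buckets with a platform-stable hash, and the bucket vector is
#' L2-normalized. Identical inputs always give identical vectors, and any
#' token — including ones never seen before — lands in some bucket, so no
#' input fails.
#'
#' `ligandFallbackEmbedding` accepts any non-empty string.
#' `proteinFallbackEmbedding` accepts sequences over the 20 amino acid
#' letters; the ambiguity codes X, U, B, Z are mapped to a single wildcard
#' token; length must be at least 3.
#'
#' @param smiles,sequence structure string.
#' @param dimension embedding dimension (default 300 for ligands, 100 for
#'   proteins).
#' @param hashSeed fixed integer seed of the token hash.
#' @return numeric unit vector of length `dimension`.
#' @examples
#' sum(ligandFallbackEmbedding("CCO")^2)  # 1
#' @export
ligandFallbackEmbedding <- function(smiles, dimension = 300L,
                                    hashSeed = 1769L) {
    if (!nzchar(smiles)) stop("empty SMILES string")
    tokens <- .charNgrams(smiles, 2L:4L)
    if (!length(tokens)) tokens <- smiles  # single-character input
    .hashedCounts(tokens, dimension, hashSeed, normalize = TRUE)
}

#' @rdname ligandFallbackEmbedding
#' @export
proteinFallbackEmbedding <- function(sequence, dimension = 100L,
                                     hashSeed = 2311L) {
    tokens <- .proteinTrigrams(sequence)
    .hashedCounts(tokens, dimension, hashSeed, normalize = TRUE)
}

.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.proteinTrigrams <- function(sequence) {
    if (nchar(sequence) < 3) stop("protein sequence must have length >= 3")
    chars <- strsplit(toupper(sequence), "")[[1]]
    chars[chars %in% c("X", "U", "B", "Z")] <- "X"
    bad <- setdiff(unique(chars), c(.AA_LETTERS, "X"))
    if (length(bad))
        stop("illegal amino acid character(s): ", paste(bad, collapse = ", "))
    n <- length(chars)
    vapply(seq_len(n - 2L), function(p)
        paste(chars[p:(p + 2L)], collapse = ""), character(1))
}

.charNgrams <- function(x, sizes) {
    n <- nchar(x)
    unlist(lapply(sizes[sizes <= n], function(k)
        substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)))
}

.hashedCounts <- function(tokens, dimension, hashSeed, normalize = TRUE) {
    v <- numeric(dimension)
    b <- .hashBucket(tokens, dimension, hashSeed)
    tb <- table(b)
    v[as.integer(names(tb))] <- as.numeric(tb)
    if (normalize) {
        nrm <- sqrt(sum(v^2))
        if (nrm > 0) v <- v / nrm
    }
    v
}

#' Construct embedding providers
#'
#' `hashedLigandProvider()` / `hashedProteinProvider()` wrap the fallback
#' embeddings as [EmbeddingProvider-class] objects with per-string caching.
#' `tableEmbeddingProvider()` wraps an externally computed embedding table
#' (TSV: `id` then `dimension` numeric columns), so pretrained vectors can
#' be plugged in behind the same contract; lookups are by identifier.
#'
#' @param dimension embedding dimension.
#' @param hashSeed fixed hash seed.
#' @return an [EmbeddingProvider-class].
#' @export
hashedLigandProvider <- function(dimension = 300L, hashSeed = 1769L) {
    new("EmbeddingProvider", side = "ligand",
        dimension = as.integer(dimension), kind = "hashed_ngram",
        hashSeed = as.integer(hashSeed),
        fun = function(x) ligandFallbackEmbedding(x, dimension, hashSeed),
        cache = new.env(parent = emptyenv()))
}

#' @rdname hashedLigandProvider
#' @export
hashedProteinProvider <- function(dimension = 100L, hashSeed = 2311L) {
    new("EmbeddingProvider", side = "protein",
        dimension = as.integer(dimension), kind = "hashed_trigram",
        hashSeed = as.integer(hashSeed),
        fun = function(x) proteinFallbackEmbedding(x, dimension, hashSeed),
        cache = new.env(parent = emptyenv()))
}

#' @param path TSV file (`id` column then one column per dimension).
#' @param side `"ligand"` or `"protein"`.
#' @rdname hashedLigandProvider
#' @export
tableEmbeddingProvider <- function(path, side) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- ids
    new("EmbeddingProvider", side = side, dimension = ncol(mat),
        kind = "table", hashSeed = 0L,
        fun = function(x) {
            if (!x %in% ids) stop("no embedding for id: ", x)
            as.numeric(mat[x, ])
        },
        cache = new.env(parent = emptyenv()))
}

#' Embed structure strings through a provider
#'
#' Vectorized, cached evaluation of an [EmbeddingProvider-class].
#'
#' @param provider an [EmbeddingProvider-class].
#' @param x character vector of structure strings (or table ids).
#' @return numeric matrix, one row per element of `x`.
#' @export
embedStructures <- function(provider, x) {
    stopifnot(is(provider, "EmbeddingProvider"))
    out <- matrix(0, nrow = length(x), ncol = provider@dimension)
    for (k in seq_along(x)) {
        key <- x[[k]]
        v <- provider@cache[[key]]
        if (is.null(v)) {
            v <- provider@fun(key)
            if (length(v) != provider@dimension)
                stop("provider returned wrong dimension for input ", key)
            assign(key, v, envir = provider@cache)
        }
        out[k, ] <- v
    }
    out
}

setMethod("show", "EmbeddingProvider", function(object) {
    cat(sprintf("EmbeddingProvider (%s, %s): %d dimensions\n",
                object@side, object@kind, object@dimension))
})

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector (header token -> sequence).
#' @export
readProteinFasta <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    stats::setNames(as.character(seqs), ids)
}

#' Read a ligand SMILES table
#'
#' TSV with columns `ligand_id` and `smiles`.
#'
#' @param path file path.
#' @return named character vector (ligand id -> SMILES).
#' @export
readSmilesTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("ligand_id", "smiles") %in% names(d)))
        stop("expected columns ligand_id, smiles in ", path)
    stats::setNames(d$smiles, d$ligand_id)
}
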