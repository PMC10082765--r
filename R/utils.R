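# internal helpers shared across modules

# Deterministic 32-bit polynomial string hash (Horner scheme over UTF-8
# bytes, modulus 2^31 - 1). All intermediates stay < 2^53 so the arithmetic
# is exact in doubles and stable across platforms.
.HASH_MOD <- 2147483647

.hashString <- function(x, seed = 0L) {
    vapply(x, function(s) {
        h <- (abs(seed) %% .HASH_MOD) + 1
        for (b in utf8ToInt(s)) h <- (h * 131 + b) %% .HASH_MOD
        h
    }, numeric(1), USE.NAMES = FALSE)
}

# bucket indices in 1..dimension
.hashBucket <- function(tokens, dimension, seed = 0L) {
    .hashString(tokens, seed) %% dimension + 1L
}

.pairKey <- function(ligand, protein) paste(ligand, protein, sep = "\r")

# normalize a label column to 0/1 integers; accepts 0/1, "positive"/"negative"
.binaryLabel <- function(label) {
    if (is.numeric(label) || is.logical(label)) {
        lab <- as.integer(label)
        if (!all(lab %in% c(0L, 1L)))
            stop("labels must be 0/1 or positive/negative")
        return(lab)
    }
    lab <- match(as.character(label), c("negative", "positive")) - 1L
    if (anyNA(lab)) stop("labels must be 0/1 or positive/negative")
    lab
}

.assertPairFrame <- function(pairs) {
    stopifnot(is.data.frame(pairs),
              all(c("ligand_id", "protein_id") %in% names(pairs)))
    invisible(pairs)
}
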