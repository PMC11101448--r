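#' Construct a word-embedding model
#'
#' An embedding model maps words to dense semantic vectors. Related words have
#' nearby vectors, so free-text responses can be compared and averaged
#' geometrically.
#'
#' @param words Character vector of vocabulary words (unique, lowercase).
#' @param vectors Numeric matrix with one row per word and `d` columns.
#' @return An object of class `embedding_model`.
#' @export
embedding_model <- function(words, vectors) {
  vectors <- check_matrix(vectors, "vectors")
  if (length(words) != nrow(vectors)) {
    abort("`words` must have one entry per row of `vectors`.")
  }
  if (anyDuplicated(words)) abort("`words` must be unique.")
  rownames(vectors) <- words
  structure(
    list(vocab = words, vectors = vectors, d = ncol(vectors)),
    class = "embedding_model"
  )
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model: %d words, %d dimensions>\n",
              length(x$vocab), x$d))
  invisible(x)
}

#' Read a word embedding in GloVe text format
#'
#' Each line holds a word followed by `d` space-separated floats. The
#' dimension is inferred from the first line; lines with a different number
#' of fields are an error. When a word appears twice, the last occurrence
#' wins (with a warning).
#'
#' @param path Path to the embedding text file.
#' @return An [embedding_model()].
#' @export
load_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("Embedding file is empty.")
  fields <- strsplit(lines, " +")
  d <- length(fields[[1]]) - 1L
  if (d < 1) abort("First embedding line has no vector values.")
  nf <- lengths(fields)
  if (any(nf != d + 1L)) {
    bad <- which(nf != d + 1L)[1]
    abort(sprintf("Ragged embedding row at line %d: expected %d fields, found %d.",
                  bad, d + 1L, nf[bad]))
  }
  words <- vapply(fields, `[[`, character(1), 1L)
  vec <- matrix(as.numeric(unlist(lapply(fields, `[`, -1L))),
                nrow = length(words), ncol = d, byrow = TRUE)
  if (!all(is.finite(vec))) abort("Embedding file contains non-numeric vector values.")
  if (anyDuplicated(words)) {
    warn("Duplicate words in embedding file; keeping the last occurrence of each.")
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]
    vec <- vec[keep, , drop = FALSE]
  }
  embedding_model(words, vec)
}

#' Look up word vectors
#'
#' @param embedding An [embedding_model()].
#' @param words Character vector of words.
#' @param strict Error on out-of-vocabulary words (default) instead of
#'   dropping them.
#' @return A matrix with one row per (found) word.
#' @export
embedding_lookup <- function(embedding, words, strict = TRUE) {
  stopifnot(inherits(embedding, "embedding_model"))
  hit <- words %in% embedding$vocab
  if (strict && !all(hit)) {
    abort(sprintf("Words not in embedding vocabulary: %s",
                  paste(unique(words[!hit]), collapse = ", ")))
  }
  embedding$vectors[words[hit], , drop = FALSE]
}

#' @rdname embedding_lookup
#' @export
in_vocabulary <- function(embedding, words) {
  stopifnot(inherits(embedding, "embedding_model"))
  words %in% embedding$vocab
}

#' Rank lexicon words by cosine similarity to a semantic vector
#'
#' Used to summarize recovered semantic directions with interpretable words.
#' Ties are broken lexicographically so rankings are deterministic.
#'
#' @param vector Numeric semantic vector of length `d`.
#' @param embedding An [embedding_model()].
#' @param lexicon Character vector of candidate words (subset of the
#'   vocabulary). Defaults to the whole vocabulary.
#' @param k Number of words to return; if larger than the lexicon, the full
#'   ranking is returned.
#' @return A tibble with columns `word`, `similarity`, `rank`.
#' @export
nearest_words <- function(vector, embedding, lexicon = NULL, k = 5) {
  stopifnot(inherits(embedding, "embedding_model"))
  if (k < 1) abort("`k` must be at least 1.")
  lexicon <- lexicon %||% embedding$vocab
  if (length(lexicon) == 0) abort("`lexicon` is empty.")
  missing <- setdiff(lexicon, embedding$vocab)
  if (length(missing) > 0) {
    abort(sprintf("Lexicon words not in vocabulary: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  vecs <- embedding$vectors[lexicon, , drop = FALSE]
  sims <- as.numeric(vecs %*% vector) /
    (sqrt(rowSums(vecs^2)) * sqrt(sum(vector^2)))
  ord <- order(-sims, lexicon)
  n <- min(k, length(lexicon))
  tibble(
    word = lexicon[ord][seq_len(n)],
    similarity = sims[ord][seq_len(n)],
    rank = seq_len(n)
  )
}
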