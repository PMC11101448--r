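# Cleaning and embedding of open-ended verbal responses.

#' Default English stopword list
#'
#' A compact standard stopword list (function words, pronouns, auxiliaries).
#' Any word list can be supplied instead; the cleaning rules do not depend on
#' this particular choice.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "he", "him", "his", "she", "her", "hers", "it", "its",
    "they", "them", "their", "theirs", "what", "which", "who", "whom",
    "this", "that", "these", "those", "am", "is", "are", "was", "were",
    "be", "been", "being", "have", "has", "had", "having", "do", "does",
    "did", "doing", "a", "an", "the", "and", "but", "if", "or", "because",
    "as", "until", "while", "of", "at", "by", "for", "with", "about",
    "against", "between", "into", "through", "during", "before", "after",
    "above", "below", "to", "from", "up", "down", "in", "out", "on", "off",
    "over", "under", "again", "further", "then", "once", "here", "there",
    "when", "where", "why", "how", "all", "any", "both", "each", "few",
    "more", "most", "other", "some", "such", "no", "nor", "not", "only",
    "own", "same", "so", "than", "too", "very", "can", "will", "just",
    "should", "now")
}

is_numeral <- function(x) {
  grepl("[0-9]", x) | !is.na(suppressWarnings(as.numeric(x)))
}

# Candidate spell corrections within `max_dist` Levenshtein edits.
# Tie-break among minimal-distance candidates: priority lexicon membership,
# then corpus frequency (if supplied), then lexicographic order.
spell_correct <- function(word, vocab, priority_lexicon = character(),
                          frequencies = NULL, max_dist = 2) {
  len <- nchar(word)
  cand <- vocab[abs(nchar(vocab) - len) <= max_dist]
  if (length(cand) == 0) return(NA_character_)
  d <- as.integer(adist(word, cand))
  ok <- d <= max_dist
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok]; d <- d[ok]
  dmin <- min(d)
  cand <- sort(cand[d == dmin])
  in_prio <- cand %in% priority_lexicon
  if (any(in_prio)) cand <- cand[in_prio]
  if (!is.null(frequencies) && length(cand) > 1) {
    f <- frequencies[cand]
    f[is.na(f)] <- 0
    cand <- cand[order(-f, cand)]
  }
  cand[1]
}

#' Clean free-text trial responses
#'
#' Lowercases labels, removes stopwords, single characters and numerals,
#' spell-corrects words unrecognized by the embedding (maximum Levenshtein
#' edit distance 2, preferring priority-lexicon candidates, then higher
#' corpus frequency, then lexicographic order), and drops uncorrectable
#' words. Multi-word labels recognized whole by the embedding are kept as
#' single tokens; otherwise they are split and cleaned per word. Every input
#' word is accounted for exactly once in the audit log (kept, corrected, or
#' dropped with a reason), and cleaning is idempotent.
#'
#' @param responses A data frame of raw responses: columns `trial_id` and
#'   `label` (long format), or the wide trial-table format of
#'   [load_trials()] with `label_1` .. `label_3` columns. Extra identifier
#'   columns (`participant_id`, `stimulus_id`) are carried through.
#' @param embedding An [embedding_model()] defining the recognized vocabulary.
#' @param priority_lexicon Words preferred when breaking correction ties
#'   (e.g. labels of a natural-image database).
#' @param stopwords Stopword list; see [default_stopwords()].
#' @param frequencies Optional named numeric vector of corpus frequencies for
#'   correction tie-breaking.
#' @param max_dist Maximum edit distance for corrections.
#' @return A list with `responses` (tibble: identifier columns plus `word`,
#'   one row per retained word) and `audit` (tibble: one row per input word
#'   with `original`, `action` in kept/corrected/dropped, `replacement`,
#'   `reason`).
#' @export
clean_responses <- function(responses, embedding,
                            priority_lexicon = character(),
                            stopwords = default_stopwords(),
                            frequencies = NULL, max_dist = 2) {
  long <- responses_to_long(responses)
  stopwords <- tolower(stopwords)
  vocab <- embedding$vocab

  out_rows <- vector("list", nrow(long))
  audit_rows <- vector("list", nrow(long))
  for (i in seq_len(nrow(long))) {
    label <- tolower(trimws(long$label[i]))
    ids <- long[i, setdiff(names(long), "label"), drop = FALSE]
    if (label %in% vocab && !label %in% stopwords &&
        nchar(label) > 1 && !is_numeral(label)) {
      tokens <- label   # multi-word label recognized whole
    } else {
      tokens <- strsplit(label, "[[:space:]]+")[[1]]
      tokens <- tokens[nzchar(tokens)]
    }
    kept <- character(0)
    audits <- vector("list", length(tokens))
    for (ti in seq_along(tokens)) {
      tok <- gsub("[^[:alnum:] '-]", "", tokens[ti])
      res <- clean_token(tok, vocab, stopwords, priority_lexicon,
                         frequencies, max_dist)
      audits[[ti]] <- tibble(original = tokens[ti], action = res$action,
                             replacement = res$word %||% NA_character_,
                             reason = res$reason)
      if (!is.null(res$word)) kept <- c(kept, res$word)
    }
    audit_rows[[i]] <- dplyr::bind_cols(
      ids[rep(1, length(tokens)), , drop = FALSE],
      dplyr::bind_rows(audits)
    )
    if (length(kept) > 0) {
      out_rows[[i]] <- dplyr::bind_cols(
        ids[rep(1, length(kept)), , drop = FALSE],
        tibble(word = kept)
      )
    }
  }
  list(
    responses = dplyr::bind_rows(out_rows),
    audit = dplyr::bind_rows(audit_rows)
  )
}

clean_token <- function(tok, vocab, stopwords, priority_lexicon,
                        frequencies, max_dist) {
  if (!nzchar(tok)) {
    return(list(word = NULL, action = "dropped", reason = "empty"))
  }
  if (tok %in% stopwords) {
    return(list(word = NULL, action = "dropped", reason = "stopword"))
  }
  if (nchar(tok) == 1) {
    return(list(word = NULL, action = "dropped", reason = "single character"))
  }
  if (is_numeral(tok)) {
    return(list(word = NULL, action = "dropped", reason = "numeral"))
  }
  if (tok %in% vocab) {
    return(list(word = tok, action = "kept", reason = NA_character_))
  }
  corr <- spell_correct(tok, vocab, priority_lexicon, frequencies, max_dist)
  if (is.na(corr)) {
    return(list(word = NULL, action = "dropped", reason = "unrecognized"))
  }
  if (corr %in% stopwords || nchar(corr) == 1 || is_numeral(corr)) {
    return(list(word = NULL, action = "dropped",
                reason = "correction filtered"))
  }
  list(word = corr, action = "corrected", reason = NA_character_)
}

# Accepts long (trial_id, label) or wide (label_1..label_3) response tables
# and returns the long form with one row per label string.
responses_to_long <- function(responses) {
  responses <- as_tibble(responses)
  if ("label" %in% names(responses)) {
    if (!"trial_id" %in% names(responses)) abort("`responses` needs a trial_id column.")
    return(dplyr::filter(responses, !is.na(.data$label) & nzchar(.data$label)))
  }
  label_cols <- grep("^label_[0-9]+$", names(responses), value = TRUE)
  if (length(label_cols) == 0) {
    abort("`responses` must contain a `label` column or `label_1`.. columns.")
  }
  long <- tidyr::pivot_longer(responses, dplyr::all_of(label_cols),
                              names_to = "label_slot", values_to = "label")
  long <- dplyr::filter(long, !is.na(.data$label) & nzchar(.data$label))
  dplyr::select(long, -"label_slot")
}

#' Embed one trial's words as a single semantic vector
#'
#' The arithmetic mean of the word vectors. Labels recognized whole by the
#' embedding are embedded as single tokens; otherwise they are split on
#' whitespace and the in-vocabulary parts contribute individually.
#'
#' @param words Character vector of (cleaned) words, at least one.
#' @param embedding An [embedding_model()].
#' @return Numeric vector of length `d`.
#' @export
embed_trial <- function(words, embedding) {
  if (length(words) == 0) abort("`words` must contain at least one word.")
  vecs <- lapply(words, function(w) {
    if (w %in% embedding$vocab) {
      embedding$vectors[w, , drop = FALSE]
    } else {
      parts <- strsplit(w, "[[:space:]]+")[[1]]
      parts <- parts[parts %in% embedding$vocab]
      if (length(parts) == 0) {
        abort(sprintf("Word '%s' (and its parts) not in vocabulary.", w))
      }
      embedding$vectors[parts, , drop = FALSE]
    }
  })
  colMeans(do.call(rbind, vecs))
}

#' Per-trial semantic vectors for a cleaned response table
#'
#' @param cleaned Cleaned responses (the `responses` element of
#'   [clean_responses()], or any tibble with `trial_id` and `word`).
#' @param embedding An [embedding_model()].
#' @return A tibble with `trial_id`, `n_words`, and matrix column `semantic`
#'   (one row per trial; trials with no valid words are absent).
#' @export
embed_trials <- function(cleaned, embedding) {
  stopifnot(all(c("trial_id", "word") %in% names(cleaned)))
  split_words <- split(cleaned$word, cleaned$trial_id)
  vecs <- t(vapply(split_words, embed_trial, numeric(embedding$d),
                   embedding = embedding))
  tibble(
    trial_id = names(split_words),
    n_words = lengths(split_words),
    semantic = vecs
  )
}

#' Extract the trial-by-dimension semantic matrix
#'
#' @param trial_semantics Output of [embed_trials()].
#' @return Numeric matrix with trial ids as row names.
#' @export
semantic_matrix <- function(trial_semantics) {
  m <- trial_semantics$semantic
  rownames(m) <- trial_semantics$trial_id
  m
}

#' Binary indicator vector over a fixed vocabulary
#'
#' Entry `j` is 1 iff vocabulary word `j` appears among the trial's words.
#' Used as the embedding-free control analysis.
#'
#' @param words Character vector of a trial's words.
#' @param vocab Ordered, non-empty word list defining the indicator entries.
#' @return Named 0/1 integer vector of length `length(vocab)`.
#' @export
binary_trial_vector <- function(words, vocab) {
  if (length(vocab) == 0) abort("`vocab` must be non-empty.")
  setNames(as.integer(vocab %in% words), vocab)
}

#' Binary trial matrix for a cleaned response table
#'
#' @inheritParams embed_trials
#' @param vocab Ordered word list.
#' @return 0/1 matrix, trials by vocab, trial ids as row names.
#' @export
binary_trial_matrix <- function(cleaned, vocab) {
  split_words <- split(cleaned$word, cleaned$trial_id)
  m <- t(vapply(split_words, binary_trial_vector, integer(length(vocab)),
                vocab = vocab))
  rownames(m) <- names(split_words)
  m
}

#' Participant exclusion by response concreteness
#'
#' A participant is excluded when the fraction of their words with a
#' concreteness rating below `threshold_rating` strictly exceeds
#' `threshold_frac` (the boundary value keeps the participant). Words without
#' a rating are ignored in the fraction.
#'
#' @param cleaned Cleaned responses with `participant_id` and `word` columns.
#' @param concreteness Data frame with columns `word` and `rating`.
#' @param threshold_rating Ratings below this count as low-concreteness.
#' @param threshold_frac Maximum tolerated low-concreteness fraction.
#' @return A tibble per participant: `participant_id`, `n_rated`,
#'   `frac_low`, `keep`.
#' @export
validate_participant <- function(cleaned, concreteness,
                                 threshold_rating = 4, threshold_frac = 0.25) {
  stopifnot(all(c("participant_id", "word") %in% names(cleaned)))
  stopifnot(all(c("word", "rating") %in% names(concreteness)))
  ratings <- setNames(concreteness$rating, concreteness$word)
  cleaned |>
    dplyr::mutate(rating = ratings[.data$word]) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_rated = sum(!is.na(.data$rating)),
      frac_low = ifelse(.data$n_rated > 0,
                        sum(.data$rating < threshold_rating, na.rm = TRUE) /
                          .data$n_rated,
                        0),
      .groups = "drop"
    ) |>
    dplyr::mutate(keep = .data$frac_low <= threshold_frac)
}

# Singular/plural equivalence used by validation analyses: a word matches
# another if equal after optionally stripping one trailing "s". This is a
# documented approximation, not full lemmatization.
plural_equivalent <- function(a, b) {
  strip <- function(w) ifelse(nchar(w) > 2 & endsWith(w, "s"),
                              substr(w, 1, nchar(w) - 1), w)
  a == b | strip(a) == b | a == strip(b) | strip(a) == strip(b)
}

# All surface forms of `word` under the same equivalence (for response
# removal in leave-concept-out fits).
word_variants <- function(word) {
  base <- if (nchar(word) > 2 && endsWith(word, "s")) {
    substr(word, 1, nchar(word) - 1)
  } else {
    word
  }
  unique(c(word, base, paste0(base, "s")))
}
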