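# Tweet-aware tokenization and sparse count features.
#
# Texts are split on whitespace; `#hashtag` and `@mention` survive as single
# tokens, plain words are lowercased with surrounding punctuation stripped,
# and stop-word unigrams are dropped. Features are counts of unigrams,
# adjacent-pair bigrams, hashtags and mentions over a fixed vocabulary.

#' Default English stop-word list
#'
#' A standard English stop-word list (articles, pronouns, auxiliaries,
#' prepositions and common contractions). Pass `extra` to augment it with
#' domain-specific terms, mirroring common practice of extending a stock
#' list for social-media text.
#'
#' @param extra Character vector of additional stop words (lowercased).
#' @return Character vector of stop words.
#' @export
english_stopwords <- function(extra = character()) {
  base <- c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "you're", "you've", "you'll", "you'd", "your", "yours", "yourself",
    "yourselves", "he", "him", "his", "himself", "she", "she's", "her",
    "hers", "herself", "it", "it's", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom",
    "this", "that", "that'll", "these", "those", "am", "is", "are", "was",
    "were", "be", "been", "being", "have", "has", "had", "having", "do",
    "does", "did", "doing", "a", "an", "the", "and", "but", "if", "or",
    "because", "as", "until", "while", "of", "at", "by", "for", "with",
    "about", "against", "between", "into", "through", "during", "before",
    "after", "above", "below", "to", "from", "up", "down", "in", "out",
    "on", "off", "over", "under", "again", "further", "then", "once",
    "here", "there", "when", "where", "why", "how", "all", "any", "both",
    "each", "few", "more", "most", "other", "some", "such", "no", "nor",
    "not", "only", "own", "same", "so", "than", "too", "very", "s", "t",
    "can", "will", "just", "don", "don't", "should", "should've", "now",
    "d", "ll", "m", "o", "re", "ve", "y", "ain", "aren", "aren't",
    "couldn", "couldn't", "didn", "didn't", "doesn", "doesn't", "hadn",
    "hadn't", "hasn", "hasn't", "haven", "haven't", "isn", "isn't", "ma",
    "mightn", "mightn't", "mustn", "mustn't", "needn", "needn't", "shan",
    "shan't", "shouldn", "shouldn't", "wasn", "wasn't", "weren",
    "weren't", "won", "won't", "wouldn", "wouldn't"
  )
  unique(c(base, tolower(extra)))
}

#' Tokenize a tweet-style text
#'
#' Splits on whitespace, keeps `#hashtag` and `@mention` intact as single
#' tokens (lowercased), lowercases plain words while stripping surrounding
#' punctuation, and removes stop-word unigrams. Hashtags and mentions are
#' never stop-word filtered.
#'
#' @param text A single character string (`NA` or empty gives an empty
#'   token vector).
#' @param stopwords Character vector of stop words; see [english_stopwords()].
#' @return Character vector of tokens, possibly empty.
#' @examples
#' tokenize("End Vaccine Tyranny now! End SB276")
#' tokenize("@JohnDoe @JaneDoe")
#' @export
tokenize <- function(text, stopwords = english_stopwords()) {
  if (length(text) != 1L) stopf("tokenize() expects a single string; see tokenize_corpus()")
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  raw <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  keep <- character(length(raw))
  n <- 0L
  for (tok in raw) {
    if (substr(tok, 1L, 1L) %in% c("#", "@")) {
      tok <- tolower(gsub("[^#@[:alnum:]_]", "", tok))
      if (nchar(tok) > 1L) { n <- n + 1L; keep[n] <- tok }
    } else {
      tok <- tolower(gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", tok))
      tok <- gsub("[^[:alnum:]_']", "", tok)
      if (nzchar(tok) && !(tok %in% stopwords)) { n <- n + 1L; keep[n] <- tok }
    }
  }
  keep[seq_len(n)]
}

#' Tokenize a corpus of texts
#'
#' @param texts Character vector.
#' @inheritParams tokenize
#' @return List of token vectors, one per text.
#' @export
tokenize_corpus <- function(texts, stopwords = english_stopwords()) {
  lapply(texts, tokenize, stopwords = stopwords)
}

#' Classify a vocabulary token by kind
#'
#' @param token Character vector of tokens.
#' @return Character vector in `{unigram, bigram, hashtag, mention}`.
#' @export
token_kind <- function(token) {
  kind <- rep("unigram", length(token))
  kind[grepl(" ", token, fixed = TRUE)] <- "bigram"
  kind[startsWith(token, "#")] <- "hashtag"
  kind[startsWith(token, "@")] <- "mention"
  kind[grepl(" ", token, fixed = TRUE)] <- "bigram"
  kind
}

# all countable terms of one document: its tokens plus adjacent bigrams
doc_terms <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return(character())
  if (n == 1L) return(tokens)
  c(tokens, paste(tokens[-n], tokens[-1L]))
}

#' Build a token vocabulary from a tokenized corpus
#'
#' Every unigram, adjacent-pair bigram, hashtag and mention occurring in the
#' corpus receives one column, in deterministic lexicographic (C collation)
#' order.
#'
#' @param tokens List of token vectors (see [tokenize_corpus()]).
#' @return An object of class `vocabulary`: list with `tokens` (ordered
#'   character), `kind` (parallel vector) and `size`.
#' @export
build_vocabulary <- function(tokens) {
  if (!is.list(tokens) || length(tokens) == 0L)
    stopf("build_vocabulary() needs a non-empty list of token vectors")
  terms <- unique(unlist(lapply(tokens, doc_terms), use.names = FALSE))
  if (length(terms) == 0L)
    stopf("empty vocabulary: no tokens survive preprocessing")
  terms <- lex_sort(terms)
  structure(
    list(tokens = terms, kind = token_kind(terms), size = length(terms)),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (%s)\n", x$size,
              paste(sprintf("%s: %d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a sparse count feature matrix over a fixed vocabulary
#'
#' Entry (i, j) is the frequency of vocabulary term j (unigram, bigram,
#' hashtag or mention) in document i; terms absent from the vocabulary are
#' ignored.
#'
#' @param tokens List of token vectors.
#' @param vocab A [build_vocabulary()] result.
#' @return A `dgCMatrix` with one row per document and the vocabulary terms
#'   as column names.
#' @export
vectorize <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  n <- length(tokens)
  ii <- vector("list", n)
  jj <- vector("list", n)
  for (i in seq_len(n)) {
    j <- match(doc_terms(tokens[[i]]), vocab$tokens)
    j <- j[!is.na(j)]
    ii[[i]] <- rep.int(i, length(j))
    jj[[i]] <- j
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = 1,
    dims = c(n, vocab$size),
    dimnames = list(NULL, vocab$tokens)
  )
}
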