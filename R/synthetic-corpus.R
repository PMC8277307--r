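# Synthetic tweet-like corpora with planted topic structure.
#
# Each stance class owns `n_topics_per_stance` topics with disjoint topic
# vocabularies; all tweets also draw from one shared vocabulary pool. The
# `separation` knob sets the odds that a token comes from the tweet's topic
# vocabulary rather than the shared pool (separation = 0 makes every topic
# draw from the same shared distribution, i.e. statistically
# indistinguishable topics), and `dispersion` jitters the per-tweet mixing
# proportion on the logit scale, controlling within-topic variability.
# Injection layers reproduce the pathologies of multi-keyword collection:
# verbatim duplicates retrieved under a second keyword, retweets embedding
# their originals, and closed-loop "handle-only" conversation clusters.

#' Specify a synthetic tweet corpus
#'
#' @param n_per_class Named counts for the `anti`, `pro` and `neutral`
#'   classes (default 0 each).
#' @param n_topics_per_stance Number of planted topics per stance class.
#' @param vocab_size_per_topic Topic-specific vocabulary size.
#' @param shared_vocab_size Size of the shared vocabulary pool.
#' @param separation Nonnegative; odds that a token is topic-specific
#'   rather than shared. 0 makes all topics statistically identical.
#' @param dispersion Nonnegative; SD of the per-tweet logit jitter on the
#'   topic-token proportion (within-topic variability).
#' @param duplicate_rate Fraction in `[0, 1)` of base tweets re-emitted
#'   verbatim under a second keyword channel.
#' @param retweet_rate Fraction in `[0, 1)` of base tweets re-emitted as
#'   retweets embedding the original text.
#' @param handle_cluster_sizes Integer sizes of closed-loop mention-only
#'   conversation clusters to inject (possibly empty).
#' @param topic_weights Per-stance topic size profile: `NULL` (default)
#'   assigns tweets to topics round-robin (equal sizes), `"zipf"` draws
#'   topic memberships with 1/rank weights (a few large topics, many
#'   small, as in real discourse), or a numeric weight vector of length
#'   `n_topics_per_stance`.
#' @param tokens_per_tweet Mean token count per tweet (Poisson, min 3).
#' @param hashtag_rate Probability a topic/shared token renders as a
#'   `#hashtag` variant.
#' @param mention_rate Probability a token position is an `@mention` drawn
#'   from a small shared account pool.
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_per_class = c(anti = 0, pro = 0, neutral = 0),
                        n_topics_per_stance = 3,
                        vocab_size_per_topic = 25,
                        shared_vocab_size = 120,
                        separation = 1,
                        dispersion = 0.5,
                        duplicate_rate = 0,
                        retweet_rate = 0,
                        handle_cluster_sizes = integer(),
                        topic_weights = NULL,
                        tokens_per_tweet = 12,
                        hashtag_rate = 0.15,
                        mention_rate = 0.05,
                        seed = 1L) {
  if (is.null(names(n_per_class)) && length(n_per_class) == 3L)
    names(n_per_class) <- stance_levels()
  if (!all(stance_levels() %in% names(n_per_class)))
    stopf("invalid spec: n_per_class must be named counts for %s",
          paste(stance_levels(), collapse = ", "))
  n_per_class <- n_per_class[stance_levels()]
  for (cl in stance_levels())
    if (!is_count(n_per_class[[cl]]))
      stopf("invalid spec: n_per_class[%s] must be a nonnegative integer", cl)
  if (!is_count(n_topics_per_stance) || n_topics_per_stance < 1)
    stopf("invalid spec: n_topics_per_stance must be a positive integer")
  if (!is_count(vocab_size_per_topic) || vocab_size_per_topic < 1)
    stopf("invalid spec: vocab_size_per_topic must be a positive integer")
  if (!is_count(shared_vocab_size) || shared_vocab_size < 1)
    stopf("invalid spec: shared_vocab_size must be a positive integer")
  if (!is.numeric(separation) || separation < 0)
    stopf("invalid spec: separation must be nonnegative")
  if (!is.numeric(dispersion) || dispersion < 0)
    stopf("invalid spec: dispersion must be nonnegative")
  for (r in c(duplicate_rate = duplicate_rate, retweet_rate = retweet_rate)) {
    if (!is.numeric(r) || r < 0 || r >= 1)
      stopf("invalid spec: duplicate_rate and retweet_rate must lie in [0, 1)")
  }
  if (length(handle_cluster_sizes) &&
      !all(vapply(handle_cluster_sizes, is_count, logical(1)) &
             handle_cluster_sizes >= 1))
    stopf("invalid spec: handle_cluster_sizes must be positive integers")
  if (!is.null(topic_weights)) {
    if (identical(topic_weights, "zipf")) {
      topic_weights <- zipf_weights(n_topics_per_stance)
    } else if (!(is.numeric(topic_weights) &&
                 length(topic_weights) == n_topics_per_stance &&
                 all(topic_weights > 0))) {
      stopf("invalid spec: topic_weights must be NULL, \"zipf\", or %d positive weights",
            n_topics_per_stance)
    }
  }
  structure(
    list(n_per_class = n_per_class,
         n_topics_per_stance = as.integer(n_topics_per_stance),
         vocab_size_per_topic = as.integer(vocab_size_per_topic),
         shared_vocab_size = as.integer(shared_vocab_size),
         separation = separation, dispersion = dispersion,
         duplicate_rate = duplicate_rate, retweet_rate = retweet_rate,
         handle_cluster_sizes = as.integer(handle_cluster_sizes),
         topic_weights = topic_weights,
         tokens_per_tweet = tokens_per_tweet,
         hashtag_rate = hashtag_rate, mention_rate = mention_rate,
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

# Zipf-ish weights so some terms dominate, as in real term distributions
zipf_weights <- function(n) 1 / seq_len(n)

#' Generate a synthetic tweet corpus
#'
#' Emits the base tweets of each stance class, then injects verbatim
#' duplicates (same `tweet_id`, second `source_keyword`), retweets
#' (fresh id, `is_retweet = TRUE`, embedding the original text) and
#' closed-loop handle clusters whose tweets are >= 95% `@mention` tokens
#' among a 3-account pool. Deterministic for a fixed spec (seed included).
#'
#' @param spec A [corpus_spec()].
#' @return A tibble of class `synthetic_corpus` with columns `tweet_id`,
#'   `text`, `label`, `true_topic`, `is_retweet`, `original_tweet_id`,
#'   `source_keyword`, carrying a `log` attribute with injection counts.
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) stopf("spec must be a corpus_spec")
  with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  shared <- sprintf("shared%03d", seq_len(spec$shared_vocab_size))
  mentions <- sprintf("@account%02d", 1:20)
  p_topic <- spec$separation / (1 + spec$separation)

  rows <- list()
  topic_id <- 0L
  for (stance in stance_levels()) {
    n <- spec$n_per_class[[stance]]
    if (n == 0) next
    topics <- seq_len(spec$n_topics_per_stance)
    vocabs <- lapply(topics, function(t)
      sprintf("%s_t%d_w%03d", stance, t, seq_len(spec$vocab_size_per_topic)))
    assign_topic <- if (is.null(spec$topic_weights)) rep_len(topics, n) else
      sample(topics, n, replace = TRUE, prob = spec$topic_weights)
    lens <- pmax(3L, stats::rpois(n, spec$tokens_per_tweet))
    texts <- character(n)
    for (i in seq_len(n)) {
      p_i <- stats::plogis(stats::qlogis(pmin(pmax(p_topic, 1e-9), 1 - 1e-9)) +
                             stats::rnorm(1, 0, spec$dispersion))
      if (spec$separation == 0) p_i <- 0
      len <- lens[i]
      from_topic <- stats::runif(len) < p_i
      tv <- vocabs[[assign_topic[i]]]
      toks <- character(len)
      nt <- sum(from_topic)
      if (nt > 0)
        toks[from_topic] <- sample(tv, nt, replace = TRUE,
                                   prob = zipf_weights(length(tv)))
      if (nt < len)
        toks[!from_topic] <- sample(shared, len - nt, replace = TRUE,
                                    prob = zipf_weights(length(shared)))
      tag <- stats::runif(len) < spec$hashtag_rate
      toks[tag] <- paste0("#", toks[tag])
      men <- stats::runif(len) < spec$mention_rate
      if (any(men)) toks[men] <- sample(mentions, sum(men), replace = TRUE)
      texts[i] <- paste(toks, collapse = " ")
    }
    rows[[stance]] <- tibble::tibble(
      text = texts, label = stance, true_topic = topic_id + assign_topic)
    topic_id <- topic_id + spec$n_topics_per_stance
  }
  base <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(text = character(), label = character(),
                   true_topic = integer())
  n_base <- nrow(base)
  corpus <- tibble::tibble(
    tweet_id = sprintf("t%06d", seq_len(n_base)),
    text = base$text, label = base$label,
    true_topic = as.integer(base$true_topic),
    is_retweet = FALSE,
    original_tweet_id = NA_character_,
    source_keyword = "kw1"
  )

  # handle-only closed-loop clusters: >=95% mention tokens among 3 accounts
  n_handle <- 0L
  if (length(spec$handle_cluster_sizes)) {
    hc <- list()
    stance_cycle <- rep_len(c("pro", "anti"), length(spec$handle_cluster_sizes))
    for (ci in seq_along(spec$handle_cluster_sizes)) {
      sz <- spec$handle_cluster_sizes[ci]
      accounts <- sprintf("@loop%02du%d", ci, 1:3)
      texts <- vapply(seq_len(sz), function(i) {
        len <- max(4L, stats::rpois(1, spec$tokens_per_tweet))
        toks <- sample(accounts, len, replace = TRUE)
        plain <- stats::runif(len) < 0.05
        if (any(plain)) toks[plain] <- sample(shared, sum(plain), replace = TRUE)
        if (mean(startsWith(toks, "@")) < 0.95) toks[!startsWith(toks, "@")] <-
            sample(accounts, sum(!startsWith(toks, "@")), replace = TRUE)
        paste(toks, collapse = " ")
      }, character(1))
      hc[[ci]] <- tibble::tibble(
        tweet_id = sprintf("h%02d%05d", ci, seq_len(sz)),
        text = texts, label = stance_cycle[ci], true_topic = NA_integer_,
        is_retweet = FALSE, original_tweet_id = NA_character_,
        source_keyword = "kw1")
      n_handle <- n_handle + sz
    }
    corpus <- rbind(corpus, do.call(rbind, hc))
  }

  # duplicates: the same tweet retrieved again under a second keyword
  n_dup <- floor(spec$duplicate_rate * n_base)
  if (n_dup > 0) {
    pick <- sample(n_base, n_dup, replace = FALSE)
    dup <- corpus[pick, ]
    dup$source_keyword <- "kw2"
    corpus <- rbind(corpus, dup)
  }

  # retweets embedding the original text under a fresh id
  n_rt <- floor(spec$retweet_rate * n_base)
  if (n_rt > 0) {
    pick <- sample(n_base, n_rt, replace = FALSE)
    orig <- corpus[pick, ]
    rt <- tibble::tibble(
      tweet_id = sprintf("r%06d", seq_len(n_rt)),
      text = paste("rt", orig$text), label = orig$label,
      true_topic = orig$true_topic, is_retweet = TRUE,
      original_tweet_id = orig$tweet_id, source_keyword = "kw1")
    corpus <- rbind(corpus, rt)
  }

  structure(corpus,
            class = c("synthetic_corpus", class(corpus)),
            log = list(n_base = n_base, n_duplicates = n_dup,
                       n_retweets = n_rt, n_handle = n_handle))
}

#' Generate planted cluster geometry in feature space
#'
#' Places `n_clusters` centroids pairwise `centroid_distance` apart
#' (vertices of a regular simplex) and samples isotropic Gaussian points
#' around each with per-coordinate SD `dispersion / sqrt(dim)`, so the
#' expected member-to-centroid distance (the cluster radius) is close to
#' `dispersion` in any dimension.
#'
#' @param n_clusters Number of planted clusters (>= 1).
#' @param centroid_distance Pairwise distance between true centroids.
#' @param dispersion Isotropic spread; 0 collapses every point onto its
#'   centroid.
#' @param size_per_cluster Points per cluster (>= 1).
#' @param dim Ambient dimension (>= `n_clusters` so the simplex embeds).
#' @param seed Integer RNG seed.
#' @return An object of class `planted_geometry`: list with `points`
#'   (matrix), `assignment`, `centroids_true`, `dispersions_true`.
#' @export
generate_geometry <- function(n_clusters, centroid_distance, dispersion,
                              size_per_cluster, dim = max(2L, n_clusters),
                              seed = 1L) {
  if (!is_count(n_clusters) || n_clusters < 1) stopf("n_clusters must be >= 1")
  if (!is_count(size_per_cluster) || size_per_cluster < 1)
    stopf("size_per_cluster must be >= 1")
  if (!is_count(dim) || dim < 1) stopf("dim must be >= 1")
  if (n_clusters > 1 && dim < n_clusters)
    stopf("dim must be >= n_clusters to embed %d equidistant centroids",
          n_clusters)
  if (centroid_distance < 0 || dispersion < 0)
    stopf("centroid_distance and dispersion must be nonnegative")
  with_seed(seed, {
    centroids <- matrix(0, n_clusters, dim)
    if (n_clusters > 1) {
      for (i in seq_len(n_clusters))
        centroids[i, i] <- centroid_distance / sqrt(2)
    }
    assignment <- rep(seq_len(n_clusters), each = size_per_cluster)
    # per-coordinate SD chosen so E||point - centroid|| = dispersion exactly
    # (mean of a chi_dim variate), in any dimension
    chi_mean <- sqrt(2) * exp(lgamma((dim + 1) / 2) - lgamma(dim / 2))
    noise <- matrix(stats::rnorm(length(assignment) * dim,
                                 sd = dispersion / chi_mean),
                    ncol = dim)
    structure(
      list(points = centroids[assignment, , drop = FALSE] + noise,
           assignment = assignment,
           centroids_true = centroids,
           dispersions_true = rep(dispersion, n_clusters)),
      class = "planted_geometry")
  })
}

#' @export
print.planted_geometry <- function(x, ...) {
  cat(sprintf("<planted_geometry> %d points, %d clusters, dim %d\n",
              nrow(x$points), nrow(x$centroids_true), ncol(x$points)))
  invisible(x)
}

#' Injection log of a synthetic corpus
#'
#' @param corpus A [generate_corpus()] result.
#' @return List with `n_base`, `n_duplicates`, `n_retweets`, `n_handle`.
#' @export
corpus_log <- function(corpus) attr(corpus, "log")
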