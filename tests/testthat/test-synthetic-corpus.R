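test_that("generate_corpus emits the specified class counts", {
  spec <- corpus_spec(n_per_class = c(anti = 1550, pro = 1639, neutral = 2422),
                      seed = 3)
  co <- generate_corpus(spec)
  expect_equal(nrow(co), 5611)
  expect_equal(as.vector(table(co$label)[c("anti", "pro", "neutral")]),
               c(1550, 1639, 2422))
  expect_false(anyDuplicated(co$tweet_id) > 0)

  empty <- generate_corpus(corpus_spec(n_per_class = c(anti = 0, pro = 0,
                                                       neutral = 0)))
  expect_equal(nrow(empty), 0)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(corpus_spec(n_per_class = c(anti = -1, pro = 0, neutral = 0)),
               "n_per_class")
  expect_error(corpus_spec(duplicate_rate = 1), "duplicate_rate")
  expect_error(corpus_spec(separation = -0.1), "separation")
  expect_error(corpus_spec(n_topics_per_stance = 0), "n_topics_per_stance")
  expect_error(corpus_spec(handle_cluster_sizes = c(3, 0)),
               "handle_cluster_sizes")
})

test_that("duplicate injection matches the generator log", {
  spec <- corpus_spec(n_per_class = c(anti = 40, pro = 30, neutral = 30),
                      duplicate_rate = 0.1, seed = 9)
  co <- generate_corpus(spec)
  log <- corpus_log(co)
  expect_equal(sum(duplicated(co$tweet_id)), log$n_duplicates)
  expect_equal(log$n_duplicates, 10)
  # duplicates are verbatim re-emissions under a second keyword channel
  dup_ids <- co$tweet_id[duplicated(co$tweet_id)]
  for (id in dup_ids) {
    rows <- co[co$tweet_id == id, ]
    expect_equal(length(unique(rows$text)), 1L)
    expect_setequal(rows$source_keyword, c("kw1", "kw2"))
  }
})

test_that("retweets reference an existing original", {
  spec <- corpus_spec(n_per_class = c(anti = 50, pro = 50, neutral = 0),
                      retweet_rate = 0.2, seed = 4)
  co <- generate_corpus(spec)
  rt <- co[co$is_retweet, ]
  expect_equal(nrow(rt), corpus_log(co)$n_retweets)
  expect_true(all(rt$original_tweet_id %in% co$tweet_id))
})

test_that("handle clusters are mention-dominated closed loops", {
  spec <- corpus_spec(n_per_class = c(anti = 20, pro = 20, neutral = 0),
                      handle_cluster_sizes = c(12, 9), seed = 5)
  co <- generate_corpus(spec)
  hc <- co[startsWith(co$tweet_id, "h"), ]
  expect_equal(nrow(hc), 21)
  frac_mention <- vapply(strsplit(hc$text, " "), function(t)
    mean(startsWith(t, "@")), numeric(1))
  expect_true(all(frac_mention >= 0.95))
})

test_that("corpus generation is byte-deterministic per seed", {
  spec <- corpus_spec(n_per_class = c(anti = 30, pro = 30, neutral = 30),
                      duplicate_rate = 0.05, retweet_rate = 0.05,
                      handle_cluster_sizes = 5, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(generate_corpus(spec), f1)
  write_corpus(generate_corpus(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero separation gives statistically indistinguishable topics", {
  spec <- corpus_spec(n_per_class = c(anti = 0, pro = 120, neutral = 0),
                      n_topics_per_stance = 2, separation = 0, seed = 6)
  co <- generate_corpus(spec)
  toks <- tokenize_corpus(co$text)
  X <- vectorize(toks, build_vocabulary(toks))
  # no topic-specific terms at all: every term comes from the shared pools
  expect_false(any(grepl("_t[0-9]+_w", colnames(X))))
  sc <- distinctiveness(X, which(co$true_topic == 1), which(co$true_topic == 2))
  expect_lt(sc, 0.5)
})

test_that("mean planted distinctiveness is nondecreasing in separation", {
  mean_score <- function(sep) mean(vapply(1:5, function(s)
    planted_pair_score(sep, seed = 100 + s), numeric(1)))
  scores <- vapply(c(0.2, 1, 4), mean_score, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("topic_weights controls the planted topic size profile", {
  base <- list(n_per_class = c(anti = 0, pro = 400, neutral = 0),
               n_topics_per_stance = 4, seed = 2)
  uni <- generate_corpus(do.call(corpus_spec, base))
  expect_equal(as.vector(table(uni$true_topic)), rep(100, 4))

  zipf <- generate_corpus(do.call(corpus_spec, c(base, topic_weights = "zipf")))
  sizes <- as.vector(table(factor(zipf$true_topic, levels = 1:4)))
  expect_gt(sizes[1], sizes[4])  # 1/rank weights: first topic dominates

  expect_error(corpus_spec(n_topics_per_stance = 3, topic_weights = c(1, 2)),
               "topic_weights")
})

test_that("generate_geometry places centroids and spread as requested", {
  g <- generate_geometry(2, centroid_distance = 10, dispersion = 1,
                         size_per_cluster = 200, seed = 1)
  cent <- t(vapply(1:2, function(k)
    colMeans(g$points[g$assignment == k, , drop = FALSE]),
    numeric(ncol(g$points))))
  sep <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  expect_lt(abs(sep - 10) / 10, 0.05)
  r1 <- cluster_radius(g$points, which(g$assignment == 1))
  expect_lt(abs(r1 - 1), 0.15)

  # degenerate spread: every point sits on its centroid
  g0 <- generate_geometry(3, centroid_distance = 5, dispersion = 0,
                          size_per_cluster = 10, seed = 2)
  for (k in 1:3)
    expect_equal(cluster_radius(g0$points, which(g0$assignment == k)), 0)

  # a single cluster defines no pairwise distinctiveness
  g1 <- generate_geometry(1, centroid_distance = 0, dispersion = 1,
                          size_per_cluster = 10, seed = 3)
  expect_equal(nrow(g1$centroids_true), 1L)
  geom <- cluster_geometry(g1$points, g1$assignment)
  expect_error(prominent_vs_rest(geom, geom$ids, integer()), "non-empty")

  expect_error(generate_geometry(2, 1, 1, 5, dim = 0), "dim")
  expect_identical(generate_geometry(4, 6, 0.5, 20, seed = 7),
                   generate_geometry(4, 6, 0.5, 20, seed = 7))
})
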