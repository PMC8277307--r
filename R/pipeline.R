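# End-to-end deterministic pipeline: simulate -> dedup -> train ->
# classify -> cluster per stance -> geometry -> report. Every artifact is
# a plain-text file and the whole run is byte-reproducible for a fixed
# seed.

#' Run the full synthetic analysis pipeline
#'
#' Generates a corpus from `spec`, deduplicates it, trains the one-vs-all
#' stance model on the labeled tweets, classifies the corpus, extracts
#' topics per stance group (silhouette-chosen k, handle-cluster exclusion,
#' 5% prominence rule on the stance total net of excluded clusters),
#' computes cluster geometry and the pro-vs-anti distinctiveness t-test,
#' and writes all artifacts under `out_dir`.
#'
#' @param spec A [corpus_spec()]; its seed is overridden by `seed`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; all stage seeds derive from it.
#' @param k_range Candidate k for [select_k()] (clipped per stance group).
#' @param k Optional fixed cluster count per stance group, bypassing the
#'   silhouette selection (the analyst's override after inspecting the
#'   curve); the curve is still computed and written.
#' @param C Inverse regularization strength for training.
#' @param prominence_fraction Prominence rule fraction (default 0.05).
#' @param figures Also render the circle-and-edge figures (default FALSE).
#' @return Invisible list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(spec, out_dir, seed = spec$seed, k_range = 2:8,
                         k = NULL, C = 1, prominence_fraction = 0.05,
                         figures = FALSE) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  spec$seed <- as.integer(seed)

  corpus <- generate_corpus(spec)
  write_corpus(corpus, pth("corpus.jsonl"))
  ded <- deduplicate(corpus)
  write_corpus(ded$unique, pth("corpus_dedup.jsonl"))
  tweets <- ded$unique

  tokens <- tokenize_corpus(tweets$text)
  vocab <- build_vocabulary(tokens)
  X <- vectorize(tokens, vocab)
  model <- train_stance(X, tweets$label, C = C, seed = seed + 1L,
                        vocabulary = vocab)
  write_stance_model(model, pth("model.json"))
  tweets$predicted <- predict(model, X)
  write_corpus_predictions(tweets, pth("labeled.jsonl"))

  stance_results <- list()
  scores <- list()
  for (stance in c("pro", "anti")) {
    rows <- which(tweets$predicted == stance)
    xs <- X[rows, , drop = FALSE]
    kr <- k_range[k_range <= length(rows) - 1L & k_range >= 2L]
    sel <- select_k(xs, kr, seed = seed + 2L)
    k_use <- if (is.null(k)) sel$k_best else min(as.integer(k), length(rows) - 1L)
    fit <- kmeans_fit(xs, k_use, seed = seed + 3L)
    handle <- Filter(function(id)
      is_handle_cluster(top_terms(xs, fit, id)), seq_len(fit$k))
    n_net <- sum(fit$sizes[setdiff(seq_len(fit$k), handle)])
    thr <- prominence_threshold(n_net, prominence_fraction)
    prom <- filter_prominent(fit, thr, exclude = unlist(handle))
    geom <- cluster_geometry(xs, fit, stance = stance)
    utils::write.csv(
      data.frame(tweet_id = tweets$tweet_id[rows], stance = stance,
                 cluster_id = fit$cluster),
      pth(sprintf("clusters_%s.csv", stance)), row.names = FALSE)
    utils::write.csv(
      data.frame(k = sel$curve$k, silhouette = sel$curve$silhouette),
      pth(sprintf("silhouette_%s.csv", stance)), row.names = FALSE)
    utils::write.csv(
      data.frame(cluster_id = geom$ids, size = geom$sizes,
                 radius = unname(geom$radii)),
      pth(sprintf("geometry_%s.csv", stance)), row.names = FALSE)
    sc <- NULL
    if (length(prom$prominent) && length(prom$rest)) {
      sc <- prominent_vs_rest(geom, prom$prominent, prom$rest)
      utils::write.csv(as.data.frame(sc$scores),
                       pth(sprintf("distances_%s.csv", stance)),
                       row.names = FALSE)
      if (figures)
        plot_geometry(geom, prom$prominent, prom$rest,
                      pth(sprintf("geometry_%s.svg", stance)))
    }
    stance_results[[stance]] <- list(k_best = sel$k_best, k_used = k_use,
                                     fit = fit,
                                     prominent = prom, geometry = geom,
                                     distances = sc)
    scores[[stance]] <- if (is.null(sc)) numeric() else sc$scores$score
  }

  comparison <- NULL
  if (length(scores$pro) >= 2L && length(scores$anti) >= 2L)
    comparison <- two_sample_t(scores$anti, scores$pro)

  report <- list(
    n_corpus = nrow(corpus), n_dropped = ded$n_dropped,
    n_unique = nrow(tweets), vocabulary_size = vocab$size,
    class_counts = as.list(table(tweets$label)),
    predicted_counts = as.list(table(tweets$predicted)),
    k_best = lapply(stance_results, `[[`, "k_best"),
    k_used = lapply(stance_results, `[[`, "k_used"),
    prominent = lapply(stance_results, function(s) s$prominent$prominent),
    excluded_handle_clusters = lapply(stance_results, function(s)
      s$prominent$excluded_handle_clusters),
    distinctiveness = lapply(stance_results, function(s)
      if (is.null(s$distances)) NULL else
        list(mean = s$distances$mean, sd = s$distances$sd,
             n = nrow(s$distances$scores))),
    comparison = if (is.null(comparison)) NULL else
      list(t = comparison$t, df = comparison$df, p = comparison$p,
           tail = comparison$tail, variance = comparison$variance))
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(corpus = corpus, dedup = ded, model = model,
                 stances = stance_results, comparison = comparison,
                 report = report, dir = out_dir))
}

write_corpus_predictions <- function(tweets, path) {
  df <- tweets
  df$label <- df$predicted
  df$predicted <- NULL
  write_corpus(df, path)
}

#' Distinctiveness of one planted topic pair in a replicate corpus
#'
#' Generates a small two-topic corpus at the given topic separation, runs
#' it through tokenization and count features, and returns the
#' intertopic-distinctiveness score of the two planted topics under their
#' true assignments. Replicate corpora (distinct seeds) give statistically
#' independent scores, which makes them the right unit for comparing topic
#' separation between conditions with a two-sample t-test: pair scores
#' within a single clustering share clusters and are not independent.
#'
#' @param separation Topic separation of the planted pair.
#' @param seed RNG seed of the replicate.
#' @param per_topic Tweets per topic (default 25).
#' @param dispersion Within-topic variability (default 0.5).
#' @return A single distinctiveness score.
#' @export
planted_pair_score <- function(separation, seed, per_topic = 25L,
                               dispersion = 0.5) {
  spec <- corpus_spec(
    n_per_class = c(anti = 0, pro = 2L * per_topic, neutral = 0),
    n_topics_per_stance = 2L, separation = separation,
    dispersion = dispersion, seed = seed)
  co <- generate_corpus(spec)
  tokens <- tokenize_corpus(co$text)
  X <- vectorize(tokens, build_vocabulary(tokens))
  distinctiveness(X, which(co$true_topic == 1L), which(co$true_topic == 2L))
}
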