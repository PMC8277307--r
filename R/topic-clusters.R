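# Topic extraction: K-means on the raw count-feature space with
# silhouette-based choice of k, a 5% prominence rule, and exclusion of
# "handle-only" clusters (closed-loop conversation threads whose top terms
# are all @-mentions).

#' Fit K-means with seeded multi-restart Lloyd iteration
#'
#' Runs `n_init` Lloyd restarts from random distinct-row initial centers
#' and keeps the partition with the lowest within-cluster sum of squares.
#' Deterministic for a fixed seed.
#'
#' @param x Feature matrix (rows = documents); sparse input is densified.
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer RNG seed.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `cluster_assignment`: `k`, `cluster` (index per
#'   row), `centroids` (k x p), `sizes`, `inertia`.
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  x <- as.matrix(x)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (k > nrow(x)) stopf("k = %d exceeds the %d rows", k, nrow(x))
  ux <- unique(x)
  if (nrow(ux) < k)
    stopf("only %d distinct rows; cannot place %d centers", nrow(ux), k)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      centers0 <- ux[sample(nrow(ux), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers0,
                                       iter.max = max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stopf("k-means failed for all %d restarts", n_init)
    structure(
      list(k = k, cluster = as.integer(best$cluster),
           centroids = unname(best$centers),
           sizes = as.integer(table(factor(best$cluster, levels = seq_len(k)))),
           inertia = best$tot.withinss),
      class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, n = %d, inertia = %.4g\n",
              x$k, length(x$cluster), x$inertia))
  invisible(x)
}

cluster_vector <- function(assignment) {
  if (inherits(assignment, "cluster_assignment")) assignment$cluster
  else as.integer(assignment)
}

#' Mean silhouette coefficient of a partition
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the lowest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)` (0 for singleton clusters). The mean
#' over points, in `[-1, 1]`, scores cluster cohesion: near 1 means members
#' sit closer to their own cluster than to any other, near 0 means clusters
#' are not well separated.
#'
#' @param x Feature matrix.
#' @param assignment Cluster index per row, or a [kmeans_fit()] result;
#'   needs k >= 2 non-empty clusters.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(x, assignment) {
  cl <- cluster_vector(assignment)
  x <- as.matrix(x)
  if (length(cl) != nrow(x)) stopf("assignment length must match rows")
  ks <- sort(unique(cl))
  if (length(ks) < 2L) stopf("silhouette needs at least 2 clusters")
  D <- as.matrix(stats::dist(x))
  sizes <- table(factor(cl, levels = ks))
  # S[i, c] = total distance from point i to all members of cluster c
  S <- t(rowsum(D, group = cl))
  own <- match(cl, ks)
  a <- S[cbind(seq_len(nrow(x)), own)] / pmax(sizes[own] - 1, 1)
  Smean <- sweep(S, 2L, as.numeric(sizes), `/`)
  Smean[cbind(seq_len(nrow(x)), own)] <- Inf
  b <- apply(Smean, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1] <- 0
  s[!is.finite(s)] <- 0
  mean(s)
}

#' Select k by mean silhouette over a range
#'
#' Fits K-means at each k in the range, scores each partition by mean
#' silhouette, and returns the argmax (ties resolve to the smallest k)
#' together with the full curve.
#'
#' @param x Feature matrix.
#' @param k_range Integer vector of candidate k, within `[2, nrow(x) - 1]`.
#' @param seed RNG seed used for every fit.
#' @param n_init Restarts per fit.
#' @return List with `k_best` and `curve` (tibble of k, silhouette).
#' @export
select_k <- function(x, k_range, seed = 1L, n_init = 10L) {
  if (length(k_range) == 0L) stopf("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(as.matrix(x))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stopf("k_range must lie within [2, nrow(x) - 1]")
  sil <- vapply(k_range, function(k)
    mean_silhouette(x, kmeans_fit(x, k, seed = seed, n_init = n_init)),
    numeric(1))
  list(k_best = k_range[which.max(sil)],
       curve = tibble::tibble(k = k_range, silhouette = sil))
}

#' Prominence threshold: 5% of the total tweet count
#'
#' @param total_tweets Base tweet count (configurable: all stance tweets,
#'   or stance tweets net of excluded handle clusters).
#' @param fraction Prominence fraction, in (0, 1); default 0.05.
#' @return `ceiling(fraction * total_tweets)` as an integer.
#' @export
prominence_threshold <- function(total_tweets, fraction = 0.05) {
  if (!is_count(total_tweets)) stopf("total_tweets must be a nonnegative integer")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stopf("fraction must lie in (0, 1)")
  as.integer(ceiling(fraction * total_tweets))
}

#' Split clusters into prominent, rest, and excluded sets
#'
#' After removing the excluded (handle-only) clusters, clusters holding at
#' least `threshold_count` members are prominent; the remaining retained
#' clusters form the rest.
#'
#' @param assignment A [kmeans_fit()] result or cluster index vector.
#' @param threshold_count Nonnegative integer member-count threshold.
#' @param exclude Integer ids of clusters excluded from the analysis.
#' @return Object of class `prominent_set`: `threshold_count`, `prominent`,
#'   `excluded_handle_clusters`, `rest`.
#' @export
filter_prominent <- function(assignment, threshold_count, exclude = integer()) {
  if (!is_count(threshold_count)) stopf("threshold_count must be nonnegative")
  cl <- cluster_vector(assignment)
  ids <- sort(unique(cl))
  sizes <- as.integer(table(factor(cl, levels = ids)))
  exclude <- intersect(as.integer(exclude), ids)
  retained <- setdiff(ids, exclude)
  prominent <- retained[sizes[match(retained, ids)] >= threshold_count]
  structure(
    list(threshold_count = as.integer(threshold_count),
         prominent = prominent,
         excluded_handle_clusters = exclude,
         rest = setdiff(retained, prominent)),
    class = "prominent_set")
}

#' @export
print.prominent_set <- function(x, ...) {
  cat(sprintf("<prominent_set> threshold %d | prominent: %s | excluded: %s | rest: %d clusters\n",
              x$threshold_count, paste(x$prominent, collapse = ","),
              if (length(x$excluded_handle_clusters))
                paste(x$excluded_handle_clusters, collapse = ",") else "none",
              length(x$rest)))
  invisible(x)
}

#' Top terms of a cluster by summed frequency
#'
#' @param x Count-feature matrix with vocabulary terms as column names.
#' @param assignment A [kmeans_fit()] result or cluster index vector.
#' @param cluster_id Cluster to summarize.
#' @param n Number of terms (default 50); ties break lexicographically,
#'   zero-count terms are dropped.
#' @return Character vector of at most `n` terms, descending frequency.
#' @export
top_terms <- function(x, assignment, cluster_id, n = 50L) {
  cl <- cluster_vector(assignment)
  if (!cluster_id %in% cl) stopf("unknown cluster id %s", cluster_id)
  counts <- Matrix::colSums(x[cl == cluster_id, , drop = FALSE])
  terms <- colnames(x)
  if (is.null(terms)) stopf("feature matrix needs vocabulary column names")
  keep <- counts > 0
  counts <- counts[keep]; terms <- terms[keep]
  ord <- order(-counts, terms, method = "radix")
  utils::head(terms[ord], n)
}

#' Is a cluster a handle-only (closed-loop conversation) cluster?
#'
#' TRUE iff every one of the cluster's top terms (the top 50, or all of
#' them when fewer exist) consists of Twitter handles: `@mention` tokens,
#' or bigrams whose both parts are mentions. Such clusters are closed-loop
#' tweet exchanges between a few accounts rather than public discourse and
#' are excluded from topic analysis.
#'
#' @param top Ranked term vector from [top_terms()] (non-empty).
#' @param kind Optional kind vector parallel to `top`; derived from the
#'   tokens via [token_kind()] when omitted.
#' @return Logical flag.
#' @export
is_handle_cluster <- function(top, kind = NULL) {
  if (length(top) == 0L) stopf("top term list must be non-empty")
  top <- utils::head(top, 50L)
  if (is.null(kind)) kind <- token_kind(top) else kind <- utils::head(kind, 50L)
  mentionish <- kind == "mention" |
    (kind == "bigram" & vapply(strsplit(top, " ", fixed = TRUE),
                               function(p) all(startsWith(p, "@")),
                               logical(1)))
  all(mentionish)
}
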