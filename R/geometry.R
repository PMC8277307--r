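# Intratopic consistency and intertopic distinctiveness.
#
# The radius of a topic cluster is the mean Euclidean distance from its
# member tweets to the cluster center: a larger radius means less
# internally consistent discourse. The distinctiveness of a pair of
# clusters is their centroid separation normalized by the sum of the two
# radii, so a score below 1 means the clusters overlap substantially and a
# score of 1 or more means they are distinct. NOTE: the normalization
# (centroid distance / (radius_X + radius_Y)) is an inference from the
# decision rule's semantics, chosen so that tangent clusters score exactly
# 1; it is stated as an assumption, not a transcription.

euclid <- function(u, v) sqrt(sum((u - v)^2))

#' Intratopic consistency radius of a cluster
#'
#' Mean Euclidean distance from member points to the cluster centroid.
#'
#' @param x Feature matrix.
#' @param members Row indices of the cluster (non-empty).
#' @param centroid Optional centroid vector; defaults to the member mean.
#' @return Nonnegative radius.
#' @export
cluster_radius <- function(x, members, centroid = NULL) {
  if (length(members) == 0L) stopf("cluster must be non-empty")
  xm <- as.matrix(x[members, , drop = FALSE])
  if (is.null(centroid)) centroid <- colMeans(xm)
  mean(sqrt(rowSums(sweep(xm, 2L, centroid)^2)))
}

#' Intertopic distinctiveness of two clusters
#'
#' Centroid separation divided by the sum of the two cluster radii.
#' Coincident centroids give 0; two point-clusters (both radii 0) at
#' distinct locations are reported as `Inf` (undefined overlap).
#'
#' @param x Feature matrix.
#' @param members_x,members_y Row indices of the two clusters (non-empty).
#' @param centroid_x,centroid_y Optional centroids; default member means.
#' @return Nonnegative score; `< 1` indicates substantial overlap, `>= 1`
#'   distinct topics.
#' @export
distinctiveness <- function(x, members_x, members_y,
                            centroid_x = NULL, centroid_y = NULL) {
  if (length(members_x) == 0L || length(members_y) == 0L)
    stopf("both clusters must be non-empty")
  mx <- as.matrix(x[members_x, , drop = FALSE])
  my <- as.matrix(x[members_y, , drop = FALSE])
  if (is.null(centroid_x)) centroid_x <- colMeans(mx)
  if (is.null(centroid_y)) centroid_y <- colMeans(my)
  d <- euclid(centroid_x, centroid_y)
  if (d == 0) return(0)
  rx <- cluster_radius(x, members_x, centroid_x)
  ry <- cluster_radius(x, members_y, centroid_y)
  if (rx + ry == 0) return(Inf)
  d / (rx + ry)
}

#' Per-cluster geometry of a partition
#'
#' @param x Feature matrix.
#' @param assignment A [kmeans_fit()] result or cluster index vector.
#' @param stance Optional stance tag carried along (`"pro"`/`"anti"`).
#' @return Object of class `cluster_geometry`: `ids`, `sizes`, `radii`,
#'   `centroids` (rows in `ids` order), `stance`.
#' @export
cluster_geometry <- function(x, assignment, stance = NA_character_) {
  cl <- cluster_vector(assignment)
  x <- as.matrix(x)
  ids <- sort(unique(cl))
  centroids <- t(vapply(ids, function(id)
    colMeans(x[cl == id, , drop = FALSE]), numeric(ncol(x))))
  radii <- vapply(seq_along(ids), function(i)
    cluster_radius(x, which(cl == ids[i]), centroids[i, ]), numeric(1))
  structure(
    list(ids = ids,
         sizes = as.integer(table(factor(cl, levels = ids))),
         radii = stats::setNames(radii, ids),
         centroids = centroids,
         stance = stance),
    class = "cluster_geometry")
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf("<cluster_geometry>%s %d clusters | radii %.3g-%.3g\n",
              if (is.na(x$stance)) "" else paste0(" [", x$stance, "]"),
              length(x$ids), min(x$radii), max(x$radii)))
  invisible(x)
}

geometry_pair_score <- function(geom, i, j) {
  d <- euclid(geom$centroids[i, ], geom$centroids[j, ])
  if (d == 0) return(0)
  rsum <- geom$radii[i] + geom$radii[j]
  if (rsum == 0) return(Inf)
  unname(d / rsum)
}

#' Distinctiveness of prominent clusters versus the rest
#'
#' One score per ordered (prominent, rest) pair, `|prominent| * |rest|`
#' values, with mean and SD summaries.
#'
#' @param geom A [cluster_geometry()] object.
#' @param prominent,rest Disjoint, non-empty cluster-id sets.
#' @return Object of class `distinctiveness_scores`: tibble `scores`
#'   (`from`, `to`, `score`), `mean`, `sd`, `stance`.
#' @export
prominent_vs_rest <- function(geom, prominent, rest) {
  stopifnot(inherits(geom, "cluster_geometry"))
  if (length(prominent) == 0L || length(rest) == 0L)
    stopf("prominent and rest must both be non-empty")
  if (length(intersect(prominent, rest)))
    stopf("prominent and rest id sets must be disjoint")
  if (!all(c(prominent, rest) %in% geom$ids))
    stopf("unknown cluster ids")
  pairs <- expand.grid(from = prominent, to = rest)
  score <- mapply(function(a, b)
    geometry_pair_score(geom, match(a, geom$ids), match(b, geom$ids)),
    pairs$from, pairs$to)
  structure(
    list(scores = tibble::tibble(from = pairs$from, to = pairs$to,
                                 score = as.numeric(score)),
         mean = mean(score), sd = stats::sd(score), stance = geom$stance),
    class = "distinctiveness_scores")
}

#' @export
print.distinctiveness_scores <- function(x, ...) {
  cat(sprintf("<distinctiveness_scores>%s %d pairs | mean %.2f (SD %.2f)\n",
              if (is.na(x$stance)) "" else paste0(" [", x$stance, "]"),
              nrow(x$scores), x$mean, x$sd))
  invisible(x)
}

#' Two-sample t-test comparison of score groups
#'
#' Pooled-variance two-tailed by default (the convention for the
#' intertopic-distinctiveness comparison); one-tailed (`a` greater) and
#' Welch unequal-variance modes are available.
#'
#' @param a,b Numeric score vectors, each of length >= 2.
#' @param tail `"two"` (default) or `"one"` (alternative: mean of `a`
#'   greater than mean of `b`).
#' @param variance `"pooled"` (default) or `"unequal"` (Welch).
#' @return Object of class `group_comparison` with group means/SDs/sizes,
#'   `t`, `df`, `p`, and the modes used.
#' @export
two_sample_t <- function(a, b, tail = c("two", "one"),
                         variance = c("pooled", "unequal")) {
  tail <- match.arg(tail)
  variance <- match.arg(variance)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 observations")
  ht <- stats::t.test(a, b,
                      alternative = if (tail == "two") "two.sided" else "greater",
                      var.equal = variance == "pooled")
  structure(
    list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
         mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value), tail = tail, variance = variance),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> mean %.2f (SD %.2f, n=%d) vs %.2f (SD %.2f, n=%d)\n  t(%.4g) = %.2f, P = %.3g [%s-tailed, %s variance]\n",
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$df, x$t, x$p, x$tail, x$variance))
  invisible(x)
}

#' Summary-statistic two-sample pooled t-test
#'
#' Pooled t computed directly from group means, SDs and sizes — useful for
#' checking printed group summaries without the raw scores.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
summary_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  df <- n_a + n_b - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

circle_df <- function(cx, cy, r, id, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th), id = id)
}

#' Plot the circle-and-edge topic geometry
#'
#' Prominent clusters are drawn centrally as circles whose radius is
#' proportional to the intratopic radius (less consistency, larger
#' circle); the rest of the clusters sit on an outer ring, connected to
#' each prominent cluster by edges labeled with the distinctiveness score.
#' A zero-radius cluster is rendered as a minimum-size marker with an
#' annotation. The layout is deterministic, so re-rendering writes an
#' identical file.
#'
#' @param geom A [cluster_geometry()] object.
#' @param prominent,rest Cluster-id sets to draw.
#' @param path Output file; `.svg` or `.png` by extension.
#' @param edge_labels Label edges with scores (default TRUE).
#' @return `path`, invisibly, carrying the computed circle layout and edge
#'   table as `layout` and `edges` attributes.
#' @export
plot_geometry <- function(geom, prominent, rest, path, edge_labels = TRUE) {
  stopifnot(inherits(geom, "cluster_geometry"))
  scores <- prominent_vs_rest(geom, prominent, rest)$scores
  rmax <- max(geom$radii[as.character(c(prominent, rest))], 1e-9)
  r_in <- if (length(prominent) > 1L) 3 * rmax else 0
  r_out <- 8 * rmax
  place <- function(ids, R, offset = 0) {
    th <- offset + 2 * pi * (seq_along(ids) - 1L) / max(length(ids), 1L)
    data.frame(id = ids, cx = R * cos(th), cy = R * sin(th))
  }
  pos <- rbind(place(prominent, r_in), place(rest, r_out, offset = pi / 8))
  pos$r <- pmax(geom$radii[as.character(pos$id)], 0.02 * rmax)
  pos$zero <- geom$radii[as.character(pos$id)] == 0

  edges <- merge(scores, stats::setNames(pos[, c("id", "cx", "cy")],
                                         c("from", "x0", "y0")), by = "from")
  edges <- merge(edges, stats::setNames(pos[, c("id", "cx", "cy")],
                                        c("to", "x1", "y1")), by = "to")
  circles <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i)
    circle_df(pos$cx[i], pos$cy[i], pos$r[i], pos$id[i])))

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = x0, y = y0, xend = x1, yend = y1),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(x, y, group = id),
                       color = "steelblue") +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(cx, cy,
                                    label = ifelse(zero,
                                                   paste0(id, " (r=0)"),
                                                   id)),
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf(
      "Intertopic distinctiveness%s: prominent clusters vs the rest",
      if (is.na(geom$stance)) "" else paste0(" (", geom$stance, ")")))
  if (edge_labels)
    p <- p + ggplot2::geom_text(
      data = edges,
      ggplot2::aes((x0 + x1) / 2, (y0 + y1) / 2,
                   label = sprintf("%.2f", score)),
      size = 2.2, color = "grey40")

  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 8, height = 8)
  else if (ext == "png") grDevices::png(path, width = 800, height = 800)
  else stopf("unsupported figure extension '%s' (use .svg or .png)", ext)
  print(p)
  grDevices::dev.off()
  invisible(structure(path, layout = pos, edges = edges))
}
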