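# shared fixtures built in code

# the study's published 3-class confusion matrix (rows actual, cols predicted)
study_confusion <- function() {
  matrix(c(1344, 166, 40,
           175, 1364, 100,
           25, 48, 2349),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("anti", "pro", "neutral"),
                         c("anti", "pro", "neutral")))
}

# a near-separable three-class corpus spec: high topic separation, little
# within-topic jitter, no hashtag/mention rendering noise
separable_spec <- function(seed, n = 100) {
  corpus_spec(n_per_class = c(anti = n, pro = n, neutral = n),
              n_topics_per_stance = 2, separation = 50, dispersion = 0.1,
              hashtag_rate = 0, mention_rate = 0, seed = seed)
}

# brute-force oracles ------------------------------------------------------

brute_silhouette <- function(x, cl) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (c2 in setdiff(unique(cl), cl[i])) {
      mem <- which(cl == c2)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

brute_radius <- function(x, members, centroid = NULL) {
  x <- as.matrix(x)
  if (is.null(centroid)) centroid <- colMeans(x[members, , drop = FALSE])
  tot <- 0
  for (i in members) tot <- tot + sqrt(sum((x[i, ] - centroid)^2))
  tot / length(members)
}

brute_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- 0
  for (ct in cats) pe <- pe + mean(a == ct) * mean(b == ct)
  (po - pe) / (1 - pe)
}
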