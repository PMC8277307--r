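test_that("oversampling balances classes while keeping every original row", {
  labels <- c(rep("anti", 10), rep("pro", 10), rep("neutral", 10))
  expect_identical(oversample(labels, seed = 1), seq_along(labels))

  labels2 <- c(rep("anti", 5), rep("pro", 10), rep("neutral", 10))
  idx <- oversample(labels2, seed = 1)
  expect_identical(idx[1:25], 1:25)  # originals retained, in place
  expect_equal(as.vector(table(labels2[idx])), c(10, 10, 10))
  expect_true(all(labels2[idx[-(1:25)]] == "anti"))

  labels3 <- c(rep("anti", 1550), rep("pro", 1639), rep("neutral", 2422))
  expect_equal(as.vector(table(labels3[oversample(labels3, seed = 2)])),
               rep(2422, 3))

  expect_identical(oversample(labels2, seed = 7), oversample(labels2, seed = 7))
  expect_error(oversample(factor("a", levels = c("a", "b"))), "class")
})

test_that("training separates a separable toy set and collapses at tiny C", {
  x <- rbind(matrix(rnorm(40, mean = -3), 20, 2),
             matrix(rnorm(40, mean = 3), 20, 2))
  labels <- rep(c("anti", "pro"), each = 20)
  m <- train_stance(x, labels, seed = 1)
  expect_equal(mean(predict(m, x) == labels), 1)

  mtiny <- train_stance(x, labels, C = 1e-6, seed = 1)
  expect_equal(max(abs(mtiny$W)), 0)

  expect_error(train_stance(x, rep("anti", 40)), "2 classes")
  expect_error(train_stance(x, labels, C = 0), "C must be")
})

test_that("fitted probabilities match an independent penalized-likelihood fit", {
  x <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2, 3, 1), ncol = 2, byrow = TRUE)
  y <- c(0, 0, 1, 1, 1)
  C <- 1
  m <- train_stance(x, ifelse(y == 1, "pro", "anti"), C = C, balance = FALSE)
  p_pkg <- predict(m, x, type = "prob")[, "pro"]

  obj <- function(par) {
    z <- x %*% par[1:2] + par[3]
    sum(log1p(exp(-ifelse(y == 1, z, -z)))) + (1 / C) * sum(abs(par[1:2]))
  }
  best <- NULL
  for (start in list(c(0, 0, 0), c(1, 1, 0), c(-1, 1, 1))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p_oracle <- stats::plogis(x %*% best$par[1:2] + best$par[3])
  expect_lt(max(abs(p_pkg - as.numeric(p_oracle))), 1e-3)
})

test_that("prediction takes the highest confidence, ties in fixed class order", {
  mk <- function(b) structure(
    list(W = Matrix::Matrix(0, 2, 3, sparse = TRUE,
                            dimnames = list(NULL, stance_levels())),
         b = stats::setNames(b, stance_levels()),
         classes = stance_levels(), C = 1, vocabulary = NULL),
    class = "stance_model")
  x0 <- matrix(0, 1, 2)
  # all-zero features: decision falls to the intercepts
  expect_equal(predict(mk(c(anti = 1, pro = 0, neutral = -1)), x0), "anti")
  expect_equal(predict(mk(c(anti = -1, pro = 2, neutral = 0)), x0), "pro")
  # exact three-way tie resolves to anti (first in the fixed order)
  expect_equal(predict(mk(c(0, 0, 0)), x0), "anti")
  expect_error(predict(mk(c(0, 0, 0)), matrix(0, 1, 5)), "width")
})

test_that("stratified CV is near-perfect on a separable corpus", {
  co <- generate_corpus(separable_spec(seed = 11))
  tokens <- tokenize_corpus(co$text)
  rep <- cross_validate(tokens, co$label, k = 10, seed = 5)
  expect_gte(rep$accuracy, 99)
  # pooled confusion row sums equal the class supports
  expect_equal(unname(rowSums(rep$confusion)), rep(100, 3))
  expect_error(cross_validate(tokens[1:30], co$label[1:30], k = 50),
               "fewer than k")
})

test_that("CV accuracy sits near chance under label permutation", {
  co <- generate_corpus(separable_spec(seed = 12))
  tokens <- tokenize_corpus(co$text)
  accs <- vapply(1:5, function(s) {
    perm <- with(list(), { set.seed(s); sample(co$label) })
    cross_validate(tokens, perm, k = 10, seed = 5)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 25)
  expect_lt(mean(accs), 42)
})

test_that("CV accuracy is stable across two orders of magnitude of penalty", {
  co <- generate_corpus(
    corpus_spec(n_per_class = c(anti = 60, pro = 60, neutral = 60),
                n_topics_per_stance = 2, separation = 3, dispersion = 0.5,
                seed = 13))
  tokens <- tokenize_corpus(co$text)
  # penalty weight lambda = 1/C swept over two orders of magnitude
  accs <- vapply(c(10, 1, 0.1, 0.05), function(C)
    cross_validate(tokens, co$label, k = 10, C = C, seed = 5)$accuracy,
    numeric(1))
  expect_lt(diff(range(accs)), 10)
  expect_gt(min(accs), 80)
})

test_that("metrics reproduce the published per-class and binary tables", {
  r <- compute_metrics(study_confusion())
  expect_equal(round(unname(r$precision), 1), c(87.0, 86.4, 94.4))
  expect_equal(round(unname(r$recall), 1), c(86.7, 83.2, 97.0))
  expect_equal(round(unname(r$f_measure), 1), c(86.9, 84.8, 95.7))
  expect_equal(round(r$accuracy, 1), 90.1)
  expect_equal(unname(r$support), c(1550, 1639, 2422))

  b <- collapse_binary(study_confusion())
  expect_equal(unname(b), matrix(c(3049, 140, 73, 2349), 2, byrow = TRUE))
  rb <- compute_metrics(b)
  expect_equal(round(unname(rb$precision), 1), c(97.7, 94.4))
  expect_equal(round(unname(rb$recall), 1), c(95.6, 97.0))
  expect_equal(round(unname(rb$f_measure), 1), c(96.6, 95.7))
  expect_equal(round(rb$accuracy, 1), 96.2)
})

test_that("metric edge cases behave as documented", {
  perfect <- compute_metrics(diag(c(5, 5, 5)))
  expect_true(all(perfect$precision == 100, perfect$recall == 100,
                  perfect$f_measure == 100, perfect$accuracy == 100))
  # an unpredicted class has undefined precision
  m <- matrix(c(3, 0, 2, 0), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(r <- compute_metrics(m), "precision undefined")
  expect_true(is.nan(r$precision[["b"]]))
  expect_error(compute_metrics(matrix(0, 2, 2)), "at least one")
})

test_that("collapse_binary preserves totals and never lowers the trace", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(rpois(9, 20), 3)
    b <- collapse_binary(m)
    expect_equal(sum(b), sum(m))
    expect_gte(sum(diag(b)), sum(diag(m)))
  }
  expect_equal(unname(collapse_binary(matrix(0, 3, 3))), matrix(0, 2, 2))
})

test_that("stance models survive a JSON round trip", {
  co <- generate_corpus(separable_spec(seed = 14, n = 30))
  tokens <- tokenize_corpus(co$text)
  vocab <- build_vocabulary(tokens)
  X <- vectorize(tokens, vocab)
  m <- train_stance(X, co$label, seed = 1, vocabulary = vocab)
  f <- withr::local_tempfile(fileext = ".json")
  write_stance_model(m, f)
  m2 <- read_stance_model(f)
  expect_equal(as.matrix(m2$W), as.matrix(m$W), tolerance = 1e-12)
  expect_equal(m2$b, m$b)
  expect_equal(m2$classes, m$classes)
  expect_equal(m2$vocabulary$tokens, vocab$tokens)
  expect_identical(predict(m2, X), predict(m, X))
})
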