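# One-vs-all l1-regularized logistic stance classification.
#
# Each class gets one binary model (class vs rest) fitted by penalized
# maximum likelihood; prediction takes the class whose binary model gives
# the highest logistic confidence score, ties broken by the fixed class
# order anti < pro < neutral. Class imbalance is handled by resampling
# minority-class training rows with replacement until all classes match
# the majority count. The inverse-penalty convention C is used (C = 1
# default, no tuning); the per-observation penalty handed to the
# coordinate-descent fitter is lambda = 1 / (N * C), which makes the
# optimized objective sum(log-loss) + (1/C) * ||w||_1.

canonical_classes <- function(labels) {
  u <- unique(as.character(labels))
  if (all(u %in% stance_levels())) intersect(stance_levels(), u) else lex_sort(u)
}

#' Oversample minority classes to balance training data
#'
#' Returns a row-index multiset in which every class count equals the
#' majority-class count: all original rows, plus indices drawn with
#' replacement from each minority class.
#'
#' @param labels Class label per row.
#' @param seed Integer RNG seed.
#' @return Integer vector of row indices (length = k * majority count).
#' @export
oversample <- function(labels, seed = 1L) {
  counts <- table(labels)  # factor input keeps empty levels visible
  if (any(counts == 0) || length(counts) < 1L)
    stopf("every class must have at least one example")
  labels <- as.character(labels)
  target <- max(counts)
  with_seed(seed, {
    extra <- lapply(names(counts), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0) return(integer())
      sample(which(labels == cl), need, replace = TRUE)
    })
    c(seq_along(labels), unlist(extra))
  })
}

fit_binary_l1 <- function(x, y01, C, lambda_eff = NULL) {
  # pad a zero column if needed: the fitter requires >= 2 predictors
  pad <- ncol(x) < 2L
  if (pad) x <- cbind(x, 0)
  lam <- if (is.null(lambda_eff)) 1 / (nrow(x) * C) else lambda_eff
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                   lambda = lam, standardize = FALSE,
                   thresh = 1e-10, maxit = 1e6),
    warning = function(w) {
      # tiny fixtures trip an informational small-n warning; not actionable
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  w <- as.numeric(fit$beta[, 1L])
  if (pad) w <- w[-length(w)]
  list(w = w, b = as.numeric(fit$a0[1L]))
}

#' Train a one-vs-all l1-logistic stance model
#'
#' @param x Feature matrix (sparse `dgCMatrix` from [vectorize()] or a
#'   dense matrix), one row per document.
#' @param labels Class label per row (>= 2 distinct classes).
#' @param C Inverse regularization strength (> 0); the penalty weight
#'   `lambda = 1/C` in the penalized log-likelihood.
#' @param seed RNG seed for the oversampling draw.
#' @param balance Oversample minority classes before fitting (default TRUE).
#' @param vocabulary Optional [build_vocabulary()] object stored with the
#'   model for serialization and width checks.
#' @return Object of class `stance_model`: coefficient matrix `W`
#'   (features x classes), intercepts `b`, `classes`, `C`, `vocabulary`.
#' @export
train_stance <- function(x, labels, C = 1, seed = 1L, balance = TRUE,
                         vocabulary = NULL) {
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stopf("nrow(x) must match length(labels)")
  if (length(unique(labels)) < 2L)
    stopf("training needs at least 2 classes, got %d", length(unique(labels)))
  if (!is.numeric(C) || C <= 0) stopf("C must be > 0")
  idx <- if (balance) oversample(labels, seed) else seq_along(labels)
  xs <- x[idx, , drop = FALSE]
  ys <- labels[idx]
  classes <- canonical_classes(labels)
  fits <- lapply(classes, function(cl)
    fit_binary_l1(xs, as.numeric(ys == cl), C))
  W <- do.call(cbind, lapply(fits, `[[`, "w"))
  colnames(W) <- classes
  structure(
    list(W = Matrix::Matrix(W, sparse = TRUE),
         b = stats::setNames(vapply(fits, `[[`, numeric(1), "b"), classes),
         classes = classes, C = C, vocabulary = vocabulary),
    class = "stance_model")
}

#' @export
print.stance_model <- function(x, ...) {
  cat(sprintf("<stance_model> classes %s | %d features | C = %g | %d nonzero coefs\n",
              paste(x$classes, collapse = "/"), nrow(x$W), x$C,
              sum(x$W != 0)))
  invisible(x)
}

#' Predict stance classes or per-class confidence scores
#'
#' Applies each binary model's logistic score and returns the argmax class;
#' exact ties resolve to the earliest class in the fixed order
#' anti < pro < neutral.
#'
#' @param object A [train_stance()] model.
#' @param newx Feature matrix with width equal to the model's feature count.
#' @param type `"class"` (default) or `"prob"` for the n x k score matrix.
#' @param ... Unused.
#' @return Character vector of classes, or a score matrix.
#' @export
predict.stance_model <- function(object, newx, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (ncol(newx) != nrow(object$W))
    stopf("feature width %d does not match model width %d",
          ncol(newx), nrow(object$W))
  z <- as.matrix(newx %*% object$W)
  scores <- stats::plogis(sweep(z, 2L, object$b, `+`))
  colnames(scores) <- object$classes
  if (type == "prob") return(scores)
  object$classes[apply(scores, 1L, which.max)]
}

#' Stratified k-fold cross-validation of the stance classifier
#'
#' Rows are split into k stratified folds by a seeded within-class shuffle.
#' For each fold the training portion is oversampled to class balance, a
#' one-vs-all model is trained, and the held-out fold is predicted; one
#' pooled confusion matrix is accumulated over all folds. By default the
#' vocabulary is built once on the full corpus before splitting (the
#' preprocess-then-split order); `vocabulary_mode = "fold"` rebuilds it on
#' each fold's training portion instead.
#'
#' @param tokens List of token vectors ([tokenize_corpus()]).
#' @param labels Class label per document; every class needs >= k rows.
#' @param k Number of folds (default 10).
#' @param C Inverse regularization strength (default 1).
#' @param seed RNG seed for fold assignment and per-fold oversampling.
#' @param vocabulary_mode `"full"` (default) or `"fold"`.
#' @return An `evaluation_report` (see [compute_metrics()]) with the pooled
#'   confusion matrix; also carries `k` and `C`.
#' @export
cross_validate <- function(tokens, labels, k = 10L, C = 1, seed = 1L,
                           vocabulary_mode = c("full", "fold")) {
  vocabulary_mode <- match.arg(vocabulary_mode)
  labels <- as.character(labels)
  if (length(tokens) != length(labels))
    stopf("tokens and labels lengths differ")
  counts <- table(labels)
  if (any(counts < k))
    stopf("class '%s' has %d examples, fewer than k = %d",
          names(counts)[which.min(counts)], min(counts), k)
  classes <- canonical_classes(labels)

  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      ids <- sample(which(labels == cl))
      folds[ids] <- rep_len(seq_len(k), length(ids))
    }
  })

  if (vocabulary_mode == "full") {
    vocab <- build_vocabulary(tokens)
    X <- vectorize(tokens, vocab)
  }
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(actual = classes, predicted = classes))
  for (fold in seq_len(k)) {
    test <- folds == fold
    if (vocabulary_mode == "fold") {
      vocab <- build_vocabulary(tokens[!test])
      X <- vectorize(tokens, vocab)
    }
    model <- train_stance(X[!test, , drop = FALSE], labels[!test], C = C,
                          seed = seed + fold, vocabulary = vocab)
    pred <- predict(model, X[test, , drop = FALSE])
    confusion <- confusion + as.matrix(table(
      factor(labels[test], levels = classes),
      factor(pred, levels = classes)))
  }
  report <- compute_metrics(confusion)
  report$k <- k
  report$C <- C
  report
}

#' Serialize a stance model to portable JSON
#'
#' Stores class order, vocabulary (tokens and kinds), per-class sparse
#' coefficients (index/value pairs), intercepts and C.
#'
#' @param model A [train_stance()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stance_model <- function(model, path) {
  stopifnot(inherits(model, "stance_model"))
  coefs <- lapply(model$classes, function(cl) {
    w <- model$W[, cl]
    nz <- which(w != 0)
    list(index = nz, value = unname(w[nz]))
  })
  names(coefs) <- model$classes
  obj <- list(
    classes = model$classes,
    n_features = nrow(model$W),
    C = model$C,
    intercepts = as.list(model$b),
    coefficients = coefs,
    vocabulary = if (!is.null(model$vocabulary))
      list(tokens = model$vocabulary$tokens, kind = model$vocabulary$kind)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized stance model
#'
#' @param path JSON file written by [write_stance_model()].
#' @return A `stance_model`.
#' @export
read_stance_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$n_features
  classes <- obj$classes
  W <- Matrix::Matrix(0, p, length(classes), sparse = TRUE,
                      dimnames = list(NULL, classes))
  for (cl in classes) {
    co <- obj$coefficients[[cl]]
    if (length(co$index)) W[co$index, cl] <- co$value
  }
  vocab <- NULL
  if (!is.null(obj$vocabulary)) {
    vocab <- structure(list(tokens = obj$vocabulary$tokens,
                            kind = obj$vocabulary$kind,
                            size = length(obj$vocabulary$tokens)),
                       class = "vocabulary")
  }
  structure(list(W = W, b = unlist(obj$intercepts)[classes],
                 classes = classes, C = obj$C, vocabulary = vocab),
            class = "stance_model")
}
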