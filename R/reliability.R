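# Inter-rater reliability machinery for the two-phase qualitative coding:
# agreement contingency tables, unweighted Cohen kappa (two coders), and
# coding-record structures including the four message-frame categories.

#' The four message-frame categories
#'
#' The four-part framing taxonomy used in the deductive coding phase:
#' defining the problem, interpreting its cause, evaluating it morally,
#' and recommending a remedy.
#'
#' @return Character vector of the four category names.
#' @export
entman_frames <- function() {
  c("problem_definition", "causal_interpretation",
    "moral_evaluation", "remedy_recommendation")
}

#' Build a coding-record table
#'
#' One row per (item, coder, phase) with the assigned code; the triple must
#' be unique.
#'
#' @param item_id,coder_id Character identifiers.
#' @param phase `"topic"` or `"frame"`.
#' @param code Assigned code (stance label, topic label, or a frame
#'   category; frame-phase codes must be one of [entman_frames()]).
#' @return Tibble of coding records.
#' @export
coding_records <- function(item_id, coder_id, phase, code) {
  phase <- match.arg(phase, c("topic", "frame"), several.ok = TRUE)
  df <- tibble::tibble(item_id = as.character(item_id),
                       coder_id = as.character(coder_id),
                       phase = phase, code = as.character(code))
  key <- paste(df$item_id, df$coder_id, df$phase, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (item_id, coder_id, phase) coding record")
  bad <- df$phase == "frame" & !df$code %in% entman_frames()
  if (any(bad))
    stopf("frame-phase codes must be one of: %s",
          paste(entman_frames(), collapse = ", "))
  df
}

#' Contingency table of two coders' codes
#'
#' Entry (i, j) counts items coded category i by coder A and category j by
#' coder B, over a fixed shared category order (sorted union by default).
#'
#' @param a,b Codes per item. Either named vectors (aligned by item name)
#'   or equal-length vectors coding the same items in the same order.
#' @param categories Optional fixed category order; defaults to the sorted
#'   union of observed codes.
#' @return Square integer matrix with shared dimnames.
#' @export
agreement_table <- function(a, b, categories = NULL) {
  if (length(a) == 0L || length(b) == 0L)
    stopf("agreement_table() needs a non-empty item set")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stopf("coders rated different item sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stopf("coders rated different numbers of items")
  }
  a <- as.character(a); b <- as.character(b)
  if (is.null(categories)) categories <- lex_sort(unique(c(a, b)))
  if (!all(c(a, b) %in% categories)) stopf("codes outside the category set")
  tab <- table(factor(a, levels = categories), factor(b, levels = categories))
  m <- matrix(as.integer(tab), nrow = length(categories),
              dimnames = list(coder_a = categories, coder_b = categories))
  m
}

#' Cohen kappa from a contingency table
#'
#' Chance-corrected agreement between two coders:
#' `p_o = trace / total`, `p_e = sum_c rowsum_c * colsum_c / total^2`,
#' `kappa = (p_o - p_e) / (1 - p_e)` (1 in the degenerate `p_e = 1`,
#' `p_o = 1` case).
#'
#' @param table Square nonnegative contingency matrix with total >= 1, or
#'   a pair of code vectors via [agreement_table()].
#' @return Object of class `kappa_result`: `p_o`, `p_e`, `kappa`, `n`.
#' @export
cohen_kappa <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stopf("contingency table must be square")
  if (any(m < 0)) stopf("contingency table entries must be nonnegative")
  n <- sum(m)
  if (n < 1) stopf("contingency table must hold at least one item")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (p_e >= 1) {
    if (p_o == 1) 1 else stopf("degenerate table: p_e = 1 with p_o < 1")
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Read coding records from CSV
#'
#' @param path CSV with columns `item_id`, `coder_id`, `phase`, `code`.
#' @return Tibble of validated coding records.
#' @export
read_coding_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "coder_id", "phase", "code")
  if (!all(need %in% names(df)))
    stopf("coding records need columns %s", paste(need, collapse = ", "))
  coding_records(df$item_id, df$coder_id, df$phase, df$code)
}

#' Kappa between two coders from coding records
#'
#' @param records Coding-record tibble ([coding_records()]).
#' @param coder_a,coder_b Coder ids to compare.
#' @param phase Coding phase to restrict to (`"topic"` or `"frame"`).
#' @return A `kappa_result`.
#' @export
coder_agreement <- function(records, coder_a, coder_b, phase = "topic") {
  ra <- records[records$coder_id == coder_a & records$phase == phase, ]
  rb <- records[records$coder_id == coder_b & records$phase == phase, ]
  if (nrow(ra) == 0L || nrow(rb) == 0L)
    stopf("no records for the requested coders/phase")
  a <- stats::setNames(ra$code, ra$item_id)
  b <- stats::setNames(rb$code, rb$item_id)
  cohen_kappa(agreement_table(a, b))
}
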