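#' Expert-by-condition score matrix
#'
#' Container for the raw output of a Delphi scoring panel: an integer matrix
#' of ordinal equity scores in \{1, 2, 3, 4\}, one row per expert and one
#' column per disease condition. A score of 4 marks a condition predominantly
#' affecting the poor and rural residents; 1 marks one at least as prevalent
#' among the better off. Missing scores (an expert who did not rate a
#' condition) are `NA`.
#'
#' Validation enforces: every non-missing score is an integer in 1..4;
#' expert and condition ids are unique, non-empty strings; every condition
#' has at least one non-missing score.
#'
#' @param scores integer (or whole-number) matrix, experts in rows,
#'   conditions in columns; `NA` allowed.
#' @param expert_ids character vector of unique expert identifiers,
#'   length `nrow(scores)`. Defaults to existing rownames.
#' @param condition_ids character vector of unique condition identifiers,
#'   length `ncol(scores)`. Defaults to existing colnames.
#'
#' @return A `score_matrix`: an integer matrix with `expert_ids` as rownames
#'   and `condition_ids` as colnames.
#' @export
#' @examples
#' m <- score_matrix(rbind(c(4, 3), c(2, 1)),
#'                   expert_ids = c("E1", "E2"),
#'                   condition_ids = c("C1", "C2"))
#' mean_scores(m)
score_matrix <- function(scores, expert_ids = rownames(scores),
                         condition_ids = colnames(scores)) {
  if (!is.matrix(scores)) {
    abort_schema("`scores` must be a matrix (experts x conditions).")
  }
  if (is.null(expert_ids) || is.null(condition_ids)) {
    abort_schema("expert_ids and condition_ids are required (dimnames or arguments).")
  }
  expert_ids <- as.character(expert_ids)
  condition_ids <- as.character(condition_ids)
  check_ids(expert_ids, "expert_ids")
  check_ids(condition_ids, "condition_ids")
  if (length(expert_ids) != nrow(scores) || length(condition_ids) != ncol(scores)) {
    abort_schema("id lengths must match the score matrix dimensions.")
  }

  vals <- scores[!is.na(scores)]
  bad <- !is.numeric(vals) | vals != round(vals) | vals < 1 | vals > 4
  if (any(bad)) {
    idx <- which(!is.na(scores) & (scores != round(scores) | scores < 1 | scores > 4),
                 arr.ind = TRUE)[1, ]
    abort_schema(sprintf(
      "score %s at expert '%s', condition '%s' is not an integer in 1..4",
      format(scores[idx[1], idx[2]]), expert_ids[idx[1]], condition_ids[idx[2]]))
  }
  all_missing <- colSums(!is.na(scores)) == 0
  if (any(all_missing)) {
    abort_schema(sprintf("condition '%s' has no non-missing score",
                         condition_ids[which(all_missing)[1]]))
  }

  out <- matrix(as.integer(scores), nrow = nrow(scores),
                dimnames = list(expert_ids, condition_ids))
  class(out) <- c("score_matrix", class(out))
  out
}

check_ids <- function(ids, what) {
  if (length(ids) == 0 || anyNA(ids) || any(!nzchar(ids))) {
    abort_schema(sprintf("%s must be non-empty strings", what))
  }
  if (anyDuplicated(ids)) {
    abort_schema(sprintf("duplicate id '%s' in %s", ids[duplicated(ids)][1], what))
  }
  invisible(ids)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d experts x %d conditions, %d missing cell(s)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Test for score_matrix objects
#' @param x object to test.
#' @return `TRUE` if `x` is a `score_matrix`.
#' @export
is_score_matrix <- function(x) inherits(x, "score_matrix")
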