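#' Per-condition average equity scores
#'
#' Computes, for every condition, the mean of the non-missing expert scores
#' — the panel's average equity score — together with the number of raters
#' and the full 1..4 score distribution. Condition order is preserved.
#'
#' @param matrix a [score_matrix()].
#' @return A tibble with one row per condition: `condition_id`,
#'   `mean_score`, `n_raters`, and counts `n1`..`n4`.
#' @export
mean_scores <- function(matrix) {
  stopifnot(is_score_matrix(matrix))
  n_raters <- colSums(!is.na(matrix))
  if (any(n_raters == 0)) {
    abort_domain(sprintf("condition '%s' has no raters",
                         colnames(matrix)[which(n_raters == 0)[1]]))
  }
  counts <- vapply(1:4, function(k) colSums(matrix == k, na.rm = TRUE),
                   numeric(ncol(matrix)))
  if (ncol(matrix) == 1) counts <- matrix(counts, nrow = 1)
  tibble::tibble(
    condition_id = colnames(matrix),
    mean_score = unname(colMeans(matrix, na.rm = TRUE)),
    n_raters = as.integer(n_raters),
    n1 = as.integer(counts[, 1]),
    n2 = as.integer(counts[, 2]),
    n3 = as.integer(counts[, 3]),
    n4 = as.integer(counts[, 4])
  )
}

#' Score distribution for one condition
#'
#' Counts how many experts gave each score 1..4 to a condition (the bar
#' heights of a per-condition score histogram). Missing scores are excluded.
#'
#' @param matrix a [score_matrix()].
#' @param condition_id a single condition identifier present in `matrix`.
#' @return Named integer vector of length 4 (`"1"`..`"4"`) summing to the
#'   number of raters.
#' @export
score_distribution <- function(matrix, condition_id) {
  stopifnot(is_score_matrix(matrix))
  if (!condition_id %in% colnames(matrix)) {
    abort_lookup(sprintf("unknown condition id '%s'", condition_id))
  }
  col <- matrix[, condition_id]
  out <- vapply(1:4, function(k) sum(col == k, na.rm = TRUE), integer(1))
  names(out) <- as.character(1:4)
  out
}

#' GBD level-2 group averages
#'
#' Averages the per-condition mean scores within each GBD level-2 category:
#' an unweighted mean of condition means, one row per category.
#'
#' @param summaries tibble from [mean_scores()].
#' @param meta condition metadata tibble (see [read_condition_meta()]).
#' @return A tibble with `gbd_level2`, `mean_score`, `n_conditions`, ordered
#'   by descending group mean.
#' @export
group_means <- function(summaries, meta) {
  missing_meta <- setdiff(summaries$condition_id, meta$condition_id)
  if (length(missing_meta)) {
    abort_referential(sprintf("condition(s) missing from metadata: %s",
                              paste(utils::head(missing_meta, 5), collapse = ", ")))
  }
  dplyr::left_join(summaries, meta[, c("condition_id", "gbd_level2")],
                   by = "condition_id") |>
    dplyr::group_by(.data$gbd_level2) |>
    dplyr::summarise(mean_score = mean(.data$mean_score),
                     n_conditions = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_score))
}
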