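#' Categorize conditions into high / medium / low equity groups
#'
#' Sorts conditions by their average equity score in descending order and
#' splits the sorted list into three contiguous blocks — high, medium, low —
#' with sizes as equal as possible (remainder conditions go to the earlier
#' blocks). Conditions with tied means never straddle a block boundary:
#' among all boundary placements that keep ties together, the one with block
#' sizes closest to equal is chosen, boundaries moving down on remaining
#' ties so a tied run joins the higher category. With `cutpoints` supplied,
#' score thresholds are used instead of tertiles.
#'
#' @param summaries tibble with `condition_id` and `mean_score`
#'   (e.g. from [mean_scores()]).
#' @param cutpoints optional numeric length-2 vector
#'   `c(high_min, medium_min)`: a condition is `high` when its mean is
#'   `>= high_min`, `medium` when `>= medium_min`, else `low`.
#' @return The input tibble, in input order, with a `category` column
#'   (`"high"`, `"medium"` or `"low"`).
#' @export
categorize <- function(summaries, cutpoints = NULL) {
  n <- nrow(summaries)
  if (n < 3) abort_domain("categorization needs at least 3 conditions")
  m <- summaries$mean_score

  if (!is.null(cutpoints)) {
    if (length(cutpoints) != 2 || diff(cutpoints) >= 0) {
      abort_config("cutpoints must be two decreasing score thresholds c(high_min, medium_min)")
    }
    cat <- ifelse(m >= cutpoints[1], "high",
                  ifelse(m >= cutpoints[2], "medium", "low"))
    return(tibble::tibble(summaries, category = cat))
  }

  ord <- order(-m)                       # stable: ties keep input order
  sorted <- m[ord]
  # boundary b = number of sorted conditions at or above it; valid positions
  # are those that do not split a run of tied means
  valid <- c(0, which(diff(sorted) != 0), n)
  base <- n %/% 3
  rem <- n %% 3
  ideal <- c(base + (rem >= 1), base + (rem >= 2), base)

  best <- NULL
  for (b1 in valid) {
    for (b2 in valid[valid >= b1]) {
      sizes <- c(b1, b2 - b1, n - b2)
      # minimize deviation from equal sizes; then move boundaries down
      # (tied runs join the higher category)
      key <- c(sum(abs(sizes - ideal)), -b1, -b2)
      if (is.null(best) || lex_less(key, best$key)) {
        best <- list(key = key, b = c(b1, b2))
      }
    }
  }
  cat_sorted <- rep(c("high", "medium", "low"),
                    times = c(best$b[1], best$b[2] - best$b[1], n - best$b[2]))
  cat <- character(n)
  cat[ord] <- cat_sorted
  tibble::tibble(summaries, category = cat)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Maternal/child-health score reassignment
#'
#' Conditions predominantly affecting women or children (MCH flag) that the
#' panel placed in the medium or low category are lifted to the lowest
#' average score found in the high category, so that maternal and childhood
#' conditions rank at least at the bottom of the high group. High-category
#' and non-MCH conditions are unchanged; the reassignment never lowers a
#' score.
#'
#' @param categorized tibble from [categorize()] (`condition_id`,
#'   `mean_score`, `category`).
#' @param meta condition metadata with `condition_id` and `mch_flag`.
#' @return The input tibble with `mch_flag` and `post_mch_score` columns.
#' @export
mch_reassign <- function(categorized, meta) {
  missing_meta <- setdiff(categorized$condition_id, meta$condition_id)
  if (length(missing_meta)) {
    abort_referential(sprintf("condition(s) missing from metadata: %s",
                              paste(utils::head(missing_meta, 5), collapse = ", ")))
  }
  high <- categorized$mean_score[categorized$category == "high"]
  if (length(high) == 0) abort_domain("high category is empty; cannot reassign MCH conditions")
  floor_score <- min(high)

  out <- dplyr::left_join(categorized, meta[, c("condition_id", "mch_flag")],
                          by = "condition_id")
  lift <- out$mch_flag & out$category %in% c("medium", "low")
  out$post_mch_score <- ifelse(lift, pmax(out$mean_score, floor_score), out$mean_score)
  out
}

#' Standardize scores to multiplicative equity weights
#'
#' Affine min-max rescaling of the (post-reassignment) scores onto a target
#' range, by default \[1, 2\]: `w = 1 + (s - min) / (max - min)`. The lowest
#' score maps to 1 (no extra weight) and the highest to 2 (health gains
#' count double), preserving order. If all scores are identical there is no
#' equity differentiation: every weight is set to the range minimum and a
#' warning is raised.
#'
#' @param scores numeric vector of scores.
#' @param range numeric length-2 target interval, default `c(1, 2)`.
#' @return Numeric vector of equity weights in `range`.
#' @export
standardize_weights <- function(scores, range = c(1, 2)) {
  if (length(range) != 2 || diff(range) <= 0) {
    abort_config("range must be an increasing length-2 interval")
  }
  lo <- min(scores)
  hi <- max(scores)
  if (hi == lo) {
    warn_degenerate("all scores identical: no equity differentiation, every weight set to the range minimum")
    return(rep(range[1], length(scores)))
  }
  range[1] + (scores - lo) / (hi - lo) * diff(range)
}

#' Build the full equity table
#'
#' Composes the equity-scoring pipeline on a score matrix: per-condition
#' mean scores, high/medium/low categorization, maternal/child reassignment,
#' then min-max standardization of the post-reassignment scores to equity
#' weights.
#'
#' @param matrix a [score_matrix()].
#' @param meta condition metadata tibble.
#' @param cutpoints optional score thresholds passed to [categorize()].
#' @param range target weight range passed to [standardize_weights()].
#' @return A tibble with one row per condition: `condition_id`, `name`,
#'   `raw_mean`, `n_raters`, `category`, `mch_flag`, `post_mch_score`,
#'   `equity_weight`.
#' @export
build_equity_table <- function(matrix, meta, cutpoints = NULL, range = c(1, 2)) {
  summaries <- mean_scores(matrix)
  staged <- mch_reassign(categorize(summaries[, c("condition_id", "mean_score")],
                                    cutpoints = cutpoints),
                         meta)
  tibble::tibble(
    condition_id = staged$condition_id,
    name = meta$name[match(staged$condition_id, meta$condition_id)],
    raw_mean = staged$mean_score,
    n_raters = summaries$n_raters,
    category = staged$category,
    mch_flag = staged$mch_flag,
    post_mch_score = staged$post_mch_score,
    equity_weight = standardize_weights(staged$post_mch_score, range = range)
  )
}

#' Write an equity table
#' @param equity tibble from [build_equity_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_equity_table <- function(equity, path) {
  readr::write_csv(equity, path, na = "")
  invisible(path)
}
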