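#' Map condition equity weights onto interventions
#'
#' An intervention linked to a single condition inherits that condition's
#' equity weight; an intervention spanning several conditions receives the
#' unweighted mean (or max / min) of the linked weights.
#'
#' @param interventions tibble from [read_interventions()] /
#'   [gen_interventions()].
#' @param equity tibble from [build_equity_table()] (needs `condition_id`
#'   and `equity_weight`).
#' @param mode aggregation over linked conditions: `"mean"` (default),
#'   `"max"` or `"min"`.
#' @return The intervention tibble with an `equity_weight` column.
#' @export
intervention_equity <- function(interventions, equity,
                                mode = c("mean", "max", "min")) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(unlist(interventions$condition_ids)), equity$condition_id)
  if (length(unknown)) {
    abort_referential(sprintf("no equity weight for condition(s): %s",
                              paste(utils::head(unknown, 5), collapse = ", ")))
  }
  f <- switch(mode, mean = mean, max = max, min = min)
  w <- vapply(interventions$condition_ids, function(ids) {
    f(equity$equity_weight[match(ids, equity$condition_id)])
  }, numeric(1))
  tibble::tibble(interventions, equity_weight = w)
}

#' Equity-adjust a cost-effectiveness ratio
#'
#' Multiplies the health-benefit denominator of a cost-effectiveness ratio
#' by the equity weight, i.e. divides the CER by the weight: with a weight
#' of 2 the CER halves, with a weight of 1 it is unchanged.
#'
#' @param cer positive cost-effectiveness ratio(s) (cost per unit benefit).
#' @param equity_weight equity weight(s) in \[1, 2\].
#' @return `cer / equity_weight`, vectorized.
#' @export
#' @examples
#' adjust_cer(100, 2)   # 50
#' adjust_cer(100, 1)   # 100
adjust_cer <- function(cer, equity_weight) {
  if (any(!is.finite(cer)) || any(cer <= 0)) {
    abort_domain("cer must be positive")
  }
  if (any(!is.finite(equity_weight)) ||
      any(equity_weight < 1) || any(equity_weight > 2)) {
    abort_domain("equity_weight must lie in [1, 2]")
  }
  cer / equity_weight
}

#' Build a league table with both rankings
#'
#' Ranks interventions ascending by unadjusted CER and, separately,
#' ascending by equity-adjusted CER (rank 1 = most cost-effective). Ties
#' are broken deterministically by intervention id, lexicographically.
#'
#' @param weighted tibble from [intervention_equity()]: `intervention_id`,
#'   `name`, `cer`, `equity_weight`.
#' @return A tibble with `intervention_id`, `name`, `cer`, `equity_weight`,
#'   `adjusted_cer`, `rank_cer`, `rank_adjusted`, ordered by `rank_cer`.
#' @export
build_league <- function(weighted) {
  if (anyDuplicated(weighted$intervention_id)) {
    abort_schema(sprintf("duplicate intervention id '%s'",
                         weighted$intervention_id[duplicated(weighted$intervention_id)][1]))
  }
  adj <- adjust_cer(weighted$cer, weighted$equity_weight)
  out <- tibble::tibble(
    intervention_id = weighted$intervention_id,
    name = weighted$name,
    cer = weighted$cer,
    equity_weight = weighted$equity_weight,
    adjusted_cer = adj,
    rank_cer = rank_by(weighted$cer, weighted$intervention_id),
    rank_adjusted = rank_by(adj, weighted$intervention_id)
  )
  dplyr::arrange(out, .data$rank_cer)
}

# rank 1 = smallest value; ties broken lexicographically on id
rank_by <- function(values, ids) {
  ord <- order(values, ids, method = "radix")
  rk <- integer(length(values))
  rk[ord] <- seq_along(values)
  rk
}

#' Compare CER and equity-adjusted rankings
#'
#' Contrasts the two league-table orderings: which interventions enter and
#' exit the top-k when ranking by adjusted instead of unadjusted CER, the
#' per-intervention signed rank change, and the Kendall tau-b rank
#' correlation between the two rank vectors.
#'
#' @param league tibble from [build_league()].
#' @param k size of the head of the league table to compare (default 30).
#' @return An object of class `rank_comparison`: a list with `k`,
#'   `entered_top_k`, `exited_top_k`, `rank_delta` (tibble with
#'   `intervention_id`, `rank_cer`, `rank_adjusted`, `delta`) and
#'   `rank_correlation`.
#' @export
compare_rankings <- function(league, k = 30) {
  n <- nrow(league)
  if (k < 1 || k > n) abort_domain(sprintf("k = %d outside 1..%d", k, n))
  top_cer <- league$intervention_id[league$rank_cer <= k]
  top_adj <- league$intervention_id[league$rank_adjusted <= k]
  delta <- tibble::tibble(
    intervention_id = league$intervention_id,
    rank_cer = league$rank_cer,
    rank_adjusted = league$rank_adjusted,
    delta = league$rank_cer - league$rank_adjusted
  )
  structure(list(
    k = k,
    entered_top_k = sort(setdiff(top_adj, top_cer)),
    exited_top_k = sort(setdiff(top_cer, top_adj)),
    rank_delta = delta,
    rank_correlation = stats::cor(league$rank_cer, league$rank_adjusted,
                                  method = "kendall")
  ), class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("<rank_comparison> top-%d: %d entered, %d exited; Kendall tau = %.3f\n",
              x$k, length(x$entered_top_k), length(x$exited_top_k),
              x$rank_correlation))
  invisible(x)
}

#' Write a league table
#' @param league tibble from [build_league()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_league <- function(league, path) {
  readr::write_csv(league, path, na = "")
  invisible(path)
}

#' Write a rank-comparison report
#'
#' One row per intervention with both ranks, the signed rank change, and a
#' `top_k_status` column (`entered`, `exited`, `stayed`, `outside`) at the
#' comparison's k.
#'
#' @param comparison object from [compare_rankings()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rank_comparison <- function(comparison, path) {
  d <- comparison$rank_delta
  status <- ifelse(d$intervention_id %in% comparison$entered_top_k, "entered",
            ifelse(d$intervention_id %in% comparison$exited_top_k, "exited",
            ifelse(d$rank_cer <= comparison$k, "stayed", "outside")))
  out <- tibble::tibble(d, top_k_status = status)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
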