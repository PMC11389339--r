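#' Pipeline run configuration
#'
#' Collects the paths and options of one end-to-end run: input CSVs
#' (score sheet, condition metadata, intervention/CER table), the
#' equity-scoring options, the league-table options, and the output
#' directory.
#'
#' @param scores path to the expert score sheet CSV.
#' @param meta path to the condition metadata CSV.
#' @param interventions path to the intervention/CER CSV.
#' @param out_dir output directory (created if needed).
#' @param orientation score-sheet orientation, see [read_score_sheet()].
#' @param cutpoints optional categorization thresholds, see [categorize()].
#' @param range equity-weight target range, default `c(1, 2)`.
#' @param multi_mode weight aggregation for multi-condition interventions,
#'   see [intervention_equity()].
#' @param top_k league-table head size for the rank comparison (default 30).
#' @return A list of class `run_config`.
#' @export
run_config <- function(scores, meta, interventions, out_dir,
                       orientation = "experts_as_rows",
                       cutpoints = NULL, range = c(1, 2),
                       multi_mode = "mean", top_k = 30) {
  if (top_k < 1) abort_config("top_k must be >= 1")
  structure(list(scores = scores, meta = meta, interventions = interventions,
                 out_dir = out_dir, orientation = orientation,
                 cutpoints = cutpoints, range = range,
                 multi_mode = multi_mode, top_k = as.integer(top_k)),
            class = "run_config")
}

#' Run the full equity-adjustment pipeline
#'
#' Reads the three input tables, computes per-condition and GBD level-2
#' score summaries, the equity table, the equity-adjusted league table and
#' the rank comparison, and writes six artifacts into `out_dir`:
#' `condition_summaries.csv`, `group_summaries.csv`, `equity_table.csv`,
#' `league_table.csv`, `rank_comparison.csv` and `manifest.json`. The
#' manifest (options echo, row counts, artifact list) is written even when
#' a stage fails, with the stage and error message recorded; the error is
#' then re-signalled with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (named paths) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c(condition_summaries = "condition_summaries.csv",
                       group_summaries = "group_summaries.csv",
                       equity_table = "equity_table.csv",
                       league_table = "league_table.csv",
                       rank_comparison = "rank_comparison.csv"))
  names(paths) <- c("condition_summaries", "group_summaries", "equity_table",
                    "league_table", "rank_comparison")
  manifest_path <- file.path(config$out_dir, "manifest.json")

  manifest <- list(
    package = "equileague",
    version = as.character(utils::packageVersion("equileague")),
    options = list(orientation = config$orientation,
                   cutpoints = config$cutpoints,
                   range = config$range,
                   multi_mode = config$multi_mode,
                   top_k = config$top_k),
    inputs = list(scores = config$scores, meta = config$meta,
                  interventions = config$interventions)
  )
  stage <- "read_inputs"
  result <- tryCatch({
    matrix <- read_score_sheet(config$scores, orientation = config$orientation)
    meta <- read_condition_meta(config$meta)
    interventions <- read_interventions(config$interventions, meta = meta)
    manifest$row_counts <- list(experts = nrow(matrix),
                                conditions = ncol(matrix),
                                interventions = nrow(interventions))

    stage <- "aggregation"
    summaries <- mean_scores(matrix)
    groups <- group_means(summaries, meta)

    stage <- "equity_scoring"
    equity <- build_equity_table(matrix, meta,
                                 cutpoints = config$cutpoints,
                                 range = config$range)

    stage <- "cea_league"
    weighted <- intervention_equity(interventions, equity, mode = config$multi_mode)
    league <- build_league(weighted)
    comparison <- compare_rankings(league, k = min(config$top_k, nrow(league)))

    stage <- "write_artifacts"
    readr::write_csv(summaries, paths[["condition_summaries"]], na = "")
    readr::write_csv(groups, paths[["group_summaries"]], na = "")
    write_equity_table(equity, paths[["equity_table"]])
    write_league(league, paths[["league_table"]])
    write_rank_comparison(comparison, paths[["rank_comparison"]])
    list(ok = TRUE)
  }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))

  if (result$ok) {
    manifest$status <- "ok"
    manifest$artifacts <- as.list(paths)
  } else {
    manifest$status <- "error"
    manifest$failed_stage <- stage
    manifest$error <- result$error
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  if (!result$ok) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage, result$error),
                 class = "equileague_pipeline_error")
  }
  invisible(list(status = 0L,
                 artifacts = c(paths, manifest = manifest_path),
                 manifest = manifest))
}

#' Text report of ranking changes
#'
#' Human-readable summary of a league table: the top-k interventions by
#' unadjusted and by equity-adjusted CER, and which interventions enter or
#' leave the top-k once equity weights are applied. When the two orderings
#' agree it states that no ranking changes occurred.
#'
#' @param league a league tibble from [build_league()], or a path to a
#'   league-table CSV written by [write_league()].
#' @param k head size (default 30, capped at the table size by the caller).
#' @return Character vector of report lines, invisibly; also printed.
#' @export
league_report <- function(league, k = 30) {
  if (is.character(league)) {
    league <- readr::read_csv(league, col_types = readr::cols(), progress = FALSE)
  }
  cmp <- compare_rankings(league, k = k)
  fmt_side <- function(rank_col) {
    side <- league[order(league[[rank_col]]), ][seq_len(k), ]
    sprintf("  %2d. %s (CER %.2f, adjusted %.2f, weight %.3f)",
            seq_len(k), side$intervention_id, side$cer, side$adjusted_cer,
            side$equity_weight)
  }
  lines <- c(
    sprintf("League table: %d interventions, top %d compared", nrow(league), k),
    sprintf("Kendall tau between rankings: %.4f", cmp$rank_correlation),
    "", sprintf("Top %d by unadjusted CER:", k), fmt_side("rank_cer"),
    "", sprintf("Top %d by equity-adjusted CER:", k), fmt_side("rank_adjusted"),
    "")
  if (length(cmp$entered_top_k) == 0) {
    lines <- c(lines, "No ranking changes in the top list.")
  } else {
    lines <- c(lines,
               sprintf("Entered top %d after equity adjustment: %s", k,
                       paste(cmp$entered_top_k, collapse = ", ")),
               sprintf("Dropped from top %d after equity adjustment: %s", k,
                       paste(cmp$exited_top_k, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
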