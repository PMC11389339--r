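#' Read an expert score sheet
#'
#' Reads a delimited score sheet (CSV, UTF-8, header row) into a
#' [score_matrix()]. By default experts are rows: the first column holds
#' expert ids and the remaining column names are condition ids. Set
#' `orientation = "conditions_as_rows"` for the transposed layout. Empty
#' cells are kept as missing scores.
#'
#' @param path path to a CSV file.
#' @param orientation `"experts_as_rows"` (default) or `"conditions_as_rows"`.
#' @return A validated [score_matrix()].
#' @export
read_score_sheet <- function(path,
                             orientation = c("experts_as_rows", "conditions_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) abort_schema("score sheet needs an id column plus at least one score column")

  row_ids <- as.character(df[[1]])
  col_ids <- names(df)[-1]
  cells <- as.matrix(df[-1])

  scores <- matrix(NA_integer_, nrow = nrow(cells), ncol = ncol(cells))
  for (j in seq_len(ncol(cells))) {
    for (i in seq_len(nrow(cells))) {
      v <- cells[i, j]
      if (is.na(v) || !nzchar(trimws(v))) next
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num) || num != round(num) || num < 1 || num > 4) {
        abort_schema(sprintf("cell '%s' at row id '%s', column '%s' is not an integer in 1..4",
                             v, row_ids[i], col_ids[j]))
      }
      scores[i, j] <- as.integer(num)
    }
  }
  if (orientation == "conditions_as_rows") {
    score_matrix(t(scores), expert_ids = col_ids, condition_ids = row_ids)
  } else {
    score_matrix(scores, expert_ids = row_ids, condition_ids = col_ids)
  }
}

#' Write an expert score sheet
#'
#' Round-trip companion of [read_score_sheet()]: writes experts as rows with
#' an `expert_id` first column; missing scores become empty cells.
#'
#' @param x a [score_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_sheet <- function(x, path) {
  stopifnot(is_score_matrix(x))
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- tibble::add_column(df, expert_id = rownames(x), .before = 1)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read condition metadata
#'
#' Reads the per-condition metadata table: `condition_id`, `name`,
#' `gbd_level2` (GBD level-2 cause category) and `mch_flag` (whether the
#' condition predominantly affects women of reproductive age or under-five
#' children). The flag accepts 0/1, true/false and yes/no in any case.
#'
#' @param path path to a CSV file.
#' @return A tibble with columns `condition_id`, `name`, `gbd_level2`,
#'   `mch_flag` (logical).
#' @export
read_condition_meta <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("condition_id", "name", "gbd_level2", "mch_flag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_schema(sprintf("condition metadata is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  check_ids(df$condition_id, "condition_id")
  if (any(is.na(df$gbd_level2) | !nzchar(df$gbd_level2))) {
    abort_schema("gbd_level2 must be non-empty for every condition")
  }
  tibble::tibble(
    condition_id = df$condition_id,
    name = df$name,
    gbd_level2 = df$gbd_level2,
    mch_flag = parse_flag(df$mch_flag, df$condition_id)
  )
}

parse_flag <- function(x, ids) {
  lut <- c("0" = FALSE, "1" = TRUE, "true" = TRUE, "false" = FALSE,
           "yes" = TRUE, "no" = FALSE)
  key <- tolower(trimws(x))
  out <- lut[key]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort_schema(sprintf("mch_flag '%s' for condition '%s' is not one of 0/1/true/false/yes/no",
                         x[bad], ids[bad]))
  }
  unname(out)
}

#' Write condition metadata
#' @param meta tibble as returned by [read_condition_meta()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_condition_meta <- function(meta, path) {
  out <- meta
  out$mch_flag <- ifelse(meta$mch_flag, "true", "false")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read an intervention / cost-effectiveness table
#'
#' Reads interventions with their linked condition(s) and unadjusted
#' cost-effectiveness ratio (CER, cost per unit health benefit, e.g. US$ per
#' DALY averted). `condition_ids` is a `;`-separated list inside one CSV
#' field. CERs must be strictly positive; when `meta` is supplied every
#' referenced condition must exist in it.
#'
#' @param path path to a CSV file with columns `intervention_id`, `name`,
#'   `condition_ids`, `cer`.
#' @param meta optional condition metadata tibble for referential checks.
#' @return A tibble with `intervention_id`, `name`, `condition_ids`
#'   (list-column of character vectors), `cer`.
#' @export
read_interventions <- function(path, meta = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("intervention_id", "name", "condition_ids", "cer")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_schema(sprintf("intervention table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  check_ids(df$intervention_id, "intervention_id")
  cer <- suppressWarnings(as.numeric(df$cer))
  bad <- is.na(cer) | cer <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    abort_schema(sprintf("cer '%s' for intervention '%s' is not a positive number",
                         df$cer[i], df$intervention_id[i]))
  }
  cond_lists <- lapply(strsplit(ifelse(is.na(df$condition_ids), "", df$condition_ids), ";",
                                fixed = TRUE),
                       function(v) trimws(v[nzchar(trimws(v))]))
  empty <- lengths(cond_lists) == 0
  if (any(empty)) {
    abort_schema(sprintf("intervention '%s' has an empty condition list",
                         df$intervention_id[which(empty)[1]]))
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(unlist(cond_lists)), meta$condition_id)
    if (length(unknown)) {
      abort_referential(sprintf("intervention table references unknown condition(s): %s",
                                paste(unknown, collapse = ", ")))
    }
  }
  tibble::tibble(
    intervention_id = df$intervention_id,
    name = df$name,
    condition_ids = cond_lists,
    cer = cer
  )
}

#' Write an intervention table
#' @param interventions tibble as returned by [read_interventions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_interventions <- function(interventions, path) {
  out <- tibble::tibble(
    intervention_id = interventions$intervention_id,
    name = interventions$name,
    condition_ids = vapply(interventions$condition_ids, paste, "", collapse = ";"),
    cer = interventions$cer
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
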