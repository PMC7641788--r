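#' Read a per-item food-diary table
#'
#' One row per recorded food item. Required columns: `participant_id`,
#' `phase` (T1/T2), `day` (integer >= 1), `item_label`, `portion_g`, and
#' sixteen nutrient columns named `ref_<nutrient>` / `app_<nutrient>` for
#' every nutrient in [nutrient_keys()]. Reference values must be complete;
#' app values may be blank, which is read as `NA` and means the app
#' database carried no value for that nutrient (distinct from zero).
#'
#' @param path Path to a UTF-8 CSV with '.' as decimal separator.
#' @return A tibble of food entries, row order preserved.
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(diary_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("diary table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, diary_columns()]
  raw$participant_id <- as.character(raw$participant_id)
  raw$item_label <- as.character(raw$item_label)
  for (col in c("day", "portion_g", ref_cols(), app_cols())) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  validate_diary(tibble::as_tibble(raw))
}

#' Write food entries back to CSV
#'
#' Inverse of [read_diary_csv()]: `NA` app values are written as blank
#' cells so that a write/read round trip preserves MISSING markers.
#'
#' @param entries Tibble of food entries.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(entries, path) {
  entries <- validate_diary(entries)
  utils::write.csv(entries, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @keywords internal
validate_diary <- function(entries) {
  entries <- tibble::as_tibble(entries)
  missing_cols <- setdiff(diary_columns(), names(entries))
  if (length(missing_cols) > 0) {
    stop("diary table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_phase <- !entries$phase %in% c("T1", "T2")
  if (any(bad_phase)) {
    stop("invalid phase (expected T1 or T2) in row(s): ",
         paste(utils::head(which(bad_phase), 5), collapse = ", "))
  }
  for (col in ref_cols()) {
    if (anyNA(entries[[col]])) {
      stop("reference values must be complete; blank '", col,
           "' in row(s): ",
           paste(utils::head(which(is.na(entries[[col]])), 5), collapse = ", "))
    }
  }
  for (col in c("portion_g", ref_cols(), app_cols())) {
    neg <- which(!is.na(entries[[col]]) & entries[[col]] < 0)
    if (length(neg) > 0) {
      stop("negative amount in column '", col, "', row(s): ",
           paste(utils::head(neg, 5), collapse = ", "))
    }
  }
  if (any(!is.na(entries$day) & entries$day < 1)) stop("day index must be >= 1")
  entries
}

#' Aggregate food entries to per-participant mean daily intakes
#'
#' Each participant's entries for one record phase are summed per nutrient
#' and divided by the number of *distinct* days observed for that
#' participant (a diary may legitimately cover fewer than 4 days). App
#' values recorded as `NA` (the app database had no entry) contribute 0 to
#' the sums, mirroring how incomplete database rows deflate app-side
#' totals.
#'
#' @param entries Tibble of food entries (see [read_diary_csv()]).
#' @param phase `"T1"` or `"T2"`.
#' @return A long tibble with one row per participant x nutrient:
#'   `participant_id`, `phase`, `n_days`, `nutrient`, `ref`, `app`
#'   (mean daily intake under each database).
#' @export
aggregate_daily_means <- function(entries, phase = c("T1", "T2")) {
  phase <- match.arg(phase)
  entries <- validate_diary(entries)
  entries <- dplyr::filter(entries, .data$phase == !!phase)
  if (nrow(entries) == 0) {
    warning("no entries for phase ", phase, "; returning empty table")
    return(tibble::tibble(participant_id = character(), phase = character(),
                          n_days = integer(), nutrient = character(),
                          ref = numeric(), app = numeric()))
  }
  long <- tidyr::pivot_longer(
    entries,
    cols = dplyr::all_of(c(ref_cols(), app_cols())),
    names_to = c("method", "nutrient"), names_sep = "_",
    values_to = "amount"
  )
  long$amount[is.na(long$amount)] <- 0
  out <- long |>
    dplyr::group_by(.data$participant_id, .data$method, .data$nutrient) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      total = sum(.data$amount),
      .groups = "drop"
    ) |>
    dplyr::mutate(daily = .data$total / .data$n_days) |>
    dplyr::select(-"total") |>
    tidyr::pivot_wider(names_from = "method", values_from = "daily") |>
    dplyr::mutate(phase = phase, .after = "participant_id") |>
    dplyr::relocate("n_days", .after = "phase") |>
    dplyr::mutate(nutrient = factor(.data$nutrient, levels = nutrient_keys())) |>
    dplyr::arrange(.data$participant_id, .data$nutrient) |>
    dplyr::mutate(nutrient = as.character(.data$nutrient))
  out[, c("participant_id", "phase", "n_days", "nutrient", "ref", "app")]
}
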