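#' Candidate grid of putative upper limits for one nutrient
#'
#' Candidates run from the 50th percentile of the observed app per-portion
#' values up to the observed maximum, in `n_steps` evenly spaced values.
#' Missing app values carry no information about entry errors and are
#' ignored when building the grid.
#'
#' @param entries Food-entry tibble.
#' @param nutrient One of [nutrient_keys()].
#' @param n_steps Number of candidates (default 200).
#' @param lower_quantile Quantile of observed values at which the grid
#'   starts (default 0.5).
#' @return Strictly increasing numeric vector of candidate limits.
#' @export
candidate_grid <- function(entries, nutrient, n_steps = 200,
                           lower_quantile = 0.5) {
  nutrient <- match.arg(nutrient, nutrient_keys())
  vals <- entries[[app_col(nutrient)]]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no observed app values for ", nutrient)
  lo <- unname(quantile(vals, lower_quantile))
  hi <- max(vals)
  if (hi <= lo) stop("degenerate app values for ", nutrient,
                     ": grid would not be strictly increasing")
  seq(lo, hi, length.out = n_steps)
}

#' Learn one nutrient's upper limit per food portion
#'
#' Sweeps the candidate limits in ascending order. For each candidate L,
#' app values of this nutrient strictly above L are excluded (they
#' contribute 0 to daily sums), participant mean daily intakes are
#' recomputed, and the correlation between app and reference daily
#' intakes across participants is recorded. The learned limit is the
#' candidate maximizing that correlation -- the compromise between
#' removing erroneous values and keeping correct ones. Ties are broken
#' toward the largest tied candidate, i.e. the fewest removals.
#'
#' @param train_entries Food-entry tibble for the training phase (the
#'   caller is expected to pass a single phase).
#' @param nutrient One of [nutrient_keys()].
#' @param grid Ascending candidate limits, e.g. from [candidate_grid()].
#' @param assoc Correlation kind: `"pearson"` or `"spearman"`.
#' @return List with `limit` (the learned upper limit), `assoc`, and
#'   `trace`: a tibble of (`limit`, `correlation`, `n_removed`) over the
#'   whole grid, for audit.
#' @export
learn_limit <- function(train_entries, nutrient, grid,
                        assoc = c("pearson", "spearman")) {
  assoc <- match.arg(assoc)
  nutrient <- match.arg(nutrient, nutrient_keys())
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  entries <- validate_diary(train_entries)

  by_part <- split(seq_len(nrow(entries)), entries$participant_id)
  if (length(by_part) < 3) stop("need >= 3 participants to learn a limit")
  ref_v <- entries[[ref_col(nutrient)]]
  app_v <- entries[[app_col(nutrient)]]
  app_v0 <- ifelse(is.na(app_v), 0, app_v)

  n_parts <- length(by_part)
  ref_daily <- numeric(n_parts)
  # Per participant: sorted app values and cumulative sums, so the sum of
  # values <= L is a cumsum lookup instead of a rescan per candidate.
  app_daily <- matrix(0, n_parts, length(grid))
  for (i in seq_len(n_parts)) {
    idx <- by_part[[i]]
    n_days <- length(unique(entries$day[idx]))
    ref_daily[i] <- sum(ref_v[idx]) / n_days
    v <- sort(app_v0[idx])
    cs <- c(0, cumsum(v))
    app_daily[i, ] <- cs[findInterval(grid, v) + 1] / n_days
  }
  removed <- vapply(grid, function(L) sum(app_v0 > L), integer(1))

  cors <- vapply(seq_along(grid), function(j) {
    a <- app_daily[, j]
    if (sd(a) == 0 || sd(ref_daily) == 0) return(NA_real_)
    suppressWarnings(cor(a, ref_daily, method = assoc))
  }, numeric(1))
  if (all(is.na(cors))) {
    stop("degenerate data: correlation undefined at every candidate limit for ",
         nutrient)
  }
  best <- max(cors, na.rm = TRUE)
  # largest tied candidate (fewest removals); exact ties only
  pick <- max(which(!is.na(cors) & cors == best))
  list(
    nutrient = nutrient,
    limit = grid[pick],
    assoc = assoc,
    trace = tibble::tibble(limit = grid, correlation = cors,
                           n_removed = removed)
  )
}

#' Default correlation policy per nutrient
#'
#' Pearson for energy, the macronutrients, sugar and fiber; Spearman rank
#' for cholesterol and sodium, whose daily intakes are typically
#' non-normal under heavy app missingness.
#'
#' @return Named character vector over [nutrient_keys()].
#' @export
default_assoc_policy <- function() {
  stats::setNames(
    ifelse(nutrient_keys() %in% c("cholesterol", "sodium"),
           "spearman", "pearson"),
    nutrient_keys()
  )
}

#' Learn upper limits for all eight nutrients
#'
#' Applies [learn_limit()] independently per nutrient. A nutrient whose
#' data are degenerate (correlation undefined at every candidate) yields
#' `limit = Inf` ("no limit") with a warning rather than an error.
#'
#' @param train_entries Training-phase food entries.
#' @param n_steps,lower_quantile Grid construction, see [candidate_grid()].
#' @param assoc_policy Named vector mapping nutrient to correlation kind;
#'   default [default_assoc_policy()].
#' @return A `limit_set`: tibble with columns `nutrient`, `unit`,
#'   `limit`, `assoc`; the per-nutrient traces are attached as an
#'   attribute `traces`.
#' @export
learn_limits <- function(train_entries, n_steps = 200, lower_quantile = 0.5,
                         assoc_policy = default_assoc_policy()) {
  traces <- list()
  rows <- lapply(nutrient_keys(), function(nut) {
    res <- tryCatch({
      grid <- candidate_grid(train_entries, nut, n_steps, lower_quantile)
      learn_limit(train_entries, nut, grid, assoc_policy[[nut]])
    }, error = function(e) {
      warning("nutrient ", nut, " is degenerate (", conditionMessage(e),
              "); using no limit", call. = FALSE)
      list(nutrient = nut, limit = Inf, assoc = assoc_policy[[nut]],
           trace = NULL)
    })
    traces[[nut]] <<- res$trace
    tibble::tibble(nutrient = nut, unit = nutrient_unit(nut),
                   limit = res$limit, assoc = res$assoc)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "traces") <- traces
  class(out) <- c("limit_set", class(out))
  out
}

#' Apply learned limits to a held-out phase
#'
#' For every entry and nutrient, an app value strictly above the limit is
#' set to missing; the item itself is retained and its other nutrients
#' are untouched. Idempotent: cleaning twice equals cleaning once.
#'
#' @param test_entries Food entries to clean (typically the held-out
#'   phase, never the phase the limits were trained on).
#' @param limits A `limit_set` from [learn_limits()] or [read_limits()].
#' @return List with `entries` (cleaned tibble) and `report`: per-nutrient
#'   removal counts plus `total_items` and `fraction_items_affected`
#'   (share of items with at least one removed value).
#' @export
apply_limits <- function(test_entries, limits) {
  entries <- validate_diary(test_entries)
  stopifnot(all(nutrient_keys() %in% limits$nutrient))
  affected <- rep(FALSE, nrow(entries))
  removed <- stats::setNames(integer(8), nutrient_keys())
  for (nut in nutrient_keys()) {
    L <- limits$limit[limits$nutrient == nut]
    col <- app_col(nut)
    over <- !is.na(entries[[col]]) & entries[[col]] > L
    removed[nut] <- sum(over)
    affected <- affected | over
    entries[[col]][over] <- NA_real_
  }
  report <- list(
    per_nutrient = tibble::tibble(nutrient = nutrient_keys(),
                                  n_removed = unname(removed)),
    total_items = nrow(entries),
    n_items_affected = sum(affected),
    fraction_items_affected = if (nrow(entries) > 0) mean(affected) else 0
  )
  list(entries = entries, report = report)
}

#' Serialize / deserialize a limit set
#'
#' Flat CSV with one row per nutrient: `nutrient`, `unit`, `limit`,
#' `assoc`. `Inf` (no limit) survives the round trip.
#'
#' @param limits A `limit_set`.
#' @param path File path.
#' @return `write_limits()`: `path`, invisibly. `read_limits()`: a
#'   `limit_set` tibble.
#' @export
write_limits <- function(limits, path) {
  utils::write.csv(as.data.frame(limits[, c("nutrient", "unit", "limit",
                                            "assoc")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nutrient", "unit", "limit", "assoc") %in% names(raw)))
  raw$limit <- as.numeric(raw$limit)
  out <- tibble::as_tibble(raw)
  class(out) <- c("limit_set", class(out))
  out
}
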