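#' Choose correlation and paired-test methods via a normality gate
#'
#' Shapiro-Wilk is applied to `x`, to `y`, and to the differences
#' `x - y`. The parametric pair (Pearson correlation, paired t test) is
#' chosen only if all three tests fail to reject normality at `alpha`;
#' otherwise the rank-based pair (Spearman, Wilcoxon signed rank). A
#' zero-variance margin cannot be normality-tested and takes the
#' rank-based path.
#'
#' @param x,y Paired samples, equal length >= 4.
#' @param alpha Gate significance level (default 0.05).
#' @return List with `test_used` (`paired_t` / `wilcoxon_signed_rank`),
#'   `corr_used` (`pearson` / `spearman`) and the three gate p-values.
#' @export
choose_methods <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 4) stop("need at least 4 pairs")
  p <- vapply(list(x = x, y = y, diff = x - y), shapiro_p, numeric(1))
  normal <- all(!is.na(p) & p >= alpha)
  list(
    test_used = if (normal) "paired_t" else "wilcoxon_signed_rank",
    corr_used = if (normal) "pearson" else "spearman",
    shapiro_p = p
  )
}

# NA for untestable input (zero variance, n outside 3..5000): treated as
# non-normal by the gate.
shapiro_p <- function(v) {
  if (length(v) < 3 || length(v) > 5000 || sd(v) == 0) return(NA_real_)
  shapiro.test(v)$p.value
}

#' Paired location test
#'
#' Two-sided paired t test or Wilcoxon signed-rank test on the
#' differences. Identical samples (all differences zero) are degenerate
#' for both tests; p = 1 is reported by convention with a note.
#'
#' @param x,y Paired samples.
#' @param test_used `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return List with `p_value`, `estimate` (mean or pseudo-median of
#'   `x - y`), `statistic` and `note`.
#' @export
paired_location_test <- function(x, y,
                                 test_used = c("paired_t",
                                               "wilcoxon_signed_rank")) {
  test_used <- match.arg(test_used)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  if (all(d == 0)) {
    return(list(p_value = 1, estimate = 0, statistic = NA_real_,
                note = "all differences zero; p = 1 by convention"))
  }
  if (test_used == "paired_t") {
    ht <- t.test(x, y, paired = TRUE)
    list(p_value = ht$p.value, estimate = unname(ht$estimate),
         statistic = unname(ht$statistic), note = NA_character_)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    list(p_value = ht$p.value, estimate = stats::median(d),
         statistic = unname(ht$statistic), note = NA_character_)
  }
}

#' Bland-Altman agreement summary
#'
#' Differences are taken as `y - x` (app minus reference). Limits of
#' agreement are `mean_diff +/- 1.96 * sd_diff`. Fixed bias is flagged
#' when the 95% one-sample t confidence interval of the mean difference
#' excludes 0; proportional bias when the OLS slope of the difference on
#' the pair mean `(x + y) / 2` differs from 0 at `alpha`.
#'
#' @param x Reference sample.
#' @param y Comparison (app) sample, paired with `x`, n >= 4.
#' @param alpha Significance level for the proportional-bias slope test.
#' @return List of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `fixed_bias`, `fixed_bias_ci`,
#'   `prop_slope`, `prop_p`, `prop_bias`, `note`.
#' @export
bland_altman <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  d <- y - x
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  note <- NA_character_

  if (sd_diff == 0) {
    ci <- c(mean_diff, mean_diff)
    fixed <- mean_diff != 0
  } else {
    ht <- t.test(d)
    ci <- unname(ht$conf.int)
    fixed <- ci[1] > 0 || ci[2] < 0
  }
  if (var(m) == 0 || sd_diff == 0) {
    slope <- NA_real_
    slope_p <- NA_real_
    prop <- FALSE
    note <- "proportional-bias test skipped (zero variance)"
  } else {
    fit <- summary(lm(d ~ m))
    slope <- fit$coefficients["m", "Estimate"]
    slope_p <- fit$coefficients["m", "Pr(>|t|)"]
    prop <- slope_p < alpha
  }
  structure(list(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff,
    loa_lower = mean_diff - 1.96 * sd_diff,
    loa_upper = mean_diff + 1.96 * sd_diff,
    fixed_bias = fixed, fixed_bias_ci = ci,
    prop_slope = slope, prop_p = slope_p, prop_bias = prop,
    note = note
  ), class = "bland_altman")
}

#' Per-nutrient agreement table for a cohort
#'
#' For each nutrient: descriptive means/SDs of reference and app daily
#' intakes, the normality-gated paired test and correlation, and the
#' Bland-Altman summary. When cleaned intakes are supplied the table
#' stacks both cleaning states, mirroring a published
#' original-vs-cleaned comparison layout.
#'
#' @param diaries Per-participant daily intakes from
#'   [aggregate_daily_means()] (original app values).
#' @param cleaned_diaries Optional: same shape, app side cleaned.
#' @param alpha Significance level for the normality gate and bias tests.
#' @return Tibble with one row per nutrient (x cleaning state):
#'   descriptives, `test_used`, `test_p`, `corr_used`, `corr`, `corr_p`,
#'   and the flattened Bland-Altman fields.
#' @export
agreement_table <- function(diaries, cleaned_diaries = NULL, alpha = 0.05) {
  out <- agreement_table_one(diaries, alpha, state = "original")
  if (!is.null(cleaned_diaries)) {
    out <- dplyr::bind_rows(
      out, agreement_table_one(cleaned_diaries, alpha, state = "cleaned"))
  }
  out
}

agreement_table_one <- function(diaries, alpha, state) {
  n_part <- dplyr::n_distinct(diaries$participant_id)
  if (n_part < 4) stop("need >= 4 participants")
  rows <- lapply(nutrient_keys(), function(nut) {
    sub <- diaries[diaries$nutrient == nut, ]
    x <- sub$ref
    y <- sub$app
    ch <- choose_methods(x, y, alpha)
    loc <- paired_location_test(x, y, ch$test_used)
    ct <- suppressWarnings(
      cor.test(x, y, method = ch$corr_used, exact = FALSE))
    ba <- bland_altman(x, y, alpha)
    tibble::tibble(
      state = state, nutrient = nut, unit = nutrient_unit(nut), n = length(x),
      ref_mean = mean(x), ref_sd = sd(x),
      app_mean = mean(y), app_sd = sd(y),
      test_used = ch$test_used, test_p = loc$p_value,
      corr_used = ch$corr_used,
      corr = unname(ct$estimate), corr_p = ct$p.value,
      ba_mean_diff = ba$mean_diff, ba_sd_diff = ba$sd_diff,
      ba_loa_lower = ba$loa_lower, ba_loa_upper = ba$loa_upper,
      ba_fixed_bias = ba$fixed_bias,
      ba_prop_slope = ba$prop_slope, ba_prop_bias = ba$prop_bias
    )
  })
  dplyr::bind_rows(rows)
}

#' Bland-Altman plot data
#'
#' Emits the per-pair coordinates a plotting front end needs: pair mean,
#' difference (app - ref), and the mean-difference / limits-of-agreement
#' lines per nutrient.
#'
#' @param diaries Per-participant daily intakes ([aggregate_daily_means()]).
#' @return Tibble: `nutrient`, `participant_id`, `pair_mean`, `diff`,
#'   `mean_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman_data <- function(diaries) {
  rows <- lapply(nutrient_keys(), function(nut) {
    sub <- diaries[diaries$nutrient == nut, ]
    ba <- bland_altman(sub$ref, sub$app)
    tibble::tibble(
      nutrient = nut, participant_id = sub$participant_id,
      pair_mean = (sub$ref + sub$app) / 2, diff = sub$app - sub$ref,
      mean_diff = ba$mean_diff, loa_lower = ba$loa_lower,
      loa_upper = ba$loa_upper
    )
  })
  dplyr::bind_rows(rows)
}
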