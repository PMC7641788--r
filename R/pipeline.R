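#' Configuration for a full validation run
#'
#' @param t1,t2 Paths to training (T1) and held-out (T2) diary CSVs, or
#'   `NULL` to simulate a cohort with `synthetic`.
#' @param synthetic A [synthetic_config()] used when no CSV paths are
#'   given; both phases are generated.
#' @param out_dir Output directory for the report bundle.
#' @param alpha Significance level used throughout.
#' @param grid_steps,grid_lower_quantile Limit-learner grid construction.
#' @param power A [power_sim_config()] for the power stage.
#' @param allow_self_clean Permit T1 == T2 (exploratory only; the
#'   held-out design is the default and limits are never learned on the
#'   phase they clean unless this is set).
#' @param seed Master seed, propagated to every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(t1 = NULL, t2 = NULL,
                       synthetic = synthetic_config(),
                       out_dir = "results",
                       alpha = 0.05,
                       grid_steps = 200,
                       grid_lower_quantile = 0.5,
                       power = power_sim_config(mode = "analytic"),
                       allow_self_clean = FALSE,
                       seed = 1L) {
  if (!is.null(t1) && !is.null(t2) && identical(t1, t2) && !allow_self_clean) {
    stop("T1 and T2 are the same file; set allow_self_clean = TRUE ",
         "to learn and apply limits on the same phase")
  }
  structure(list(t1 = t1, t2 = t2, synthetic = synthetic, out_dir = out_dir,
                 alpha = alpha, grid_steps = grid_steps,
                 grid_lower_quantile = grid_lower_quantile, power = power,
                 allow_self_clean = allow_self_clean, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Train per-nutrient upper limits on T1, clean the held-out T2, compute
#' agreement tables for original and cleaned app intakes, run the
#' power/sample-size analysis using the cleaned method-agreement
#' correlations, and write the report bundle: learned limits, cleaning
#' report, agreement table, Bland-Altman plot data, per-nutrient
#' sample-size inflation table, power-curve data, and a manifest of
#' parameters. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every computed table and the paths of
#'   the written files.
#' @export
run_validation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (is.null(config$t1)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    cohort <- generate_cohort(syn)
    t1 <- dplyr::filter(cohort, .data$phase == "T1")
    t2 <- dplyr::filter(cohort, .data$phase == "T2")
    say("simulated cohort: %d items (%d T1, %d T2)",
        nrow(cohort), nrow(t1), nrow(t2))
  } else {
    t1 <- dplyr::filter(read_diary_csv(config$t1), .data$phase == "T1")
    t2 <- dplyr::filter(read_diary_csv(config$t2), .data$phase == "T2")
    if (nrow(t1) == 0) stop("no T1 entries in ", config$t1)
    if (nrow(t2) == 0) stop("no T2 entries in ", config$t2)
  }

  limits <- learn_limits(t1, n_steps = config$grid_steps,
                         lower_quantile = config$grid_lower_quantile)
  for (i in seq_len(nrow(limits))) {
    say("learned limit  %-12s %10.1f %s (%s)", limits$nutrient[i],
        limits$limit[i], limits$unit[i], limits$assoc[i])
  }

  cleaned <- apply_limits(t2, limits)
  rep <- cleaned$report
  say("cleaning removed values from %d of %d T2 items (%.1f%%)",
      rep$n_items_affected, rep$total_items,
      100 * rep$fraction_items_affected)

  diaries_orig <- aggregate_daily_means(t2, "T2")
  diaries_clean <- aggregate_daily_means(cleaned$entries, "T2")
  agreement <- agreement_table(diaries_orig, diaries_clean,
                               alpha = config$alpha)
  ba_data <- bland_altman_data(diaries_clean)

  # power stage: cleaned method-agreement correlations feed the
  # attenuation analysis
  cleaned_rows <- agreement[agreement$state == "cleaned", ]
  inflation <- list()
  curves <- list()
  for (i in seq_len(nrow(cleaned_rows))) {
    nut <- cleaned_rows$nutrient[i]
    r_nm <- cleaned_rows$corr[i]
    if (!is.finite(r_nm) || r_nm <= 0) {
      warning("nutrient ", nut, " has non-positive method agreement; ",
              "skipped in the power table")
      next
    }
    infl_pct <- vapply(config$power$n_list, function(n) {
      sample_size_inflation(r_nm, n, config$power$target_power,
                            config$power$alpha)
    }, numeric(1))
    inflation[[nut]] <- tibble::tibble(
      nutrient = nut, r_nm = r_nm, n = config$power$n_list,
      inflation_pct = infl_pct
    )
    curves[[nut]] <- dplyr::mutate(
      power_curves(config = power_sim_config(
        rho_grid = config$power$rho_grid, alpha = config$power$alpha,
        n_list = config$power$n_list[1], mode = "analytic"),
        r_nm = r_nm),
      nutrient = nut, .before = 1)
  }
  inflation <- dplyr::bind_rows(inflation)
  curves <- dplyr::bind_rows(curves)
  inflation_wide <- tidyr::pivot_wider(
    inflation[, c("n", "nutrient", "inflation_pct")],
    names_from = "nutrient", values_from = "inflation_pct")

  paths <- list(
    limits = file.path(config$out_dir, "limits.csv"),
    cleaning_report = file.path(config$out_dir, "cleaning_report.csv"),
    cleaned_t2 = file.path(config$out_dir, "cohort_t2_cleaned.csv"),
    agreement = file.path(config$out_dir, "agreement_table.csv"),
    ba_data = file.path(config$out_dir, "bland_altman_data.csv"),
    inflation = file.path(config$out_dir, "sample_size_inflation.csv"),
    power_curves = file.path(config$out_dir, "power_curves.csv"),
    manifest = file.path(config$out_dir, "manifest.yaml"),
    log = file.path(config$out_dir, "run.log")
  )
  write_limits(limits, paths$limits)
  utils::write.csv(as.data.frame(rep$per_nutrient), paths$cleaning_report,
                   row.names = FALSE)
  write_diary_csv(cleaned$entries, paths$cleaned_t2)
  utils::write.csv(as.data.frame(agreement), paths$agreement,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ba_data), paths$ba_data, row.names = FALSE)
  utils::write.csv(as.data.frame(inflation_wide), paths$inflation,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(curves), paths$power_curves,
                   row.names = FALSE)
  yaml::write_yaml(list(
    package = "nutripair",
    version = as.character(utils::packageVersion("nutripair")),
    seed = config$seed, alpha = config$alpha,
    grid_steps = config$grid_steps,
    grid_lower_quantile = config$grid_lower_quantile,
    power = list(n_list = config$power$n_list,
                 target_power = config$power$target_power,
                 alpha = config$power$alpha),
    inputs = if (is.null(config$t1)) "synthetic" else c(config$t1, config$t2)
  ), paths$manifest)
  writeLines(log_lines, paths$log)

  invisible(list(limits = limits, cleaning_report = rep,
                 cleaned_t2 = cleaned$entries, agreement = agreement,
                 ba_data = ba_data, inflation = inflation,
                 inflation_wide = inflation_wide, power_curves = curves,
                 paths = paths))
}
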