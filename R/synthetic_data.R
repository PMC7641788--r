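#' Configuration for the synthetic paired-database cohort generator
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate a
#' 50-participant cohort keeping a 4-day food diary twice (phases T1 and
#' T2, ~12-16 items/day), whose reference-side daily intakes match the
#' published means/SDs of a Belgian validation cohort (e.g. energy
#' 1958 +/- 543 kcal/day) and whose app side carries the error structure a
#' partially user-contributed database exhibits: multiplicative
#' under-reporting bias, log-normal noise, missing nutrient fields
#' (severe for cholesterol and sodium), and occasional gross entry errors
#' (decimal/unit mistakes, modelled as x10 / x100 multipliers on a single
#' nutrient of a single item).
#'
#' @param n_participants Number of participants (default 50).
#' @param n_days Diary length in days per phase (default 4).
#' @param items_per_day Integer range (length 2) of items per day,
#'   drawn uniformly (default 12-16).
#' @param ref_daily_targets Named list/vector pairs: per-nutrient `mean`
#'   and `sd` of true participant-level daily intake, in the nutrient's
#'   own unit per day.
#' @param app_noise_sd Named numeric: per-nutrient SD (log scale) of the
#'   participant-level multiplicative app noise. This is the component
#'   that sets the cross-method correlation of daily intakes.
#' @param item_noise_sd Scalar SD (log scale) of item-level app noise;
#'   largely averages out over a day's items.
#' @param app_bias Named numeric: multiplicative app bias per nutrient
#'   (<1 models systematic under-reporting).
#' @param missing_prob Named numeric: probability an item's app value for
#'   a nutrient is missing from the app database.
#' @param contamination_rate Probability an item carries one gross error.
#' @param contamination_multiplier Numeric vector of gross-error factors.
#' @param contamination_weights Sampling weights for the multipliers.
#' @param day_sd Log-scale SD of day-to-day variation around a
#'   participant's habitual intake.
#' @param item_jitter_sd Log-scale SD of the item-composition jitter.
#' @param item_jitter_cor Correlation of item-level jitter across
#'   nutrients (diaries exhibit correlated nutrient profiles per item).
#' @param dirichlet_alpha Symmetric Dirichlet concentration used to split
#'   a day's total across its items.
#' @param seed RNG seed; identical configs reproduce identical cohorts.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 50,
                             n_days = 4,
                             items_per_day = c(12L, 16L),
                             ref_daily_targets = default_daily_targets(),
                             app_noise_sd = default_app_noise_sd(),
                             item_noise_sd = 0.25,
                             app_bias = default_app_bias(),
                             missing_prob = default_missing_prob(),
                             contamination_rate = 0.028,
                             contamination_multiplier = c(10, 100),
                             contamination_weights = c(0.7, 0.3),
                             day_sd = 0.15,
                             item_jitter_sd = 0.3,
                             item_jitter_cor = 0.5,
                             dirichlet_alpha = 2,
                             seed = 1L) {
  targets <- as_nutrient_table(ref_daily_targets)
  if (any(targets$mean <= 0)) stop("daily target means must be > 0")
  if (any(targets$sd < 0)) stop("daily target SDs must be >= 0")
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    items_per_day = as.integer(items_per_day),
    ref_daily_targets = targets,
    app_noise_sd = complete_nutrient_vector(app_noise_sd, 0),
    item_noise_sd = item_noise_sd,
    app_bias = complete_nutrient_vector(app_bias, 1),
    missing_prob = complete_nutrient_vector(missing_prob, 0),
    contamination_rate = contamination_rate,
    contamination_multiplier = contamination_multiplier,
    contamination_weights = contamination_weights,
    day_sd = day_sd,
    item_jitter_sd = item_jitter_sd,
    item_jitter_cor = item_jitter_cor,
    dirichlet_alpha = dirichlet_alpha,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_participants >= 1, cfg$n_days >= 1,
    length(cfg$items_per_day) == 2,
    cfg$items_per_day[1] >= 1, cfg$items_per_day[2] >= cfg$items_per_day[1],
    all(cfg$app_noise_sd >= 0), cfg$item_noise_sd >= 0,
    all(cfg$app_bias >= 0),
    all(cfg$missing_prob >= 0), all(cfg$missing_prob <= 1),
    cfg$contamination_rate >= 0, cfg$contamination_rate <= 1,
    all(cfg$contamination_multiplier > 0),
    length(cfg$contamination_weights) == length(cfg$contamination_multiplier),
    cfg$day_sd >= 0, cfg$item_jitter_sd >= 0,
    cfg$item_jitter_cor >= 0, cfg$item_jitter_cor < 1,
    cfg$dirichlet_alpha > 0
  )
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_daily_targets <- function() {
  tibble::tibble(
    nutrient = nutrient_keys(),
    mean = c(1958, 225, 81, 78, 19, 85, 242, 2638),
    sd   = c(543, 61, 27, 26, 8, 35, 131, 848)
  )
}

#' @rdname synthetic_config
#' @export
default_app_noise_sd <- function() {
  c(energy = 0.08, carbohydrate = 0.13, fat = 0.16, protein = 0.16,
    fiber = 0.32, sugar = 0.32, cholesterol = 0.90, sodium = 0.50)
}

#' @rdname synthetic_config
#' @export
default_app_bias <- function() {
  c(energy = 1.01, carbohydrate = 0.93, fat = 0.99, protein = 0.92,
    fiber = 0.79, sugar = 0.87, cholesterol = 0.45, sodium = 0.98)
}

#' @rdname synthetic_config
#' @export
default_missing_prob <- function() {
  c(energy = 0.02, carbohydrate = 0.02, fat = 0.02, protein = 0.02,
    fiber = 0.02, sugar = 0.02, cholesterol = 0.5, sodium = 0.5)
}

as_nutrient_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("nutrient", "mean", "sd") %in% names(x)))
    x <- x[match(nutrient_keys(), x$nutrient), c("nutrient", "mean", "sd")]
    if (anyNA(x$nutrient)) stop("daily targets must cover all 8 nutrients")
    return(tibble::as_tibble(x))
  }
  stop("ref_daily_targets must be a data frame with nutrient/mean/sd")
}

complete_nutrient_vector <- function(x, default) {
  out <- stats::setNames(rep(default, 8), nutrient_keys())
  if (length(x) > 0) {
    x <- unlist(x)
    bad <- setdiff(names(x), nutrient_keys())
    if (length(bad) > 0) stop("unknown nutrient name(s): ",
                              paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

#' Read a generator configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [synthetic_config()]; nutrient
#' maps are nested key-value blocks and `ref_daily_targets` is a list of
#' `{nutrient, mean, sd}` records.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ref_daily_targets)) {
    raw$ref_daily_targets <-
      dplyr::bind_rows(lapply(raw$ref_daily_targets, tibble::as_tibble))
  }
  do.call(synthetic_config, raw)
}

# Log-normal parameters matching a target mean/sd on the natural scale.
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a synthetic paired-database cohort
#'
#' Simulates both diary phases (T1 and T2). Per participant a habitual
#' daily intake vector is drawn log-normally to match the configured
#' means/SDs; each day's total varies log-normally around it and is split
#' across that day's items by a symmetric Dirichlet weight vector with a
#' correlated log-normal composition jitter (so an item's nutrients move
#' together). The reference database records the truth; the app channel
#' applies, in order: multiplicative bias, participant-level and
#' item-level log-normal noise (mean-one), missingness, and gross errors
#' that multiply exactly one nutrient of one item. Every planted anomaly
#' is recorded in an audit table retrievable with [audit_log()].
#'
#' @param config A [synthetic_config()].
#' @return A food-entry tibble covering phases T1 and T2 (columns as in
#'   [read_diary_csv()]), with the audit table attached as an attribute.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nk <- nutrient_keys()
  n_nut <- length(nk)
  targets <- config$ref_daily_targets
  lp <- lnorm_params(targets$mean, targets$sd)

  # Habitual participant-level daily intakes, shared across phases.
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  mu <- matrix(0, config$n_participants, n_nut, dimnames = list(ids, nk))
  for (k in seq_len(n_nut)) {
    mu[, k] <- stats::rlnorm(config$n_participants, lp$mu[k], lp$sigma[k])
  }

  rows <- list()
  for (phase in c("T1", "T2")) {
    # participant-level app noise: the dominant error component
    part_noise <- exp(sweep(
      matrix(rnorm(config$n_participants * n_nut), ncol = n_nut) %*%
        diag(config$app_noise_sd, n_nut),
      2, config$app_noise_sd^2 / 2, "-"
    ))
    dimnames(part_noise) <- list(ids, nk)
    for (p in seq_along(ids)) {
      for (d in seq_len(config$n_days)) {
        day_total <- mu[p, ] *
          exp(rnorm(n_nut, 0, config$day_sd) - config$day_sd^2 / 2)
        n_it <- sample(seq(config$items_per_day[1], config$items_per_day[2]), 1)
        w <- rgamma(n_it, config$dirichlet_alpha)
        rho <- config$item_jitter_cor
        shared <- rnorm(n_it)
        g <- exp(config$item_jitter_sd *
                   (sqrt(rho) * shared +
                      sqrt(1 - rho) * matrix(rnorm(n_it * n_nut), n_it)))
        wk <- w * g                                   # n_it x n_nut
        ref <- sweep(sweep(wk, 2, colSums(wk), "/"), 2, day_total, "*")
        item_noise <- exp(config$item_noise_sd *
                            matrix(rnorm(n_it * n_nut), n_it) -
                            config$item_noise_sd^2 / 2)
        app <- sweep(ref, 2, config$app_bias, "*") *
          item_noise * rep(part_noise[p, ], each = n_it)
        colnames(ref) <- ref_cols()
        colnames(app) <- app_cols()
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = ids[p], phase = phase, day = d,
          item_label = sprintf("item_%s_%s_d%d_%02d", ids[p], phase, d,
                               seq_len(n_it)),
          portion_g = round(ref[, "ref_energy"] / 1.5, 1),
          tibble::as_tibble(ref), tibble::as_tibble(app)
        )
      }
    }
  }
  cohort <- dplyr::bind_rows(rows)
  n_items <- nrow(cohort)
  app_mat <- as.matrix(cohort[, app_cols()])

  # Missingness channel: drawn for every item x nutrient in one block so
  # that changing one probability leaves the rest of the stream intact.
  u_mis <- matrix(runif(n_items * n_nut), n_items, n_nut)
  mis <- sweep(u_mis, 2, config$missing_prob, "<")
  audit_mis <- which(mis, arr.ind = TRUE)

  # Gross-error channel: one nutrient of one item, multiplied by a unit-
  # mistake factor. Uniforms drawn for all items regardless of the rate,
  # so raising the rate with the same seed only adds flagged items.
  u_err <- runif(n_items)
  err_nut <- sample.int(n_nut, n_items, replace = TRUE)
  err_mult <- config$contamination_multiplier[
    sample.int(length(config$contamination_multiplier), n_items,
               replace = TRUE, prob = config$contamination_weights)]
  flagged <- which(u_err < config$contamination_rate &
                     !mis[cbind(seq_len(n_items), err_nut)])

  audit <- tibble::tibble(
    row = integer(), participant_id = character(), phase = character(),
    day = numeric(), item_label = character(), nutrient = character(),
    kind = character(), original = numeric(), value = numeric()
  )
  if (nrow(audit_mis) > 0) {
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      row = as.integer(audit_mis[, 1]),
      participant_id = cohort$participant_id[audit_mis[, 1]],
      phase = cohort$phase[audit_mis[, 1]],
      day = cohort$day[audit_mis[, 1]],
      item_label = cohort$item_label[audit_mis[, 1]],
      nutrient = nk[audit_mis[, 2]],
      kind = "missing",
      original = app_mat[audit_mis],
      value = NA_real_
    ))
  }
  app_mat[mis] <- NA_real_
  if (length(flagged) > 0) {
    idx <- cbind(flagged, err_nut[flagged])
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      row = as.integer(flagged),
      participant_id = cohort$participant_id[flagged],
      phase = cohort$phase[flagged],
      day = cohort$day[flagged],
      item_label = cohort$item_label[flagged],
      nutrient = nk[err_nut[flagged]],
      kind = "gross_error",
      original = app_mat[idx],
      value = app_mat[idx] * err_mult[flagged]
    ))
    app_mat[idx] <- app_mat[idx] * err_mult[flagged]
  }
  cohort[, app_cols()] <- tibble::as_tibble(app_mat)
  audit <- dplyr::arrange(audit, .data$row, .data$nutrient)
  attr(cohort, "audit") <- audit
  attr(cohort, "config") <- config
  cohort
}

#' Retrieve the planted-anomaly audit table of a synthetic cohort
#'
#' Lists every planted missing value and gross error exactly once, with
#' the pre-anomaly app value, enabling sensitivity/false-positive
#' evaluation of the data cleaner against known truth.
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return Tibble with columns `row`, `participant_id`, `phase`, `day`,
#'   `item_label`, `nutrient`, `kind` (`missing` or `gross_error`),
#'   `original` (pre-anomaly app value) and `value` (post-anomaly).
#' @export
audit_log <- function(cohort) {
  audit <- attr(cohort, "audit")
  if (is.null(audit)) {
    stop("no audit table attached; was this cohort produced by generate_cohort()?")
  }
  audit
}
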