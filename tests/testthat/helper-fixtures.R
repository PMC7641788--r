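# Shared fixture builders and independent brute-force oracles.

# Build a diary tibble from partial columns; unspecified ref nutrients are
# 0, unspecified app nutrients mirror the ref side.
make_entries <- function(...) {
  given <- tibble::tibble(...)
  n <- nrow(given)
  out <- tibble::tibble(
    participant_id = rep("P1", n), phase = rep("T1", n), day = rep(1, n),
    item_label = sprintf("item%02d", seq_len(n)), portion_g = rep(100, n)
  )
  for (col in names(given)[names(given) %in% names(out)]) {
    out[[col]] <- given[[col]]
  }
  for (nut in nutrient_keys()) {
    rc <- paste0("ref_", nut)
    out[[rc]] <- if (rc %in% names(given)) given[[rc]] else rep(0, n)
  }
  for (nut in nutrient_keys()) {
    ac <- paste0("app_", nut)
    out[[ac]] <- if (ac %in% names(given)) given[[ac]] else
      out[[paste0("ref_", nut)]]
  }
  out
}

# Identity-channel generator config: app side equals the reference side.
identity_config <- function(...) {
  zero <- stats::setNames(rep(0, 8), nutrient_keys())
  one <- stats::setNames(rep(1, 8), nutrient_keys())
  synthetic_config(app_noise_sd = zero, item_noise_sd = 0, app_bias = one,
                   missing_prob = zero, contamination_rate = 0, ...)
}

# Low-noise config whose gross errors are hugely separated from clean
# values (x1e5 unit-mistake factor), so the cleaner's operating
# characteristics can be read off the audit log.
separated_config <- function(...) {
  synthetic_config(
    app_noise_sd = stats::setNames(rep(0.05, 8), nutrient_keys()),
    item_noise_sd = 0.1,
    app_bias = stats::setNames(rep(1, 8), nutrient_keys()),
    missing_prob = stats::setNames(rep(0, 8), nutrient_keys()),
    contamination_rate = 0.03,
    contamination_multiplier = 1e5, contamination_weights = 1, ...)
}

# Brute-force limit learner: rescan every candidate from scratch.
# Independent of the cumulative-sum path in learn_limit().
oracle_learn_limit <- function(entries, nutrient, grid, assoc = "pearson") {
  best <- -Inf
  best_limit <- NA_real_
  for (L in grid) {
    per <- t(vapply(split(entries, entries$participant_id), function(sub) {
      nd <- length(unique(sub$day))
      a <- sub[[paste0("app_", nutrient)]]
      a[is.na(a)] <- 0
      a[a > L] <- 0
      c(app = sum(a) / nd, ref = sum(sub[[paste0("ref_", nutrient)]]) / nd)
    }, c(app = 0, ref = 0)))
    cc <- if (stats::sd(per[, "app"]) == 0 || stats::sd(per[, "ref"]) == 0) {
      NA_real_
    } else {
      suppressWarnings(stats::cor(per[, "app"], per[, "ref"], method = assoc))
    }
    if (!is.na(cc) && cc >= best) {  # >= : largest tied candidate wins
      best <- cc
      best_limit <- L
    }
  }
  best_limit
}

# Spreadsheet-style daily-mean recomputation, one cell at a time.
oracle_daily_mean <- function(entries, participant, nutrient, method) {
  sub <- entries[entries$participant_id == participant, ]
  v <- sub[[paste0(method, "_", nutrient)]]
  v[is.na(v)] <- 0
  sum(v) / length(unique(sub$day))
}
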