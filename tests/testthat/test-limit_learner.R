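test_that("candidate grid spans the median-to-max range, ascending", {
  cohort <- generate_cohort(synthetic_config(n_participants = 8, seed = 6))
  g <- candidate_grid(cohort, "energy")
  expect_length(g, 200)
  expect_false(is.unsorted(g, strictly = TRUE))
  vals <- cohort$app_energy[!is.na(cohort$app_energy)]
  expect_equal(g[1], unname(quantile(vals, 0.5)))
  expect_equal(g[200], max(vals))
})

test_that("with nothing to remove the whole grid ties and the top wins", {
  cohort <- generate_cohort(identity_config(n_participants = 8, seed = 9))
  t1 <- cohort[cohort$phase == "T1", ]
  g <- candidate_grid(t1, "energy")
  # smallest candidate (median) already exceeds nothing relevant? No:
  # use a grid above the max so no value is ever excluded
  g_hi <- max(t1$app_energy) * seq(1, 2, length.out = 50)
  res <- learn_limit(t1, "energy", g_hi, "pearson")
  expect_equal(res$limit, max(g_hi))
  expect_equal(sum(res$trace$n_removed), 0)
  expect_true(all(res$trace$correlation == res$trace$correlation[1]))
})

test_that("a planted x100 energy error is isolated and matches brute force", {
  cohort <- generate_cohort(identity_config(n_participants = 10, seed = 10))
  t1 <- cohort[cohort$phase == "T1", ]
  clean_max <- max(t1$app_energy)
  victim <- which.max(t1$app_energy)
  t1$app_energy[victim] <- 45000
  g <- candidate_grid(t1, "energy")
  res <- learn_limit(t1, "energy", g, "pearson")
  expect_lt(res$limit, 45000)
  expect_gt(res$limit, max(t1$app_energy[-victim]))
  expect_equal(res$limit, oracle_learn_limit(t1, "energy", g, "pearson"))
  expect_gte(max(res$trace$correlation, na.rm = TRUE),
             res$trace$correlation[length(g)])
})

test_that("hand-built six-participant table: one aberrant value flips r", {
  # two items per participant; participant B's app side records 500 g of
  # carbohydrate for an item the reference saw as 42 g
  ref_items <- list(A = c(30, 40), B = c(38, 42), C = c(40, 50),
                    D = c(45, 55), E = c(50, 60), F = c(55, 65))
  app_items <- ref_items
  app_items$B <- c(38, 500)
  entries <- make_entries(
    participant_id = rep(names(ref_items), each = 2), day = 1,
    ref_carbohydrate = unlist(ref_items),
    app_carbohydrate = unlist(app_items)
  )
  clean_max <- 65
  g <- seq(25, 600, by = 1)
  res <- learn_limit(entries, "carbohydrate", g, "pearson")
  expect_gte(res$limit, clean_max)
  expect_lt(res$limit, 500)
  expect_equal(res$limit, oracle_learn_limit(entries, "carbohydrate", g))
  # hand-enumerated daily totals in the two regimes
  ref_tot <- vapply(ref_items, sum, numeric(1))
  with_500 <- cor(c(70, 538, 90, 100, 110, 120), ref_tot)
  without <- cor(c(70, 38, 90, 100, 110, 120), ref_tot)
  trace_at <- function(L) res$trace$correlation[match(L, res$trace$limit)]
  expect_equal(trace_at(600), with_500)
  expect_equal(trace_at(100), without)
  expect_gt(without, with_500)
})

test_that("learned-limit cleaning never lowers the training correlation", {
  for (seed in c(31, 32, 33)) {
    cohort <- generate_cohort(synthetic_config(n_participants = 15,
                                               seed = seed))
    t1 <- cohort[cohort$phase == "T1", ]
    g <- candidate_grid(t1, "energy")
    res <- learn_limit(t1, "energy", g, "pearson")
    expect_equal(res$limit, oracle_learn_limit(t1, "energy", g, "pearson"))
    no_clean <- res$trace$correlation[length(g)]
    expect_gte(max(res$trace$correlation, na.rm = TRUE), no_clean)
  }
})

test_that("learn_limits marks degenerate nutrients as unlimited", {
  cohort <- generate_cohort(identity_config(n_participants = 6, seed = 12))
  t1 <- cohort[cohort$phase == "T1", ]
  t1$app_cholesterol <- 100  # constant: no grid can be built
  expect_warning(limits <- learn_limits(t1), "cholesterol")
  expect_equal(limits$limit[limits$nutrient == "cholesterol"], Inf)
  expect_true(all(is.finite(limits$limit[limits$nutrient != "cholesterol"])))
  expect_equal(limits$assoc[limits$nutrient == "cholesterol"], "spearman")
  expect_equal(limits$assoc[limits$nutrient == "energy"], "pearson")
})

test_that("apply_limits removes strictly-above values and nothing else", {
  limits <- learn_limits(
    generate_cohort(identity_config(n_participants = 6, seed = 14)))
  limits$limit <- rep(Inf, 8)
  entries <- make_entries(ref_carbohydrate = c(20, 40, 90, 96, 300),
                          app_carbohydrate = c(20, 40, 90, 96, 300))
  res <- apply_limits(entries, limits)
  expect_equal(sum(res$report$per_nutrient$n_removed), 0)
  expect_equal(res$report$fraction_items_affected, 0)

  # published carbohydrate limit of 95 g as a worked input
  limits$limit[limits$nutrient == "carbohydrate"] <- 95
  res <- apply_limits(entries, limits)
  expect_equal(
    res$report$per_nutrient$n_removed[
      res$report$per_nutrient$nutrient == "carbohydrate"], 2)
  expect_true(all(is.na(res$entries$app_carbohydrate[4:5])))
  expect_equal(res$entries$app_carbohydrate[1:3], c(20, 40, 90))
  # reference side and other nutrients untouched
  expect_equal(res$entries$ref_carbohydrate, entries$ref_carbohydrate)
  expect_equal(res$entries$app_energy, entries$app_energy)
  expect_equal(res$report$fraction_items_affected, 2 / 5)

  # idempotence
  res2 <- apply_limits(res$entries, limits)
  expect_identical(res2$entries, res$entries)
  expect_equal(sum(res2$report$per_nutrient$n_removed), 0)
})

test_that("a smaller limit never removes fewer values", {
  cohort <- generate_cohort(synthetic_config(n_participants = 10, seed = 15))
  base <- learn_limits(cohort[cohort$phase == "T1", ])
  t2 <- cohort[cohort$phase == "T2", ]
  for (f in c(2, 1, 0.5, 0.25)) {
    lim <- base
    lim$limit <- base$limit * f
    removed <- apply_limits(t2, lim)$report$per_nutrient$n_removed
    if (f == 2) prev <- removed
    expect_true(all(removed >= prev))
    prev <- removed
  }
})

test_that("separated gross errors are removed with perfect sensitivity", {
  # learned limits land in the wide gap between the clean values and the
  # x1e5 unit mistakes, so cleaning the phase they were learned from must
  # recover the audit log exactly: sensitivity 1, zero false positives
  cohort <- generate_cohort(separated_config(seed = 16))
  t1 <- cohort[cohort$phase == "T1", ]
  limits <- learn_limits(t1)
  res <- apply_limits(t1, limits)
  audit <- audit_log(cohort)
  ge1 <- audit[audit$kind == "gross_error" & audit$phase == "T1", ]
  expect_gt(nrow(ge1), 20)
  removed_cells <- which(is.na(as.matrix(
    res$entries[, paste0("app_", nutrient_keys())])), arr.ind = TRUE)
  t1_rows <- which(cohort$phase == "T1")
  expected <- cbind(match(ge1$row, t1_rows),
                    match(ge1$nutrient, nutrient_keys()))
  expect_setequal(paste(removed_cells[, 1], removed_cells[, 2]),
                  paste(expected[, 1], expected[, 2]))
  # learned limits sit above every clean value, below every gross error
  clean_t1 <- t1
  for (i in seq_len(nrow(ge1))) {
    clean_t1[[paste0("app_", ge1$nutrient[i])]][match(ge1$row[i], t1_rows)] <-
      ge1$original[i]
  }
  for (nut in unique(ge1$nutrient)) {
    lim <- limits$limit[limits$nutrient == nut]
    expect_gte(lim, max(clean_t1[[paste0("app_", nut)]]))
    expect_lt(lim, min(ge1$value[ge1$nutrient == nut]))
  }
})

test_that("limit sets survive serialization, including Inf", {
  limits <- learn_limits(
    generate_cohort(synthetic_config(n_participants = 8, seed = 17)))
  limits$limit[3] <- Inf
  path <- withr::local_tempfile(fileext = ".csv")
  write_limits(limits, path)
  back <- read_limits(path)
  expect_equal(back$nutrient, limits$nutrient)
  expect_equal(back$limit, limits$limit)
  expect_equal(back$assoc, limits$assoc)
  expect_equal(back$unit, limits$unit)
})
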