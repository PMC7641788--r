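test_that("the normality gate picks the parametric pair for normal data", {
  set.seed(41)
  x <- rnorm(50, 100, 10)
  y <- x + rnorm(50, 0, 5)
  ch <- choose_methods(x, y)
  expect_equal(ch$test_used, "paired_t")
  expect_equal(ch$corr_used, "pearson")
  expect_true(all(ch$shapiro_p >= 0.05))
  # cross-check the gate inputs against the standard implementation
  expect_equal(ch$shapiro_p[["diff"]], shapiro.test(x - y)$p.value)
})

test_that("an extreme outlier or degenerate margin forces the rank path", {
  set.seed(42)
  x <- rnorm(50, 100, 10)
  y <- x + rnorm(50, 0, 5)
  y[7] <- y[7] * 100
  ch <- choose_methods(x, y)
  expect_equal(ch$test_used, "wilcoxon_signed_rank")
  expect_equal(ch$corr_used, "spearman")

  const <- choose_methods(rep(5, 10), rnorm(10))
  expect_equal(const$corr_used, "spearman")
  expect_true(is.na(const$shapiro_p[["x"]]))

  expect_error(choose_methods(1:5, 1:4), "paired")
  expect_error(choose_methods(1:3, 1:3), "at least 4")
})

test_that("paired t p-value equals the closed-form t CDF", {
  y <- c(10, 20, 30, 40, 50)
  x <- y + c(1, 2, 3, 4, 5)
  res <- paired_location_test(x, y, "paired_t")
  tval <- 3 / (sd(c(1, 2, 3, 4, 5)) / sqrt(5))  # = 4.2426, df = 4
  expect_equal(res$statistic, tval)
  expect_equal(res$p_value, 2 * pt(-tval, df = 4))
  expect_equal(res$estimate, 3)
})

test_that("identical samples give p = 1 by convention in both tests", {
  x <- rnorm(10)
  for (tst in c("paired_t", "wilcoxon_signed_rank")) {
    res <- paired_location_test(x, x, tst)
    expect_equal(res$p_value, 1)
    expect_match(res$note, "zero")
  }
})

test_that("paired-t rejection rate matches analytic power at a 0.5 SD shift", {
  set.seed(43)
  n <- 50
  reps <- 500
  rejections <- vapply(seq_len(reps), function(i) {
    d <- rnorm(n, 0.5, 1)
    paired_location_test(d, rep(0, n), "paired_t")$p_value < 0.05
  }, logical(1))
  p_true <- stats::power.t.test(n = n, delta = 0.5, sd = 1,
                                type = "one.sample")$power
  expect_lt(abs(mean(rejections) - p_true),
            3 * sqrt(p_true * (1 - p_true) / reps))
})

test_that("Bland-Altman identity and constant-shift cases", {
  x <- c(10, 12, 15, 18, 22)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  expect_false(ba$fixed_bias)
  expect_false(ba$prop_bias)

  # a pure fixed bias: app reads 4 units lower everywhere
  ba <- bland_altman(x, x - 4)
  expect_equal(ba$mean_diff, -4)
  expect_equal(ba$sd_diff, 0)
  expect_true(ba$fixed_bias)
  expect_false(ba$prop_bias)
  expect_match(ba$note, "skipped")
})

test_that("proportional bias slope matches the covariance closed form", {
  # y = 0.5 x + e: difference d = -0.5 x + e on pair mean m = 0.75 x + e/2
  # slope -> (-0.375 sx^2 + 0.5 se^2) / (0.5625 sx^2 + 0.25 se^2)
  set.seed(44)
  sx <- 2
  se <- 0.5
  expected <- (-0.375 * sx^2 + 0.5 * se^2) / (0.5625 * sx^2 + 0.25 * se^2)
  x <- rnorm(400, 10, sx)
  y <- 0.5 * x + rnorm(400, 5, se)
  ba <- bland_altman(x, y)
  fit <- summary(lm(I(y - x) ~ I((x + y) / 2)))
  se_slope <- fit$coefficients[2, "Std. Error"]
  expect_lt(abs(ba$prop_slope - expected), 3 * se_slope)
  expect_true(ba$prop_bias)
  expect_lt(ba$prop_slope, 0)
})

test_that("Bland-Altman differences are antisymmetric in the arguments", {
  set.seed(45)
  x <- rnorm(30, 50, 8)
  y <- 0.9 * x + rnorm(30)
  expect_equal(bland_altman(x, y)$mean_diff, -bland_altman(y, x)$mean_diff)
  expect_equal(bland_altman(x, y)$sd_diff, bland_altman(y, x)$sd_diff)
})

test_that("about 95% of normal differences fall inside the limits", {
  set.seed(46)
  x <- rnorm(2000, 100, 10)
  y <- x + rnorm(2000, 2, 3)
  ba <- bland_altman(x, y)
  d <- y - x
  covered <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_lt(abs(covered - 0.95), 3 * sqrt(0.95 * 0.05 / 2000))
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(47)
  x <- rlnorm(40, 5, 0.4)
  y <- x * exp(rnorm(40, 0, 0.3))
  r1 <- cor(x, y, method = "spearman")
  r2 <- cor(log(x), sqrt(y), method = "spearman")
  expect_equal(r1, r2)
})

test_that("agreement table cells match an independent recomputation", {
  cohort <- generate_cohort(synthetic_config(n_participants = 5, seed = 48))
  diaries <- aggregate_daily_means(cohort, "T1")
  tab <- agreement_table(diaries)
  expect_equal(nrow(tab), 8)
  for (nut in c("energy", "sodium")) {
    sub <- diaries[diaries$nutrient == nut, ]
    row <- tab[tab$nutrient == nut, ]
    expect_equal(row$ref_mean, mean(sub$ref))
    expect_equal(row$app_sd, sd(sub$app))
    expect_equal(row$corr,
                 unname(cor(sub$ref, sub$app, method = row$corr_used)))
    expect_equal(row$ba_mean_diff, mean(sub$app - sub$ref))
    expect_equal(row$ba_loa_upper,
                 mean(sub$app - sub$ref) + 1.96 * sd(sub$app - sub$ref))
    p_expected <- if (row$test_used == "paired_t") {
      t.test(sub$ref, sub$app, paired = TRUE)$p.value
    } else {
      suppressWarnings(wilcox.test(sub$ref, sub$app, paired = TRUE)$p.value)
    }
    expect_equal(row$test_p, p_expected)
  }
})

test_that("agreement table stacks original and cleaned states", {
  cohort <- generate_cohort(synthetic_config(n_participants = 8, seed = 49))
  t1 <- cohort[cohort$phase == "T1", ]
  d_orig <- aggregate_daily_means(t1, "T1")
  limits <- learn_limits(t1)
  d_clean <- aggregate_daily_means(apply_limits(t1, limits)$entries, "T1")
  tab <- agreement_table(d_orig, d_clean)
  expect_equal(nrow(tab), 16)
  expect_equal(sort(unique(tab$state)), c("cleaned", "original"))
  expect_equal(sum(tab$state == "cleaned"), 8)
})

test_that("Bland-Altman plot data carries one point per participant", {
  cohort <- generate_cohort(synthetic_config(n_participants = 6, seed = 50))
  diaries <- aggregate_daily_means(cohort, "T2")
  bd <- bland_altman_data(diaries)
  expect_equal(nrow(bd), 6 * 8)
  e <- bd[bd$nutrient == "energy", ]
  sub <- diaries[diaries$nutrient == "energy", ]
  expect_equal(e$diff, sub$app - sub$ref)
  expect_equal(e$pair_mean, (sub$app + sub$ref) / 2)
  expect_equal(unique(e$mean_diff), mean(sub$app - sub$ref))
})
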