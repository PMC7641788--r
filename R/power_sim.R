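#' Analytic power of the two-sided correlation test
#'
#' Fisher-z approximation: with `h = atanh(rho)` and critical value
#' `z = qnorm(1 - alpha/2)`, power is
#' `pnorm(h*sqrt(n-3) - z) + pnorm(-h*sqrt(n-3) - z)`. At `rho = 0` this
#' reduces to the test size `alpha`.
#'
#' @param rho True correlation, `0 <= rho < 1` (vectorized).
#' @param n Sample size, `n >= 4`.
#' @param alpha Two-sided test size (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_corr_analytic <- function(rho, n, alpha = 0.05) {
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1)")
  if (any(n < 4)) stop("n must be >= 4")
  z <- qnorm(1 - alpha / 2)
  h <- atanh(rho) * sqrt(n - 3)
  pnorm(h - z) + pnorm(-h - z)
}

#' Configuration for the power simulation
#'
#' @param rho_grid Ascending grid of nutrient-outcome correlations for
#'   the reference measure; default 0.005 to 0.5 in steps of 0.005 (100
#'   points; 0 is excluded since power there is the test size).
#' @param reps Monte Carlo replicates per grid point (default 100).
#' @param alpha Two-sided test size.
#' @param n_list Sample sizes for analytic curves / inflation tables.
#' @param target_power Intended power (default 0.80).
#' @param seed RNG seed for the empirical mode.
#' @param mode `"empirical"` (simulated outcomes, rejection fractions) or
#'   `"analytic"` (Fisher-z closed form with attenuated correlation).
#' @return List of class `power_sim_config`.
#' @export
power_sim_config <- function(rho_grid = seq(0.005, 0.5, by = 0.005),
                             reps = 100,
                             alpha = 0.05,
                             n_list = c(50, 100, 500),
                             target_power = 0.80,
                             seed = 1L,
                             mode = c("empirical", "analytic")) {
  mode <- match.arg(mode)
  stopifnot(all(rho_grid > 0), all(rho_grid < 1),
            !is.unsorted(rho_grid, strictly = TRUE),
            reps >= 1, alpha > 0, alpha < 1,
            all(n_list >= 4),
            target_power > 0, target_power < 1)
  structure(list(rho_grid = rho_grid, reps = as.integer(reps), alpha = alpha,
                 n_list = n_list, target_power = target_power,
                 seed = as.integer(seed), mode = mode),
            class = "power_sim_config")
}

#' Simulate an outcome with a prescribed correlation to a reference
#'
#' Linear Gaussian channel: `O = rho * standardize(N) + sqrt(1 - rho^2) * e`
#' with `e` i.i.d. standard normal, so that `cor(N, O)` has expectation
#' `rho` when `N` is normal.
#'
#' @param n_vec Reference values (length >= 4, non-degenerate).
#' @param rho Target correlation.
#' @return Outcome vector of the same length.
#' @export
simulate_outcome <- function(n_vec, rho) {
  if (length(n_vec) < 4) stop("need at least 4 observations")
  s <- sd(n_vec)
  if (!is.finite(s) || s == 0) stop("n_vec has zero variance")
  z <- (n_vec - mean(n_vec)) / s
  rho * z + sqrt(1 - rho^2) * rnorm(length(n_vec))
}

# Rejection indicator of the two-sided correlation t test,
# t = r * sqrt((n-2) / (1-r^2)), vectorized over r.
reject_corr <- function(r, n, alpha) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  abs(tstat) > qt(1 - alpha / 2, n - 2)
}

#' Power curves for reference and app measures over the correlation grid
#'
#' Empirical mode: for each grid `rho` and each replicate, an outcome `O`
#' is simulated from the reference values `n_vec`; the correlation tests
#' of `(n_vec, O)` and `(m_vec, O)` are performed at `alpha`, and power
#' is the rejection fraction across replicates. Analytic mode: Fisher-z
#' power at `rho` for the reference and at `rho * r_nm` for the app
#' measure (attenuation under joint normality), for each `n` in
#' `config$n_list`.
#'
#' @param n_vec Reference values (empirical mode), or `NULL`.
#' @param m_vec App values paired with `n_vec`, or `NULL`.
#' @param config A [power_sim_config()].
#' @param r_nm Method-agreement correlation; required in analytic mode,
#'   computed as `cor(n_vec, m_vec)` when omitted in empirical mode
#'   reporting.
#' @return Tibble with columns `mode`, `n`, `rho`, `power_ref`,
#'   `power_app`, `r_nm`.
#' @export
power_curves <- function(n_vec = NULL, m_vec = NULL,
                         config = power_sim_config(), r_nm = NULL) {
  if (config$mode == "analytic") {
    if (is.null(r_nm)) {
      if (is.null(n_vec) || is.null(m_vec)) {
        stop("analytic mode needs r_nm or paired n_vec/m_vec")
      }
      r_nm <- cor(n_vec, m_vec)
    }
    stopifnot(r_nm > 0, r_nm <= 1)
    grids <- lapply(config$n_list, function(n) {
      tibble::tibble(
        mode = "analytic", n = n, rho = config$rho_grid,
        power_ref = power_corr_analytic(config$rho_grid, n, config$alpha),
        power_app = power_corr_analytic(config$rho_grid * r_nm, n,
                                        config$alpha),
        r_nm = r_nm
      )
    })
    return(dplyr::bind_rows(grids))
  }
  if (is.null(n_vec) || is.null(m_vec) || length(n_vec) != length(m_vec)) {
    stop("empirical mode needs paired n_vec and m_vec")
  }
  n <- length(n_vec)
  if (is.null(r_nm)) r_nm <- cor(n_vec, m_vec)
  set.seed(config$seed)
  zn <- (n_vec - mean(n_vec)) / sd(n_vec)
  zm <- (m_vec - mean(m_vec)) / sd(m_vec)
  power_ref <- numeric(length(config$rho_grid))
  power_app <- numeric(length(config$rho_grid))
  for (j in seq_along(config$rho_grid)) {
    rho <- config$rho_grid[j]
    eps <- matrix(rnorm(n * config$reps), n, config$reps)
    o <- rho * zn + sqrt(1 - rho^2) * eps        # n x reps
    o_c <- sweep(o, 2, colMeans(o), "-")
    o_norm <- sqrt(colSums(o_c^2))
    r_no <- as.vector(crossprod(zn - mean(zn), o_c)) /
      (sqrt(sum((zn - mean(zn))^2)) * o_norm)
    r_mo <- as.vector(crossprod(zm - mean(zm), o_c)) /
      (sqrt(sum((zm - mean(zm))^2)) * o_norm)
    power_ref[j] <- mean(reject_corr(r_no, n, config$alpha))
    power_app[j] <- mean(reject_corr(r_mo, n, config$alpha))
  }
  tibble::tibble(mode = "empirical", n = n, rho = config$rho_grid,
                 power_ref = power_ref, power_app = power_app, r_nm = r_nm)
}

#' Power lost at the intended power level
#'
#' Finds the smallest grid correlation `rho*` at which the (linearly
#' interpolated) reference power reaches `target_power`, then reports
#' `100 * (target_power - power_app(rho*))`: the percentage points of
#' power given up by using the app measure at the design point where the
#' reference measure attains the target.
#'
#' @param curve One power curve (single `n`) from [power_curves()].
#' @param target_power Intended power (default 0.80).
#' @return List: `rho_star`, `power_app_at_star`, `loss_points`.
#' @export
power_loss_at_target <- function(curve, target_power = 0.80) {
  stopifnot(dplyr::n_distinct(curve$n) == 1)
  curve <- dplyr::arrange(curve, .data$rho)
  p <- curve$power_ref
  if (max(p) < target_power) {
    stop(sprintf(
      "target power %.2f not reached on the grid (max attained %.3f)",
      target_power, max(p)))
  }
  i <- which(p >= target_power)[1]
  if (i == 1) {
    rho_star <- curve$rho[1]
  } else {
    # first upward crossing, linear interpolation
    rho_star <- curve$rho[i - 1] +
      (target_power - p[i - 1]) / (p[i] - p[i - 1]) *
        (curve$rho[i] - curve$rho[i - 1])
  }
  pm <- stats::approx(curve$rho, curve$power_app, xout = rho_star)$y
  list(rho_star = rho_star, power_app_at_star = pm,
       loss_points = 100 * (target_power - pm))
}

#' Attenuated-measure power loss, closed form
#'
#' Root-finds the design correlation `rho*` with
#' `power_corr_analytic(rho*, n) = target_power`, then evaluates the
#' Fisher-z power at the attenuated correlation `rho* * r_nm`.
#'
#' @param r_nm Method-agreement correlation, `0 < r_nm <= 1`.
#' @param n Sample size.
#' @param alpha Test size.
#' @param target_power Intended power.
#' @return List: `rho_star`, `power_app_at_star`, `loss_points`.
#' @export
power_loss_analytic <- function(r_nm, n, alpha = 0.05, target_power = 0.80) {
  stopifnot(r_nm > 0, r_nm <= 1)
  rho_star <- solve_rho_for_power(n, alpha, target_power)
  pm <- power_corr_analytic(rho_star * r_nm, n, alpha)
  list(rho_star = rho_star, power_app_at_star = pm,
       loss_points = 100 * (target_power - pm))
}

solve_rho_for_power <- function(n, alpha, target_power) {
  uniroot(function(r) power_corr_analytic(r, n, alpha) - target_power,
          lower = 1e-8, upper = 1 - 1e-8, tol = 1e-10)$root
}

#' Sample-size inflation needed to restore the intended power
#'
#' `rho*` solves `power(rho*, n) = target_power` for the reference
#' measure; `n'` is the smallest integer sample size at which the
#' attenuated correlation `rho* * r_nm` again attains the target. The
#' return value is `100 * (n' - n) / n`. As `n` grows this converges to
#' `100 * (1 / r_nm^2 - 1)`. Empirical mode replaces the closed-form
#' power with simulated rejection fractions (noisy for small `reps`).
#'
#' @param r_nm Method-agreement correlation, `0 < r_nm <= 1`.
#' @param n Baseline sample size for the reference measure.
#' @param target_power Intended power (default 0.80).
#' @param alpha Test size.
#' @param mode `"analytic"` or `"empirical"`.
#' @param reps,seed Empirical mode: replicates per power evaluation, seed.
#' @return Percent increase in sample size (>= 0).
#' @export
sample_size_inflation <- function(r_nm, n, target_power = 0.80, alpha = 0.05,
                                  mode = c("analytic", "empirical"),
                                  reps = 2000, seed = 1L) {
  mode <- match.arg(mode)
  if (r_nm <= 0 || r_nm > 1) stop("r_nm must be in (0, 1]")
  rho_star <- solve_rho_for_power(n, alpha, target_power)
  rho_att <- rho_star * r_nm
  if (mode == "analytic") {
    # continuous solution then smallest integer that attains the target
    h <- atanh(rho_att)
    z <- qnorm(1 - alpha / 2)
    n_cont <- ((z + qnorm(target_power)) / h)^2 + 3
    # tiny slack absorbs the root-finding tolerance at r_nm = 1
    eps <- 1e-9
    n_prime <- max(n, floor(n_cont))
    while (power_corr_analytic(rho_att, n_prime, alpha) < target_power - eps) {
      n_prime <- n_prime + 1
    }
    while (n_prime > n &&
           power_corr_analytic(rho_att, n_prime - 1, alpha) >=
             target_power - eps) {
      n_prime <- n_prime - 1
    }
  } else {
    set.seed(seed)
    n_prime <- n
    while (empirical_power(rho_att, n_prime, alpha, reps) < target_power) {
      n_prime <- n_prime + max(1L, ceiling(n_prime * 0.02))
    }
  }
  100 * (n_prime - n) / n
}

#' Empirical power of the correlation test under bivariate normality
#'
#' Rejection fraction of the two-sided correlation t test over `reps`
#' simulated bivariate-normal samples with true correlation `rho`.
#'
#' @param rho True correlation.
#' @param n Sample size.
#' @param alpha Test size.
#' @param reps Monte Carlo replicates.
#' @return Rejection fraction.
#' @export
empirical_power <- function(rho, n, alpha = 0.05, reps = 2000) {
  x <- matrix(rnorm(n * reps), n, reps)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * reps), n, reps)
  xc <- sweep(x, 2, colMeans(x), "-")
  yc <- sweep(y, 2, colMeans(y), "-")
  r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
  mean(reject_corr(r, n, alpha))
}

#' Construct paired vectors with an exact sample correlation
#'
#' Gram-Schmidt construction: returns `m` such that `cor(n_vec, m)`
#' equals `r` to machine precision. Useful for simulating a cohort whose
#' method-agreement correlation matches a published value exactly.
#'
#' @param n_vec Base vector.
#' @param r Desired sample correlation.
#' @return Vector `m` of the same length.
#' @export
correlated_with <- function(n_vec, r) {
  stopifnot(abs(r) <= 1, length(n_vec) >= 3)
  z <- as.vector(scale(n_vec))
  e <- rnorm(length(n_vec))
  e <- stats::residuals(lm(e ~ z))
  e <- as.vector(scale(e))
  r * z + sqrt(1 - r^2) * e
}
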