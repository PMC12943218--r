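test_that("percent activity follows the control-normalised formula", {
  expect_equal(percent_activity(0.800, 0.200), 75.0)
  expect_equal(percent_activity(0.800, 0.800), 0.0)
  expect_equal(percent_activity(0.800, 0.000), 100.0)
  expect_error(percent_activity(0, 0.1), "positive")
  # affine invariance under shared rescaling of both absorbances
  set.seed(3)
  ac <- runif(20, 0.2, 1); as_ <- runif(20, 0, 1)
  k <- 3.7
  expect_equal(percent_activity(ac, as_), percent_activity(k * ac, k * as_),
    tolerance = 1e-12)
})

test_that("noiseless 4PL data are recovered to high relative accuracy", {
  truth <- list(a = 0, d = 100, c = 10, b = 1.3)
  dr <- gen_dose_response(a = truth$a, d = truth$d, c = truth$c, b = truth$b,
    noise_sd = 0, seed = 2)
  fit <- fit_four_pl(dr)
  cf <- coef(fit)
  expect_equal(cf[["c"]], truth$c, tolerance = 1e-6)
  expect_equal(cf[["b"]], truth$b, tolerance = 1e-6)
  expect_equal(fit$ic50, truth$c, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # the fitted response at x = c is exactly midway between the asymptotes
  expect_equal(predict(fit, cf[["c"]]), (cf[["a"]] + cf[["d"]]) / 2,
    tolerance = 1e-8)
})

test_that("degenerate and underdetermined dose-response inputs error", {
  flat <- tibble::tibble(concentration = c(1, 2, 4, 8), activity = rep(50, 4))
  expect_error(fit_four_pl(flat), "Degenerate")
  few <- tibble::tibble(concentration = c(1, 1, 2, 2), activity = c(1, 2, 80, 81))
  expect_error(fit_four_pl(few), "4 distinct")
  neg <- tibble::tibble(concentration = c(-1, 1, 2, 4), activity = c(0, 10, 50, 90))
  expect_error(fit_four_pl(neg), "positive")
})

test_that("IC50 inversion is analytic and matches numerical root-finding", {
  expect_equal(estimate_ic50(c(a = 0, b = 2, c = 10, d = 100)), 10.0)
  cf <- c(a = 5, b = 1, c = 10, d = 95)
  f <- function(x) cf["d"] + (cf["a"] - cf["d"]) / (1 + (x / cf["c"])^cf["b"]) - 50
  root <- uniroot(f, c(1e-4, 1e4), tol = 1e-12)$root
  expect_equal(estimate_ic50(cf), root, tolerance = 1e-9)
  expect_error(estimate_ic50(c(a = 60, b = 1, c = 10, d = 95)), "cross")
})

test_that("IC50 agrees with root-finding for random admissible parameters", {
  set.seed(7)
  for (i in 1:25) {
    cf <- c(a = runif(1, 0, 20), b = runif(1, 0.3, 4), c = runif(1, 1, 50),
      d = runif(1, 80, 110))
    x <- estimate_ic50(cf)
    f <- function(z) cf["d"] + (cf["a"] - cf["d"]) / (1 + (z / cf["c"])^cf["b"]) - 50
    root <- uniroot(f, c(1e-6, 1e6), tol = 1e-13)$root
    expect_equal(x, root, tolerance = 1e-9)
  }
})

test_that("replicate refits give an IC50 dispersion estimate", {
  dr <- gen_dose_response(c = 8, b = 1.5, noise_sd = 2, seed = 11)
  fit <- fit_four_pl(dr)
  expect_false(is.na(fit$ic50_sd))
  expect_length(fit$replicate_ic50, 3)
  g <- glance(fit)
  expect_equal(g$ic50, fit$ic50)
  expect_equal(nrow(tidy(fit)), 4)
})

test_that("FRAP calibration inverts exactly and handles edge cases", {
  std <- gen_trolox_standards(slope = 0.002, intercept = 0.05, noise_sd = 0)
  res <- frap_trolox_equivalents(std, sample_abs = 0.25, mass_factor = 1)
  expect_equal(res$te_per_gram, 100.0, tolerance = 1e-9)
  expect_equal(res$slope, 0.002, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(frap_trolox_equivalents(std, 0.05)$te_per_gram, 0,
    tolerance = 1e-9)
  # mass factor scales the per-gram value
  expect_equal(frap_trolox_equivalents(std, 0.25, mass_factor = 0.5)$te_per_gram,
    200, tolerance = 1e-9)
  expect_error(frap_trolox_equivalents(std[1:2, ], 0.2), "3")
  sing <- tibble::tibble(concentration = rep(5, 4), absorbance = 1:4)
  expect_error(frap_trolox_equivalents(sing, 0.2), "Singular")
})

test_that("noisy calibration recovers the slope within 2 standard errors", {
  std <- gen_trolox_standards(slope = 0.002, intercept = 0.05,
    noise_sd = 0.01, n = 12, seed = 13)
  fit <- lm(absorbance ~ concentration, data = std)
  se <- summary(fit)$coefficients["concentration", "Std. Error"]
  res <- frap_trolox_equivalents(std, 0.25)
  expect_lt(abs(res$slope - 0.002), 2 * se + 1e-12)
})

test_that("ANOVA with Tukey flags separated groups and rejects bad input", {
  set.seed(17)
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = 3),
    value = c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1))
  )
  res <- anova_tukey(d)
  expect_lt(res$overall$p_value, 0.001)
  expect_equal(res$pairwise$significance, "***")

  expect_error(anova_tukey(list(a = 1:3)), "2 groups")
  expect_error(anova_tukey(list(a = c(1, 2), b = 3)), "replicates")
  expect_error(anova_tukey(list(a = c(1, 1), b = c(2, 2))), "variance")
  # list interface agrees with data-frame interface
  res2 <- anova_tukey(list(a = d$value[1:3], b = d$value[4:6]))
  expect_equal(res2$overall$f_statistic, res$overall$f_statistic)
})

test_that("Tukey-adjusted p-values are no smaller than unadjusted pairwise p", {
  set.seed(19)
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 5),
    value = rnorm(15) + rep(c(0, 0.5, 1.5), each = 5)
  )
  res <- anova_tukey(d)
  raw <- pairwise.t.test(d$value, d$group, p.adjust.method = "none",
    pool.sd = TRUE)$p.value
  raw_p <- c(`b-a` = raw["b", "a"], `c-a` = raw["c", "a"], `c-b` = raw["c", "b"])
  adj <- setNames(res$pairwise$p_adj, res$pairwise$contrast)
  expect_true(all(adj[names(raw_p)] >= raw_p - 1e-10))
})
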