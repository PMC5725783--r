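test_that("LRT arithmetic, clamping and monotonicity", {
  r <- lrt(-100, -95, 1)
  expect_equal(r$stat, 10)
  expect_equal(r$p, stats::pchisq(10, 1, lower.tail = FALSE))
  expect_equal(lrt(-100, -100, 3)$p, 1)
  expect_warning(r2 <- lrt(-100, -100.0001, 1), "clamped")
  expect_equal(r2$stat, 0)
  expect_error(lrt(-100, -120, 1), "mis-ordered")
  expect_error(lrt(-100, -95, 0), "df")
  ## p decreases as the statistic grows (fixed df)
  stats <- seq(0.5, 30, by = 0.5)
  ps <- vapply(stats, function(s) lrt(-100, -100 + s / 2, 2)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BIC matches its closed form and ranking ignores constants", {
  expect_equal(bic(0, 0, 100), 0)
  expect_equal(bic(-11887.4, 149, 354.67, logBase = 10),
               2 * 11887.4 + 149 * log10(354.67))
  expect_equal(bic(-500, 10, 354.67, logBase = exp(1)),
               1000 + 10 * log(354.67))
  expect_error(bic(NA, 1, 10), "finite")
  ## adding a constant to all lnL values cannot change the ranking
  lnL <- c(-1000, -995, -990); K <- c(3, 5, 9)
  b1 <- mapply(bic, lnL, K, n = 354.67)
  b2 <- mapply(bic, lnL + 123.4, K, n = 354.67)
  expect_identical(order(b1), order(b2))
})

test_that("model comparison tables mark the lowest BIC and apply df defaults", {
  mkFit <- function(model, lnL, K, omega) {
    new("CodonFitResult", model = model, logLik = lnL,
        estimates = list(kappa = 2, omega = omega), K = as.integer(K),
        convergence = list(status = "converged"), details = list())
  }
  fits <- list(
    "1w" = mkFit("M0", -11887.4, 149, c(all = 0.151)),
    "2w" = mkFit("branch", -11778.4, 150, c(`non-snake` = 0.094,
                                            snake = 0.414)),
    "3w" = mkFit("branch", -11765.1, 151, c(`non-snake` = 0.094,
                                            henophidian = 0.149,
                                            colubrid = 0.498)))
  cmp <- compareModels(fits, list(c("1w", "2w"), c("2w", "3w")), n = 354.67)
  expect_s4_class(cmp$table, "ModelComparisonTable")
  expect_equal(cmp$table@best, "3w")
  expect_equal(which.min(cmp$table@table$BIC),
               match("3w", cmp$table@table$model))
  expect_equal(cmp$lrt$df, c(1, 1))
  expect_equal(cmp$lrt$stat[1], 2 * (11887.4 - 11778.4))
  ## BIC column recomputable from lnL, K and n
  expect_equal(cmp$table@table$BIC,
               mapply(bic, cmp$table@table$lnL, cmp$table@table$K,
                      n = 354.67))
  expect_error(compareModels(fits, list(c("1w", "9w")), n = 100), "absent")
  ## explicit df override for the branch-site convention
  cmp2 <- compareModels(fits, list(list(null = "1w", alt = "2w", df = 2)),
                        n = 354.67)
  expect_equal(cmp2$lrt$df, 2)
})

test_that("report formatting follows the table conventions", {
  f <- formatLrt(c(22.4, 7.6), c(2e-6, 0.0058))
  expect_equal(f$stat, c("22", "7.6"))
  expect_equal(f$p[1], "<1e-05")
})
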