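# Agreement statistics.

test_that("ROI statistics match hand computations", {
  vals <- matrix(0.25, 8, 8)
  r <- roi(matrix(TRUE, 8, 8))
  st <- roi_stats(vals, r)
  expect_equal(st$mean, 0.25)
  expect_equal(st$std, 0)
  # two-pixel ROI, sample standard deviation with n - 1
  v2 <- matrix(0, 4, 4); v2[1, 1] <- 0.1; v2[2, 1] <- 0.3
  m2 <- matrix(FALSE, 4, 4); m2[1:2, 1] <- TRUE
  st2 <- roi_stats(v2, roi(m2))
  expect_equal(st2$mean, 0.2)
  expect_equal(st2$std, sqrt(sum((c(0.1, 0.3) - 0.2)^2) / 1))
  expect_equal(st2$std, 0.1414214, tolerance = 1e-6)
})

test_that("ROI outside the map mask raises an error", {
  pd <- structure(list(values = matrix(0.1, 4, 4),
                       mask = matrix(FALSE, 4, 4)), class = "pdff_map")
  expect_error(roi_stats(pd, roi(matrix(TRUE, 4, 4))), "intersect")
  expect_error(roi(matrix(FALSE, 2, 2)), "empty")
})

test_that("least-squares regression recovers exact linear relations", {
  x <- c(1, 2, 3)
  r <- ls_regression(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  r2 <- ls_regression(x, 2 * x + 1)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 1, tolerance = 1e-12)
  expect_error(ls_regression(c(1, 1, 1), x), "zero variance")
  expect_error(ls_regression(1:2, 1:2), "at least 3")
})

test_that("regression matches the closed-form normal equations", {
  set.seed(8)
  x <- rnorm(20); y <- 0.8 * x + 0.1 + rnorm(20, sd = 0.3)
  r <- ls_regression(x, y)
  # independent normal-equation solution
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  expect_equal(r$slope, slope, tolerance = 1e-10)
  expect_equal(r$intercept, intercept, tolerance = 1e-10)
  expect_equal(r$r_squared, (sxy^2) / (sxx * sum((y - mean(y))^2)),
               tolerance = 1e-10)
  # invariant to reordering of the paired points
  o <- sample(20)
  r_perm <- ls_regression(x[o], y[o])
  expect_equal(r_perm$slope, r$slope, tolerance = 1e-12)
  expect_equal(r_perm$r_squared, r$r_squared, tolerance = 1e-12)
})

test_that("Bland-Altman limits follow the 1.96-sigma convention", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  ba0 <- bland_altman(x, x)
  expect_equal(unlist(ba0), c(bias = 0, loa_low = 0, loa_high = 0))
  ba1 <- bland_altman(x, x + 0.5)
  expect_equal(ba1$bias, 0.5)
  expect_equal(ba1$loa_low, 0.5)
  expect_equal(ba1$loa_high, 0.5)
  # d = (-1, 0, 1): sample sd is exactly 1
  ba2 <- bland_altman(c(1, 2, 3), c(0, 2, 4))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_low, -1.96)
  expect_equal(ba2$loa_high, 1.96)
  expect_error(bland_altman(1:4, 1:5), "equal length")
})

test_that("identical groups show no significant pairs", {
  g <- list(a = c(0.01, 0.02, 0.015, 0.018),
            b = c(0.01, 0.02, 0.015, 0.018))
  res <- anova_posthoc_std(g)
  expect_false(any(res$pairs$significant))
  # fully degenerate input returns p = 1 with a flag
  gd <- list(a = rep(0.5, 3), b = rep(0.5, 3))
  resd <- anova_posthoc_std(gd)
  expect_true(resd$degenerate)
  expect_equal(resd$pairs$p, 1)
})

test_that("a large separation between groups is flagged significant", {
  set.seed(5)
  g <- list(low = rnorm(20, 0.01, 0.001), high = rnorm(20, 0.05, 0.001))
  res <- anova_posthoc_std(g, alpha = 0.05)
  expect_true(all(res$pairs$significant))
  expect_lt(res$anova_p, 1e-6)
})

test_that("Tukey p-values match an independent studentized-range computation", {
  set.seed(17)
  g <- list(a = rnorm(8, 0.02, 0.005), b = rnorm(10, 0.025, 0.005),
            c = rnorm(9, 0.021, 0.005))
  res <- anova_posthoc_std(g)
  # published-formula oracle: q = |mi - mj| / sqrt((MSE/2)(1/ni + 1/nj)),
  # p = P(Q_{k,df} > q) via the studentized range distribution
  k <- length(g)
  ns <- vapply(g, length, integer(1))
  ms <- vapply(g, mean, numeric(1))
  df_err <- sum(ns) - k
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) / df_err
  oracle_p <- function(i, j) {
    q <- abs(ms[i] - ms[j]) / sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    stats::ptukey(q, k, df_err, lower.tail = FALSE)
  }
  want <- unname(c(oracle_p(1, 2), oracle_p(1, 3), oracle_p(2, 3)))
  got <- res$pairs$p[match(c("b-a", "c-a", "c-b"), res$pairs$comparison)]
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("map-level MAE isolates the perturbed channel", {
  maps <- random_maps(8, 3)
  expect_equal(unlist(mae_map(maps, maps)),
               c(water = 0, fat = 0, r2star_per_s = 0, fieldmap_hz = 0,
                 pdff = 0))
  shifted <- maps
  shifted$fieldmap_hz <- maps$fieldmap_hz + 10
  mm <- mae_map(shifted, maps)
  expect_equal(mm$fieldmap_hz, 10, tolerance = 1e-12)
  expect_equal(mm$water, 0)
  expect_equal(mm$pdff, 0)
  # elementwise-loop oracle on a random pair
  other <- random_maps(8, 4)
  mm2 <- mae_map(other, maps)
  acc <- 0; nn <- 0
  for (i in 1:8) for (j in 1:8) {
    acc <- acc + abs(other$r2star_per_s[i, j] - maps$r2star_per_s[i, j])
    nn <- nn + 1
  }
  expect_equal(mm2$r2star_per_s, acc / nn, tolerance = 1e-10)
  expect_error(mae_map(maps, maps, mask = matrix(FALSE, 8, 8)), "empty")
})

test_that("agreement report composes all statistics coherently", {
  set.seed(2)
  ref <- runif(26, 0.04, 0.36)
  tst <- 0.95 * ref + 0.005 + rnorm(26, sd = 0.01)
  rep_ <- agreement_report(ref, tst, runif(26, 0.005, 0.02),
                           runif(26, 0.005, 0.02))
  expect_s3_class(rep_, "agreement_report")
  expect_true(rep_$bland_altman_percent$loa_low <=
                rep_$bland_altman_percent$bias)
  expect_true(rep_$bland_altman_percent$bias <=
                rep_$bland_altman_percent$loa_high)
  expect_gte(rep_$regression$r_squared, 0)
  expect_lte(rep_$regression$r_squared, 1)
  expect_output(print(rep_), "Bland-Altman")
})
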