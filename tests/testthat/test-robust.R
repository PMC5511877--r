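test_that("projection rule flags a gross bivariate outlier and nothing else", {
  set.seed(1)
  x <- rnorm(49, sd = 1); y <- 0.5 * x + rnorm(49, sd = 0.5)
  x <- c(x, 20); y <- c(y, -20)  # ~20 robust SDs away
  out <- detectBivariateOutliers(x, y, seed = 2)
  expect_true(50 %in% out)
  expect_lte(length(setdiff(out, 50)), 2)
})

test_that("clean bivariate Gaussians are flagged at a low rate", {
  rates <- vapply(1:20, function(k) {
    set.seed(100 + k)
    x <- rnorm(50); y <- rnorm(50)
    length(detectBivariateOutliers(x, y, seed = k)) / 50
  }, numeric(1))
  expect_lt(mean(rates), 0.08)
})

test_that("degenerate and tiny inputs are handled", {
  expect_identical(detectBivariateOutliers(rep(1, 20), rep(2, 20)), integer())
  expect_message(out <- detectBivariateOutliers(rnorm(5), rnorm(5)),
                 "fewer than 10")
  expect_identical(out, integer())
})

test_that("outlier detection is deterministic under its seed", {
  set.seed(3)
  x <- c(rnorm(30), 8); y <- c(rnorm(30), -8)
  expect_identical(detectBivariateOutliers(x, y, seed = 5),
                   detectBivariateOutliers(x, y, seed = 5))
})

test_that("skipped correlation is exact Pearson when nothing is flagged", {
  set.seed(4)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, sd = 0.4)
  sk <- skippedCorrelation(x, y, n_boot = 0, seed = 1)
  if (length(sk@outlier_indices) == 0)
    expect_identical(sk@r, cor(x, y))
  # perfect linearity
  expect_equal(skippedCorrelation(x, 2 * x, n_boot = 0)@r, 1.0)
  # forced plain mode equals Pearson by construction
  expect_identical(skippedCorrelation(x, y, n_boot = 0, skip = FALSE)@r,
                   cor(x, y))
})

test_that("a gross leverage point flips plain Pearson but not the skipped r", {
  set.seed(5)
  n <- 30
  x <- rnorm(n)
  y <- -0.5 * x + rnorm(n, sd = 0.7)
  x <- c(x, 12); y <- c(y, 12)  # leverage point pulling r positive
  plain <- cor(x, y)            # plain-Pearson oracle computed alongside
  expect_gt(plain, 0)
  sk <- skippedCorrelation(x, y, n_boot = 0, seed = 6)
  expect_lt(sk@r, 0)
  expect_true((n + 1) %in% sk@outlier_indices)
})

test_that("bootstrap CI is ordered, seed-stable, and excludes 0 on strong signal", {
  set.seed(7)
  x <- rnorm(25); y <- 0.9 * x + rnorm(25, sd = 0.3)
  a <- skippedCorrelation(x, y, n_boot = 500, seed = 8)
  b <- skippedCorrelation(x, y, n_boot = 500, seed = 8)
  expect_identical(a@ci, b@ci)
  expect_lte(a@ci[1], a@ci[2])
  expect_gt(a@ci[1], 0)
  expect_error(skippedCorrelation(rnorm(3), rnorm(3), n_boot = 0), "4 retained")
})

test_that("holding the outlier set fixed in the bootstrap is anti-conservative", {
  # why strict mode is the default: with the outlier set fixed, the 95% CI
  # excludes zero on null data far above the nominal 5% rate, while the
  # calibrated significance decision stays near nominal
  out <- vapply(1:150, function(k) {
    set.seed(9000 + k)
    x <- rnorm(22); y <- rnorm(22)
    sk <- suppressMessages(skippedCorrelation(x, y, n_boot = 300, seed = k,
                                              strict = FALSE))
    c(ci = isTRUE(sk@ci[1] > 0 || sk@ci[2] < 0), sig = isTRUE(sk@significant))
  }, logical(2))
  expect_gte(mean(out["ci", ]), 0.12)
  expect_lte(mean(out["sig", ]), 0.12)
})

test_that("corrected CI levels follow the Bonferroni convention", {
  expect_equal(as.numeric(correctedCILevel(12)), 99.6)
  expect_equal(as.numeric(correctedCILevel(1)), 95.0)
  lev6 <- correctedCILevel(6)
  expect_equal(as.numeric(lev6), 99.2)
  expect_equal(attr(lev6, "sidak"), 99.1)
  expect_error(correctedCILevel(0), ">= 1")
  # monotonicity
  levs <- vapply(1:10, function(n) as.numeric(correctedCILevel(n)), numeric(1))
  expect_true(all(diff(levs) >= 0))
  expect_gt(as.numeric(correctedCILevel(4, 0.01)),
            as.numeric(correctedCILevel(4, 0.05)))
})

test_that("item-split control is deterministic and tracks the planted sign", {
  co <- makeCohort(n_subjects = 40, seed = 9,
                   truth = cohortTruth(planted_rho_negative = -0.7))
  a <- itemSplitCorrelation(co$behavior$tnt, co$behavior$final, n_iter = 60,
                            seed = 10)
  b <- itemSplitCorrelation(co$behavior$tnt, co$behavior$final, n_iter = 60,
                            seed = 10)
  expect_identical(a$r, b$r)
  expect_lt(a$mean_r, 0)
  expect_lte(a$ci[1], a$ci[2])
})

test_that("item-split mean approaches the full-item skipped r with many items", {
  co <- makeCohort(n_subjects = 60, seed = 12,
                   truth = cohortTruth(planted_rho_negative = -0.7),
                   cues_per_condition_per_valence = 16,
                   baseline_pairs_per_valence = 16)
  sc <- scoreSubjects(co$behavior)
  neg <- sc[sc$valence == "negative", ]
  full <- skippedCorrelation(neg$intrusion_proportion, neg$affect_suppression,
                             n_boot = 0, seed = 1)@r
  spl <- itemSplitCorrelation(co$behavior$tnt, co$behavior$final, n_iter = 60,
                              seed = 13)
  expect_lt(abs(spl$mean_r - full), 0.25)
  expect_lt(spl$mean_r, 0)
})
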