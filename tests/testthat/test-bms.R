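test_that("a large evidence gap drives the exceedance probability to 1", {
  F <- cbind(rep(10, 8), rep(0, 8))
  b <- rfxBMS(F, seed = 1)
  expect_gt(exceedanceProb(b)[1], 0.99)
  expect_gt(expectedPosteriorProb(b)[1], 0.8)
})

test_that("identical evidence gives symmetric EP = 1/K and valid normalization", {
  for (K in c(2, 5)) {
    F <- matrix(0, 10, K)
    b <- rfxBMS(F, seed = 2, n_samples = 2e5)
    expect_equal(sum(exceedanceProb(b)), 1, tolerance = 1e-9)
    expect_equal(sum(expectedPosteriorProb(b)), 1, tolerance = 1e-9)
    expect_equal(exceedanceProb(b), rep(1 / K, K), tolerance = 0.02)
    expect_true(all(b@alpha >= b@alpha0 - 1e-9))
  }
  expect_error(rfxBMS(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("EP sampling is deterministic under the seed", {
  F <- matrix(rnorm(30), 10, 3)
  expect_identical(exceedanceProb(rfxBMS(F, seed = 5)),
                   exceedanceProb(rfxBMS(F, seed = 5)))
})

test_that("family inference handles edge cases and size correction", {
  F <- matrix(0, 12, 7)
  # single family covering everything
  one <- familyInference(F, list(all = 1:7), seed = 3)
  expect_equal(exceedanceProb(one), c(all = 1))
  # equal evidence with sizes 1/3/3 under the size-corrected prior
  fams <- list(Emotion = 1L, Memory = 2:4, Parallel = 5:7)
  fb <- familyInference(F, fams, seed = 4, n_samples = 2e5)
  expect_equal(sum(exceedanceProb(fb)), 1, tolerance = 1e-9)
  expect_equal(unname(exceedanceProb(fb)), rep(1 / 3, 3), tolerance = 0.06)
  expect_error(familyInference(F, list(a = 1:4, b = 4:7)), "overlapping")
  expect_error(familyInference(F, list(a = 1:3, b = 5:7)), "partition")
})

test_that("family inference recovers a strongly favored family", {
  set.seed(6)
  F <- matrix(rnorm(10 * 7, sd = 0.5), 10, 7)
  F[, 6] <- F[, 6] + 8  # one Parallel member dominates
  fams <- list(Emotion = 1L, Memory = 2:4, Parallel = 5:7)
  fb <- familyInference(F, fams, seed = 7)
  expect_equal(names(which.max(exceedanceProb(fb))), "Parallel")
  expect_gt(exceedanceProb(fb)["Parallel"], 0.9)
})

test_that("BMA is the identity for one model and the mean for equal weights", {
  m <- dcmModel("top-down", "Hip", regions = c("MFG", "Hip"))
  mkfit <- function(a21, f) {
    A <- matrix(c(-0.5, a21, 0.1, -0.5), 2, 2,
                dimnames = list(c("MFG", "Hip"), c("MFG", "Hip")))
    new(Class = "DCMFit", model = m, theta = numeric(), Sigma = diag(1),
        A = A, B = list(matrix(0, 2, 2), matrix(0, 2, 2)),
        C = matrix(0, 2, 2), free_energy = f, sigma2 = c(1, 1),
        converged = TRUE)
  }
  single <- bmaParameters(list(list(mkfit(0.3, -5))))
  expect_equal(single[[1]]$A["Hip", "MFG"], 0.3)
  equal <- bmaParameters(list(list(mkfit(0.2, -5), mkfit(0.6, -5))))
  expect_equal(equal[[1]]$A["Hip", "MFG"], 0.4)
  expect_equal(equal[[1]]$weights, c(0.5, 0.5))
})

test_that("coupling bootstrap CIs behave on degenerate and planted inputs", {
  zeros <- matrix(0, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  bz <- couplingBootstrap(zeros, n_boot = 200, seed = 1)
  expect_equal(bz$ci_low, rep(0, 3))
  expect_equal(bz$ci_high, rep(0, 3))
  expect_false(any(bz$significant))
  # parameters drawn around -0.5 exclude zero at the corrected level
  set.seed(2)
  p <- matrix(rnorm(21 * 12, mean = -0.5, sd = 0.1), 21, 12)
  bp <- couplingBootstrap(p, n_boot = 500, n_comparisons = 12, seed = 3)
  expect_true(all(bp$significant))
  expect_equal(attr(bp, "level"), 99.6)
  # determinism
  bp2 <- couplingBootstrap(p, n_boot = 500, n_comparisons = 12, seed = 3)
  expect_identical(bp$ci_low, bp2$ci_low)
  expect_error(couplingBootstrap(p[1:4, ], n_boot = 10), "at least 5")
})

test_that("the aberrant-subject rule drops extreme rows before resampling", {
  set.seed(4)
  p <- matrix(rnorm(20 * 3, sd = 0.1), 20, 3)
  p[7, 2] <- 50
  b <- couplingBootstrap(p, n_boot = 100, seed = 5, exclude_outliers = TRUE)
  expect_identical(attr(b, "excluded"), 7L)
})
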