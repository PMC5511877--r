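test_that("preprocessing enforces the documented normalizations", {
  set.seed(1)
  X <- matrix(rnorm(60), 6, 10)
  Y <- matrix(rnorm(12), 6, 2)
  pp <- plsPreprocess(X, Y)
  expect_equal(unname(rowSums(pp$X^2)), rep(1, 6))
  expect_equal(unname(colMeans(pp$Y)), c(0, 0))
  expect_equal(unname(apply(pp$Y, 2, sd)), c(1, 1))
  # rows-first mode leaves X columns exactly centered
  pr <- plsPreprocess(X, Y, mode = "rows-first")
  expect_equal(unname(colMeans(pr$X)), rep(0, 10))
  # the two orders differ only slightly (O(1/N) de-centering)
  expect_lt(max(abs(colMeans(pp$X))), 0.2)
  expect_error(plsPreprocess(X, cbind(Y[, 1], 1)), "zero-variance")
  X0 <- matrix(0, 6, 10); X0[1, 1] <- 1  # rows 2..6 cannot be normalized
  expect_error(plsPreprocess(X0, Y, mode = "rows-first"), "all-zero")
})

test_that("cross-block entries match hand arithmetic", {
  # 3 subjects x 2 voxels, 1 measure; small enough to multiply by hand
  Xp <- matrix(c(1, 0, -1,
                 2, -1, -1), 3, 2)
  Yp <- matrix(c(0.5, -1, 0.5), 3, 1)
  R <- crossBlock(Xp, Yp)
  expect_equal(as.numeric(R),
               c(0.5 * 1 + (-1) * 0 + 0.5 * (-1),
                 0.5 * 2 + (-1) * (-1) + 0.5 * (-1)))
  # a Y column equal to an X column picks up that column's squared norm
  Yp2 <- Xp[, 2, drop = FALSE]
  expect_equal(crossBlock(Xp, Yp2)[1, 2], sum(Xp[, 2]^2))
  # orthogonal column gives a zero row
  Yo <- matrix(c(1, 1, 1), 3, 1)
  Xo <- matrix(c(1, -1, 0), 3, 1)
  expect_equal(as.numeric(crossBlock(Xo, Yo)), 0)
})

test_that("decomposition matches a brute-force eigendecomposition oracle", {
  set.seed(2)
  R <- matrix(rnorm(100), 2, 50)
  dec <- plsDecompose(R)
  ev <- eigen(R %*% t(R))
  expect_equal(dec$d, sqrt(pmax(ev$values, 0)), tolerance = 1e-10)
  # conservation and orthonormality
  expect_equal(sum(dec$d^2), sum(R^2), tolerance = 1e-10)
  expect_equal(crossprod(dec$u), diag(2), tolerance = 1e-10)
  expect_equal(crossprod(dec$v), diag(2), tolerance = 1e-10)
  expect_equal(sum(dec$explained), 1)
  # deterministic sign convention: largest |u| entry positive per LV
  for (k in 1:2) expect_gt(dec$u[which.max(abs(dec$u[, k])), k], 0)
})

test_that("rank-1 and symmetric matrices give the expected spectra", {
  u <- c(0.6, 0.8); v <- rnorm(30); v <- v / sqrt(sum(v^2))
  dec <- plsDecompose(3 * u %*% t(v))
  expect_equal(dec$explained[1], 1, tolerance = 1e-12)
  expect_equal(dec$d[1], 3, tolerance = 1e-12)
  dec2 <- plsDecompose(diag(2))
  expect_equal(dec2$explained, c(0.5, 0.5))
})

test_that("brain scores recover a planted rank-1 subject ordering", {
  set.seed(3)
  s <- rnorm(12)
  v <- rnorm(40); v <- v / sqrt(sum(v^2))
  Xp <- s %*% t(v)
  scores <- Xp %*% as.matrix(v)
  expect_equal(as.numeric(scores), s, tolerance = 1e-12)
  # orthogonal subject row projects to zero
  v2 <- rnorm(40); v2 <- v2 - sum(v2 * v) * v
  expect_equal(as.numeric(v2 %*% v), 0, tolerance = 1e-10)
})

test_that("full PLS on planted structure finds one dominant significant LV", {
  set.seed(4)
  truth <- latentBrainTruth(n_voxels = 400, n_mfg = 40, n_mtl = 20)
  sc <- data.frame(subject = 1:22,
                   intrusion_proportion = runif(22, 0.1, 0.6))
  sc$affect_suppression <- -0.6 * scale(sc$intrusion_proportion)[, 1] * 0.1 +
    rnorm(22, sd = 0.08)
  bm <- generateBrain(sc, truth, seed = 5)
  res <- behavioralPLS(bm, sc[, c("intrusion_proportion", "affect_suppression")],
                       n_perm = 200, n_boot = 200, seed = 6)
  expect_lte(permutationP(res)[1], 0.05)
  expect_gt(explainedCovariance(res)[1], 0.5)
  cos <- abs(sum(voxelSaliences(res)[, 1] * truth@salience_vector))
  expect_gt(cos, 0.9)
  # score/behavior correlations carry ordered CIs
  sb <- res@score_behavior
  expect_true(all(sb$ci_low <= sb$ci_high))
  # u sign convention makes the largest behavioral salience positive
  expect_gt(max(res@u[, 1]), 0)
})

test_that("permutation and bootstrap are deterministic under the seed", {
  set.seed(7)
  X <- matrix(rnorm(22 * 50), 22, 50)
  Y <- matrix(rnorm(44), 22, 2)
  p1 <- plsPermutation(X, Y, n_perm = 120, seed = 9)
  p2 <- plsPermutation(X, Y, n_perm = 120, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  b1 <- plsBootstrapBSR(X, Y, n_boot = 120, seed = 9)
  b2 <- plsBootstrapBSR(X, Y, n_boot = 120, seed = 9)
  expect_identical(b1$bsr, b2$bsr)
})

test_that("BSR separates planted-support from background voxels", {
  set.seed(10)
  truth <- latentBrainTruth(n_voxels = 500, n_mfg = 50, n_mtl = 25)
  sc <- data.frame(subject = 1:22, intrusion_proportion = runif(22, 0.1, 0.6))
  sc$affect_suppression <- -0.6 * scale(sc$intrusion_proportion)[, 1] * 0.1 +
    rnorm(22, sd = 0.08)
  bm <- generateBrain(sc, truth, seed = 11)
  bsr <- plsBootstrapBSR(brainX(bm),
                         as.matrix(sc[, c("intrusion_proportion",
                                          "affect_suppression")]),
                         n_boot = 300, seed = 12)$bsr[, 1]
  sup <- truth@salience_vector != 0
  expect_gte(mean(abs(bsr[sup]) > 1.96), 0.8)
  expect_lte(mean(abs(bsr[!sup]) > 1.96), 0.1)
})

test_that("score/behavior correlation is near 1 for a rank-1 construction", {
  # operate on an already-preprocessed X' = s v^T: brain scores X'v equal s
  # exactly, so their correlation with the planted behavior is 1
  set.seed(13)
  s <- rnorm(16)
  v <- rnorm(60); v <- v / sqrt(sum(v^2))
  Xp <- s %*% t(v)
  Yp <- cbind(behavior = s)
  dec <- plsDecompose(crossBlock(Xp, Yp))
  scores <- Xp %*% dec$v
  sb <- scoreBehaviorCorrelations(scores, Yp, n_boot = 100, seed = 2)
  expect_gt(abs(sb$r[1]), 0.999)
  expect_true(all(sb$ci_low <= sb$ci_high))
  # null data: CI straddles zero most of the time (calibration sanity)
  covered <- mean(vapply(1:30, function(k) {
    set.seed(300 + k)
    a <- rnorm(22); b <- rnorm(22)
    out <- scoreBehaviorCorrelations(cbind(a), cbind(b), n_boot = 200,
                                     seed = k)
    out$ci_low < 0 && out$ci_high > 0
  }, logical(1)))
  expect_gte(covered, 0.8)
})
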