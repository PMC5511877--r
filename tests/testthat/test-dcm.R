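# single-region closed form: dz/dt = a z, z(0) = c -> z(t) = c exp(a t)
test_that("integrator matches the closed-form exponential decay", {
  inp <- dcmInputs(20, dt = 0.01, events = list(data.frame(onset = numeric(0))))
  A <- matrix(-1, 1, 1)
  sim <- dcmSimulate(A, list(matrix(0, 1, 1)), matrix(0, 1, 1), inp, z0 = 2)
  t <- (seq_len(nrow(sim$neural)) - 1) * 0.01
  expect_lt(max(abs(sim$neural[, 1] - 2 * exp(-t))), 1e-6)
})

test_that("integrator halving the step changes the solution by < 1e-5", {
  A <- matrix(c(-0.6, 0.3, 0.2, -0.7), 2, 2)
  ev1 <- data.frame(onset = c(4, 16), duration = 3)
  inp1 <- dcmInputs(40, dt = 0.1, events = list(ev1))
  inp2 <- dcmInputs(40, dt = 0.05, events = list(ev1))
  C <- matrix(c(1, 0), 2, 1)
  s1 <- dcmSimulate(A, list(matrix(0, 2, 2)), C, inp1)
  s2 <- dcmSimulate(A, list(matrix(0, 2, 2)), C, inp2)
  # compare neural states on the shared (coarse) grid
  z1 <- s1$neural
  z2 <- s2$neural[seq(1, nrow(s2$neural), by = 2), ]
  rel <- max(abs(z1 - z2)) / max(abs(z1))
  expect_lt(rel, 1e-5)
})

test_that("superposition holds in the linear regime (B = 0)", {
  A <- matrix(c(-0.5, 0.2, 0.1, -0.6), 2, 2)
  inp <- dcmInputs(60, events = list(data.frame(onset = c(5, 25), duration = 3)))
  C1 <- matrix(c(1, 0), 2, 1)
  s1 <- dcmSimulate(A, list(matrix(0, 2, 2)), C1, inp)
  s2 <- dcmSimulate(A, list(matrix(0, 2, 2)), 2 * C1, inp)
  expect_equal(2 * s1$bold, s2$bold, tolerance = 1e-10)
})

test_that("unstable intrinsic matrices are rejected with the eigenvalue named", {
  A <- matrix(c(0.1, 0, 0, -1), 2, 2)
  inp <- dcmInputs(10, events = list(data.frame(onset = 1)))
  expect_error(dcmSimulate(A, list(matrix(0, 2, 2)), matrix(0, 2, 1), inp),
               "unstable.*eigenvalue")
})

test_that("model space enumerates the documented grid", {
  expect_length(buildModelSpace(), 29)  # 4 types x 7 subsets + null
  expect_length(buildModelSpace(c("top-down", "bidirectional"),
                                include_null = FALSE), 14)
  models <- buildModelSpace("top-down", include_null = FALSE)
  fam <- vapply(models, function(m) m@regulation_family, character(1))
  expect_equal(as.vector(table(fam)[c("Emotion", "Memory", "Parallel")]),
               c(1L, 3L, 3L))
  expect_error(buildModelSpace(target_sets = list(character())), "empty")
  # afferent models put extra driving entries, not modulation
  aff <- dcmModel("afferent", c("Hip", "Amg"))
  expect_true(all(!aff@b_masks[[2]]))
  expect_true(all(aff@c_mask[c("Hip", "Amg"), 2]))
  # null model carries no modulation and no targets
  nul <- dcmModel("null")
  expect_identical(nul@regulation_family, "none")
  expect_true(all(!nul@b_masks[[2]]))
})

test_that("noiseless two-region estimation recovers A within 0.05 Hz", {
  m2 <- dcmModel("top-down", "Hip", regions = c("MFG", "Hip"))
  pars <- list(A = matrix(c(-0.5, 0.3, 0.2, -0.5), 2, 2,
                          dimnames = list(c("MFG", "Hip"), c("MFG", "Hip"))),
               B = list(matrix(0, 2, 2), matrix(c(0, -0.6, 0, 0), 2, 2)),
               C = matrix(c(1, 0, 0, 0), 2, 2))
  inp <- TNTsuppress:::dcmTestInputs(80)
  ser <- generateDCMTimeseries(m2, pars, inp, noise_sd = 0, seed = 1)
  fit <- dcmEstimate(m2, ser, inp, max_iter = 48)
  expect_lt(max(abs(fit@A - pars$A)), 0.05)
  expect_lt(abs(fit@B[[2]][2, 1] - (-0.6)), 0.05)
  expect_true(is.finite(freeEnergy(fit)))
  expect_true(all(diag(fit@Sigma) > 0))
})

test_that("a negative planted modulation is recovered with the right sign", {
  m2 <- dcmModel("top-down", "Hip", regions = c("MFG", "Hip"))
  inp <- TNTsuppress:::dcmTestInputs(60)
  hits <- 0L
  n_rep <- 10L
  for (k in seq_len(n_rep)) {
    pars <- list(A = matrix(c(-0.5, 0.25, 0.15, -0.5), 2, 2,
                            dimnames = list(c("MFG", "Hip"), c("MFG", "Hip"))),
                 B = list(matrix(0, 2, 2), matrix(c(0, -0.5, 0, 0), 2, 2)),
                 C = matrix(c(1, 0, 0, 0), 2, 2))
    ser <- generateDCMTimeseries(m2, pars, inp, noise_sd = 0.05, seed = 100 + k)
    fit <- dcmEstimate(m2, ser, inp, max_iter = 24)
    if (fit@B[[2]][2, 1] < 0) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("pure-noise data do not reward a modulated model over the null", {
  m_null <- dcmModel("null", regions = c("MFG", "Hip"))
  m_mod <- dcmModel("top-down", "Hip", regions = c("MFG", "Hip"))
  inp <- TNTsuppress:::dcmTestInputs(50)
  dF <- vapply(1:5, function(k) {
    set.seed(200 + k)
    noise <- matrix(rnorm(49 * 2, sd = 0.1), 49, 2)
    colnames(noise) <- c("MFG", "Hip")
    f0 <- dcmEstimate(m_null, noise, inp, max_iter = 16)
    f1 <- dcmEstimate(m_mod, noise, inp, max_iter = 16)
    freeEnergy(f1) - freeEnergy(f0)
  }, numeric(1))
  expect_lte(median(dF), 3)
})

test_that("estimation rejects mismatched data and reports convergence state", {
  m2 <- dcmModel("top-down", "Hip", regions = c("MFG", "Hip"))
  inp <- TNTsuppress:::dcmTestInputs(40)
  expect_error(dcmEstimate(m2, matrix(0, 10, 3), inp), "regions")
  expect_error(dcmEstimate(m2, matrix(0, 10, 2), inp), "scans expected")
})
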