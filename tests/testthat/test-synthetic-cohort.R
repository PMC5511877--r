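test_that("default design yields the canonical trial counts", {
  d <- generateDesign(designSpec(n_subjects = 2, seed = 1))
  for (s in 1:2) {
    tb <- table(d$condition[d$subject == s])
    expect_equal(unname(tb["Think"]), 160)
    expect_equal(unname(tb["NoThink"]), 160)
    tv <- table(d$valence[d$subject == s & d$condition == "NoThink"])
    expect_equal(unname(tv["negative"]), 80)
    expect_equal(unname(tv["neutral"]), 80)
  }
  # no Baseline items in the TNT phase
  expect_false(any(d$condition == "Baseline"))
  # onsets strictly increasing within session
  for (sess in 1:5) {
    on <- d$onset_s[d$subject == 1 & d$session == sess]
    expect_true(all(diff(on) > 0))
  }
})

test_that("design scales with sessions and repetitions", {
  d <- generateDesign(designSpec(n_subjects = 1, n_sessions = 1,
                                 reps_per_session = 1, seed = 2))
  expect_equal(nrow(d), 32)
})

test_that("design generation is deterministic under the seed", {
  s <- designSpec(n_subjects = 3, seed = 11)
  expect_identical(generateDesign(s), generateDesign(s))
  d2 <- generateDesign(designSpec(n_subjects = 3, seed = 12))
  expect_false(identical(generateDesign(s), d2))
})

test_that("invalid design counts name the offending field", {
  expect_error(designSpec(n_sessions = 0), "n_sessions")
  expect_error(designSpec(cues_per_condition_per_valence = -1),
               "cues_per_condition_per_valence")
})

test_that("item inventory enumerates the critical pairs", {
  items <- designItems(designSpec())
  expect_equal(nrow(items), 48)
  expect_equal(sum(items$condition == "Baseline"), 16)
})

test_that("intrusions decline over blocks when a positive slope is planted", {
  co <- makeCohort(n_subjects = 100, seed = 21,
                   truth = cohortTruth(intrusion_decline_slope = 0.25))
  pb <- intrusionProportion(co$behavior$tnt, by = "subject", per_block = TRUE)
  m <- tapply(pb$intrusion_proportion, pb$block, mean)
  expect_lt(mean(m[9:10]), mean(m[1:2]))
})

test_that("degenerate noise reproduces item norms exactly", {
  co <- makeCohort(n_subjects = 3, seed = 31,
                   truth = cohortTruth(noise_sd = 0, affect_effect_size = 0,
                                       planted_rho_negative = 0))
  f <- co$behavior$final
  expect_equal(f$rating, pmin(9, pmax(1, round(f$norm))))
})

test_that("ratings are integers on the 1-9 scale and norms respect truncation", {
  co <- makeCohort(n_subjects = 4, seed = 41)
  f <- co$behavior$final
  expect_true(all(f$rating == round(f$rating)))
  expect_true(all(f$rating >= 1 & f$rating <= 9))
  expect_true(all(f$norm >= 1 & f$norm <= 9))
  neg <- f$norm[f$valence == "negative"]
  neu <- f$norm[f$valence == "neutral"]
  expect_lt(mean(neg), mean(neu))
})

test_that("planted intrusion/affect correlation is realized at n = 200", {
  co <- makeCohort(n_subjects = 200, seed = 51,
                   truth = cohortTruth(planted_rho_negative = -0.8))
  sc <- scoreSubjects(co$behavior)
  neg <- sc[sc$valence == "negative", ]
  r <- cor(neg$intrusion_proportion, neg$affect_suppression)
  expect_gte(r, -0.9)
  expect_lte(r, -0.6)
  # no relationship planted for neutral scenes
  neu <- sc[sc$valence == "neutral", ]
  expect_lt(abs(cor(neu$intrusion_proportion, neu$affect_suppression)), 0.2)
})

test_that("behavior generation is deterministic and infeasible planting warns", {
  co <- makeCohort(n_subjects = 2, seed = 61)
  co2 <- makeCohort(n_subjects = 2, seed = 61)
  expect_identical(co$behavior, co2$behavior)
  d <- co$design
  expect_warning(
    generateBehavior(d, cohortTruth(planted_rho_negative = -0.5,
                                    affect_effect_size = 0), seed = 1),
    "infeasible")
})

test_that("missing reports are generated at the configured rate", {
  co <- makeCohort(n_subjects = 4, seed = 71,
                   truth = cohortTruth(missing_rate = 0.1))
  expect_gt(mean(co$behavior$tnt$missing), 0.05)
  expect_lt(mean(co$behavior$tnt$missing), 0.15)
  expect_true(all(is.na(co$behavior$tnt$report[co$behavior$tnt$missing])))
})

test_that("noise-free brain matrix is exactly rank 1", {
  sc <- data.frame(subject = 1:10, intrusion_proportion = runif(10),
                   affect_suppression = rnorm(10))
  bm <- generateBrain(sc, latentBrainTruth(n_voxels = 300, voxel_noise_sd = 0),
                      seed = 1)
  d <- svd(brainX(bm))$d
  expect_gt(d[1], 1e-6)
  expect_lt(d[2] / d[1], 1e-10)
})

test_that("zero signal scale gives null voxel-behavior correlations", {
  n <- 40
  withr_seed <- function(expr) { set.seed(99); expr }
  sc <- withr_seed(data.frame(subject = 1:n, intrusion_proportion = runif(n),
                              affect_suppression = rnorm(n)))
  bm <- generateBrain(sc, latentBrainTruth(n_voxels = 500, signal_scale = 0),
                      seed = 2)
  X <- brainX(bm)
  rs <- abs(cor(X, sc$affect_suppression))
  q95 <- quantile(rs, 0.95)
  expect_gt(q95, 1 / sqrt(n))
  expect_lt(q95, 3 / sqrt(n))
})

test_that("brain generation is deterministic and validates inputs", {
  sc <- data.frame(subject = 1:8, intrusion_proportion = runif(8),
                   affect_suppression = rnorm(8))
  tb <- latentBrainTruth(n_voxels = 200, n_mfg = 20, n_mtl = 10)
  expect_identical(brainX(generateBrain(sc, tb, seed = 5)),
                   brainX(generateBrain(sc, tb, seed = 5)))
  expect_error(generateBrain(sc[, 1:2], tb, seed = 1), "columns")
  expect_error(generateBrain(rbind(sc, sc[1, ]), tb, seed = 1), "one score row")
})

test_that("synthetic DCM series flow through the network as expected", {
  inp <- dcmInputs(60, dt = 0.1,
                   events = list(data.frame(onset = 5, duration = 1)))
  m <- dcmModel("null", regions = c("MFG", "Hip"))
  A <- matrix(c(-0.6, 0.4, 0, -0.6), 2, 2,
              dimnames = list(c("MFG", "Hip"), c("MFG", "Hip")))
  pars <- list(A = A, B = list(matrix(0, 2, 2)),
               C = matrix(c(1, 0), 2, 1))
  ser <- generateDCMTimeseries(m, pars, inp, noise_sd = 0, seed = 1)
  sim <- dcmSimulate(A, pars$B, pars$C, inp, noise_sd = 0)
  # impulse to MFG: MFG neural peak precedes the Hip peak
  expect_lt(which.max(sim$neural[, 1]), which.max(sim$neural[, 2]))
  # all-zero input from rest stays identically zero
  inp0 <- dcmInputs(20, events = list(data.frame(onset = numeric(0))))
  sim0 <- dcmSimulate(A, pars$B, pars$C, inp0, noise_sd = 0)
  expect_true(all(sim0$bold == 0))
  # determinism under seed
  s1 <- generateDCMTimeseries(m, pars, inp, noise_sd = 0.1, seed = 7)
  s2 <- generateDCMTimeseries(m, pars, inp, noise_sd = 0.1, seed = 7)
  expect_identical(s1, s2)
})
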