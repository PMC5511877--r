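# Recovery and calibration studies: standardized synthetic experiments that
# measure whether each stage recovers planted structure or holds its nominal
# error rate. Used by the test suite and the acceptance script.

#' PLS recovery study on a planted rank-1 cohort
#'
#' Generates a behavioral cohort, scores it, builds a subjects x voxels
#' contrast matrix with planted rank-1 brain-behavior structure, runs the full
#' behavioral PLS, and measures: the cosine between the estimated LV1 voxel
#' salience and the planted salience, the LV1 permutation p, and the BSR
#' sensitivity (planted-support voxels with |BSR| > 1.96) and background
#' false-positive rate.
#'
#' @param n_subjects subjects entering the PLS (default 22).
#' @param n_voxels voxels (default 2000).
#' @param n_perm,n_boot resampling sizes.
#' @param seed RNG seed.
#' @param truth_brain planted brain structure (documented SNR defaults).
#' @return list: cosine, perm_p1, explained1, sensitivity, fpr.
#' @export
validatePLSRecovery <- function(n_subjects = 22, n_voxels = 2000,
                                n_perm = 500, n_boot = 500, seed = 1,
                                truth_brain = latentBrainTruth(n_voxels = n_voxels)) {
  spec <- designSpec(n_subjects = n_subjects, seed = seed)
  beh <- generateBehavior(generateDesign(spec), cohortTruth(), seed = seed)
  sc <- scoreSubjects(beh)
  neg <- sc[sc$valence == "negative", ]
  bm <- generateBrain(neg[, c("subject", "intrusion_proportion",
                              "affect_suppression")], truth_brain, seed = seed)
  res <- behavioralPLS(bm, neg[, c("intrusion_proportion", "affect_suppression")],
                       n_perm = n_perm, n_boot = n_boot, seed = seed)
  v1 <- voxelSaliences(res)[, 1]
  sup <- truth_brain@salience_vector != 0
  bsr1 <- bsrMap(res)[, 1]
  list(cosine = abs(sum(v1 * truth_brain@salience_vector)),
       perm_p1 = permutationP(res)[1],
       explained1 = explainedCovariance(res)[1],
       sensitivity = mean(abs(bsr1[sup]) > 1.96),
       fpr = mean(abs(bsr1[!sup]) > 1.96))
}

#' Type-I calibration of the LV1 permutation test
#'
#' Runs the PLS permutation test on pure-noise datasets and reports the
#' fraction with LV1 p below `alpha` (nominally about `alpha`).
#'
#' @param n_datasets number of null datasets.
#' @param n,n_voxels dataset dimensions.
#' @param n_perm permutations per dataset.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list: rate, n_datasets.
#' @export
validatePermutationCalibration <- function(n_datasets = 200, n = 22,
                                           n_voxels = 200, n_perm = 200,
                                           alpha = 0.05, seed = 1) {
  p1 <- withSeed(deriveSeed(seed, "perm", n_datasets), {
    vapply(seq_len(n_datasets), function(k) {
      X <- matrix(rnorm(n * n_voxels), n, n_voxels)
      Y <- matrix(rnorm(n * 2), n, 2)
      plsPermutation(X, Y, n_perm = n_perm, seed = seed + k)[1]
    }, numeric(1))
  })
  list(rate = mean(p1 < alpha), n_datasets = n_datasets, p = p1)
}

#' Type-I calibration of the skipped correlation
#'
#' Draws independent normal pairs, runs the skipped correlation, and reports
#' how often the null is rejected at the 95 level (`rate`, the calibrated
#' robust t-test decision) and how often the percentile bootstrap CI excludes
#' zero (`ci_rate`; conservative by construction, see
#' [skippedCorrelation()]).
#'
#' @param n_datasets number of null datasets.
#' @param n pairs per dataset.
#' @param n_boot bootstrap draws.
#' @param level CI level in percent.
#' @param seed RNG seed.
#' @return list: rate, ci_rate, n_datasets.
#' @export
validateSkippedNull <- function(n_datasets = 1000, n = 22, n_boot = 1000,
                                level = 95, seed = 1) {
  out <- withSeed(deriveSeed(seed, "boot", n_datasets), {
    vapply(seq_len(n_datasets), function(k) {
      x <- rnorm(n); y <- rnorm(n)
      sk <- suppressMessages(
        skippedCorrelation(x, y, level = level, n_boot = n_boot,
                           seed = seed + k))
      c(sig = isTRUE(sk@significant),
        ci = isTRUE(sk@ci[1] > 0 || sk@ci[2] < 0))
    }, logical(2))
  })
  list(rate = mean(out["sig", ]), ci_rate = mean(out["ci", ]),
       n_datasets = n_datasets)
}

#' Item-split control study on a planted cohort
#'
#' Generates a cohort with a planted intrusion/affect correlation and runs
#' the item-split resampling control.
#'
#' @param rho planted latent correlation (negative scenes).
#' @param n_subjects cohort size.
#' @param n_iter item-split iterations.
#' @param seed RNG seed.
#' @return list: mean_r, ci, rho.
#' @export
validateItemSplit <- function(rho = -0.6, n_subjects = 200, n_iter = 1000,
                              seed = 1) {
  spec <- designSpec(n_subjects = n_subjects, seed = seed)
  beh <- generateBehavior(generateDesign(spec),
                          cohortTruth(planted_rho_negative = rho),
                          seed = seed)
  spl <- itemSplitCorrelation(beh$tnt, beh$final, n_iter = n_iter, seed = seed)
  list(mean_r = spl$mean_r, ci = spl$ci, rho = rho)
}

#' Sign-recovery study for a planted negative modulation
#'
#' Repeatedly simulates a two-region DCM with a negative top-down modulation
#' and reports the fraction of replicates in which the posterior mean of that
#' modulatory parameter is negative.
#'
#' @param n_rep replicates.
#' @param b_true true modulatory strength (Hz).
#' @param noise_sd observation noise.
#' @param n_scans series length.
#' @param seed RNG seed.
#' @param max_iter Gauss-Newton budget per fit.
#' @return list: rate, estimates.
#' @export
validateSignRecovery <- function(n_rep = 20, b_true = -0.5, noise_sd = 0.05,
                                 n_scans = 60, seed = 1, max_iter = 24) {
  m2 <- dcmModel("top-down", "Hip", regions = c("MFG", "Hip"))
  inp <- dcmTestInputs(n_scans)
  pars <- list(A = matrix(c(-0.5, 0.25, 0.15, -0.5), 2, 2,
                          dimnames = list(c("MFG", "Hip"), c("MFG", "Hip"))),
               B = list(matrix(0, 2, 2),
                        matrix(c(0, b_true, 0, 0), 2, 2)),
               C = matrix(c(1, 0, 0, 0), 2, 2))
  est <- vapply(seq_len(n_rep), function(k) {
    ser <- generateDCMTimeseries(m2, pars, inp, noise_sd = noise_sd,
                                 seed = deriveSeed(seed, "dcm", k))
    dcmEstimate(m2, ser, inp, max_iter = max_iter)@B[[2]][2, 1]
  }, numeric(1))
  list(rate = mean(est < 0), estimates = est)
}

#' Family-recovery study for parallel top-down regulation
#'
#' Generates replicate cohorts from a top-down model modulating all three
#' MTL targets (the Parallel family), fits the 7 top-down models to every
#' subject, runs family inference over Emotion / Memory / Parallel, and
#' reports how often the Parallel family wins the exceedance probability.
#'
#' @param n_cohorts replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_scans series length per subject.
#' @param seed RNG seed.
#' @param max_iter Gauss-Newton budget per fit.
#' @return list: rate, winners.
#' @export
validateFamilyRecovery <- function(n_cohorts = 20, n_subjects = 4,
                                   n_scans = 80, seed = 1, max_iter = 16) {
  winners <- vapply(seq_len(n_cohorts), function(k) {
    ds <- dcmDemoCohort(n_subjects = n_subjects, n_scans = n_scans,
                        seed = deriveSeed(seed, "dcm", 5000 + k),
                        max_iter = max_iter)
    fb <- familyInference(ds$F, modelFamilies(ds$models), seed = seed + k)
    names(which.max(exceedanceProb(fb)))
  }, character(1))
  list(rate = mean(winners == "Parallel"), winners = winners)
}
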