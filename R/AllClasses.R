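#' @include TNTsuppress-package.R
NULL

#' Think/No-Think experimental design specification
#'
#' Parameters of the TNT scanning design: number of subjects, sessions,
#' within-session repetitions, cues per instruction condition per valence,
#' cue duration, the jittered inter-trial-interval range, and the number of
#' withheld Baseline pairs per valence. Defaults reproduce the canonical
#' design: 5 sessions of 2 repetitions of 16 Think + 16 No-Think cues
#' (8 per valence), 3 s cues, ITI jitter 0.5-8 s, and 8 Baseline pairs per
#' valence reserved for the final tests.
#'
#' @slot n_subjects number of subjects in the cohort.
#' @slot n_sessions number of scanning sessions.
#' @slot reps_per_session repetitions of the full cue set within a session.
#' @slot cues_per_condition_per_valence cues per instruction x valence cell.
#' @slot cue_duration_s cue presentation time in seconds.
#' @slot iti_range_s length-2 numeric, min and max jittered ITI in seconds.
#' @slot baseline_pairs_per_valence withheld Baseline items per valence.
#' @slot seed integer seed from which all cohort randomness is derived.
#' @exportClass DesignSpec
setClass("DesignSpec",
  representation(
    n_subjects = "integer",
    n_sessions = "integer",
    reps_per_session = "integer",
    cues_per_condition_per_valence = "integer",
    cue_duration_s = "numeric",
    iti_range_s = "numeric",
    baseline_pairs_per_valence = "integer",
    seed = "numeric"
  )
)

setValidity("DesignSpec", function(object) {
  msgs <- character()
  for (f in c("n_subjects", "n_sessions", "reps_per_session",
              "cues_per_condition_per_valence", "baseline_pairs_per_valence")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msgs <- c(msgs, sprintf("'%s' must be a single count >= 1", f))
  }
  if (length(object@iti_range_s) != 2L || any(object@iti_range_s < 0) ||
      object@iti_range_s[1] > object@iti_range_s[2])
    msgs <- c(msgs, "'iti_range_s' must be (min, max) with min <= max, both >= 0")
  if (object@cue_duration_s <= 0)
    msgs <- c(msgs, "'cue_duration_s' must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth parameters of a synthetic behavioral cohort
#'
#' Latent parameters from which intrusion reports, SAM valence ratings and
#' recognition RTs are generated. A latent intrusion tendency and a latent
#' affect-suppression aptitude are drawn per subject from a bivariate normal
#' whose correlation plants the cross-subject intrusion/affect relationship
#' (negative valence only by default). Item norms are drawn from truncated
#' Gaussians matching published picture-set statistics (negative scenes:
#' mean 2.8, SD 1.7; neutral: mean 5.9, SD 1.7; truncated to the 1-9 scale).
#'
#' @slot control_ability optional pre-specified latent control ability per
#'   subject (higher = fewer intrusions); drawn from the seed when empty.
#' @slot intrusion_intercept logit-scale baseline intrusion probability.
#' @slot intrusion_decline_slope logit-scale decline per session (practice).
#' @slot planted_rho_negative target latent correlation between intrusion
#'   tendency and affect-suppression aptitude for negative scenes.
#' @slot planted_rho_neutral same for neutral scenes (0 = no relationship).
#' @slot norm_params named numeric: neg_mean, neg_sd, neu_mean, neu_sd.
#' @slot affect_effect_size SAM rating units added to negative No-Think items
#'   per SD of affect aptitude.
#' @slot noise_sd trial-level SAM rating noise SD (rating units).
#' @slot rt_median_ms,rt_sdlog log-normal recognition RT parameters.
#' @slot rt_slowing_ms named numeric (negative, neutral): No-Think slowing.
#' @slot often_prob probability an intruding trial is reported "often".
#' @slot missing_rate probability of a missing (no-press) report.
#' @exportClass CohortTruth
setClass("CohortTruth",
  representation(
    control_ability = "numeric",
    intrusion_intercept = "numeric",
    intrusion_decline_slope = "numeric",
    planted_rho_negative = "numeric",
    planted_rho_neutral = "numeric",
    norm_params = "numeric",
    affect_effect_size = "numeric",
    noise_sd = "numeric",
    rt_median_ms = "numeric",
    rt_sdlog = "numeric",
    rt_slowing_ms = "numeric",
    often_prob = "numeric",
    missing_rate = "numeric"
  )
)

setValidity("CohortTruth", function(object) {
  msgs <- character()
  if (abs(object@planted_rho_negative) > 1 || abs(object@planted_rho_neutral) > 1)
    msgs <- c(msgs, "planted correlations must lie in [-1, 1]")
  need <- c("neg_mean", "neg_sd", "neu_mean", "neu_sd")
  if (!all(need %in% names(object@norm_params)))
    msgs <- c(msgs, "norm_params must name neg_mean, neg_sd, neu_mean, neu_sd")
  else if (any(object@norm_params[c("neg_mean", "neu_mean")] < 1) ||
           any(object@norm_params[c("neg_mean", "neu_mean")] > 9))
    msgs <- c(msgs, "norm means must lie on the 1-9 SAM scale")
  if (object@noise_sd < 0) msgs <- c(msgs, "noise_sd must be >= 0")
  if (object@missing_rate < 0 || object@missing_rate >= 1)
    msgs <- c(msgs, "missing_rate must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth latent brain structure for synthetic contrast maps
#'
#' A planted rank-1 voxel salience pattern: voxels labelled as control
#' (MFG) regions carry positive salience, medial-temporal voxels
#' (hippocampus, amygdala, parahippocampal) carry negative salience, and
#' background voxels carry zero. The salience vector has unit sum of squares.
#'
#' @slot salience_vector numeric per voxel, unit sum of squares.
#' @slot signal_scale scalar multiplying the rank-1 signal.
#' @slot voxel_noise_sd iid Gaussian noise SD added per voxel.
#' @slot roi_labels factor-like character per voxel: MFG, hippocampus,
#'   amygdala, parahippocampal, or background.
#' @exportClass LatentBrainTruth
setClass("LatentBrainTruth",
  representation(
    salience_vector = "numeric",
    signal_scale = "numeric",
    voxel_noise_sd = "numeric",
    roi_labels = "character"
  )
)

setValidity("LatentBrainTruth", function(object) {
  msgs <- character()
  if (length(object@salience_vector) != length(object@roi_labels))
    msgs <- c(msgs, "salience_vector and roi_labels lengths differ")
  ss <- sum(object@salience_vector^2)
  if (abs(ss - 1) > 1e-8)
    msgs <- c(msgs, "salience_vector must have unit sum of squares")
  bad <- setdiff(unique(object@roi_labels),
                 c("MFG", "hippocampus", "amygdala", "parahippocampal", "background"))
  if (length(bad)) msgs <- c(msgs, paste("unknown roi labels:", paste(bad, collapse = ", ")))
  if (object@voxel_noise_sd < 0) msgs <- c(msgs, "voxel_noise_sd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Subjects-by-voxels contrast matrix container
#'
#' A thin SummarizedExperiment wrapper for per-subject voxelwise contrast
#' values. Rows are voxels (rowData carries x/y/z coordinates and ROI
#' labels), columns are subjects. Use [brainX()] to obtain the subjects x
#' voxels matrix consumed by the PLS routines.
#'
#' @exportClass BrainMatrix
setClass("BrainMatrix", contains = "SummarizedExperiment")

setValidity("BrainMatrix", function(object) {
  msgs <- character()
  if (!"contrast" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'contrast' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("x", "y", "z", "roi_label") %in% colnames(rd)))
    msgs <- c(msgs, "rowData must carry x, y, z, roi_label")
  if (length(msgs)) msgs else TRUE
})

#' Statistic map on a voxel grid
#'
#' A 3-D array of statistic values with a binary mask and a neighbourhood
#' scheme (6- or 26-connectivity) used by peak finding and region growing.
#'
#' @slot values numeric 3-D array of statistic values.
#' @slot mask logical 3-D array; statistics are defined on mask voxels only.
#' @slot connectivity integer, 6 or 26.
#' @exportClass StatMap
setClass("StatMap",
  representation(values = "array", mask = "array", connectivity = "integer")
)

setValidity("StatMap", function(object) {
  msgs <- character()
  if (length(dim(object@values)) != 3L) msgs <- c(msgs, "values must be a 3-D array")
  if (!identical(dim(object@values), dim(object@mask)))
    msgs <- c(msgs, "values and mask dimensions differ")
  if (!object@connectivity %in% c(6L, 26L))
    msgs <- c(msgs, "connectivity must be 6 or 26")
  if (any(!is.finite(object@values[object@mask])))
    msgs <- c(msgs, "non-finite statistic inside the mask")
  if (length(msgs)) msgs else TRUE
})

#' Skipped (outlier-resistant) correlation result
#'
#' Pearson correlation computed after removing bivariate outliers flagged by
#' a robust projection rule, with a percentile-bootstrap confidence interval
#' over the retained pairs.
#'
#' @slot r correlation on retained pairs.
#' @slot n_used number of retained pairs.
#' @slot outlier_indices indices of flagged pairs in the input.
#' @slot ci length-2 numeric, percentile bootstrap CI.
#' @slot level CI level as a percentage (e.g. 95).
#' @slot significant logical; at the 95 level this is the calibrated robust
#'   t-test decision (see [skippedCorrelation()]), otherwise CI exclusion of 0.
#' @slot n_boot bootstrap draws used.
#' @slot seed RNG seed used for the bootstrap.
#' @exportClass SkippedCorrelation
setClass("SkippedCorrelation",
  representation(r = "numeric", n_used = "integer", outlier_indices = "integer",
                 ci = "numeric", level = "numeric", significant = "logical",
                 n_boot = "integer", seed = "numeric")
)

setValidity("SkippedCorrelation", function(object) {
  msgs <- character()
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msgs <- c(msgs, "r must lie in [-1, 1]")
  if (length(object@ci) == 2L && !any(is.na(object@ci)) && object@ci[1] > object@ci[2])
    msgs <- c(msgs, "ci low must be <= ci high")
  if (length(msgs)) msgs else TRUE
})

#' Behavioral PLS decomposition result
#'
#' Result of a behavioral partial-least-squares analysis: singular vectors
#' and values of the cross-block matrix, covariance explained per latent
#' variable (LV), per-subject brain scores, permutation p values per LV,
#' bootstrap standard ratios (BSR) per voxel, and brain-score/behavior
#' correlations with bootstrap CIs.
#'
#' @slot u behavioral saliences (measures x LVs), orthonormal columns.
#' @slot v voxel saliences (voxels x LVs), orthonormal columns.
#' @slot d singular values, decreasing.
#' @slot explained proportion of squared cross-block covariance per LV.
#' @slot brain_scores subjects x LVs projection of preprocessed X onto v.
#' @slot perm_p permutation p value per LV (NA if not run).
#' @slot bsr voxels x LVs bootstrap standard ratios (0 rows if not run).
#' @slot score_behavior data.frame of brain-score/behavior correlations.
#' @slot meta list: preprocessing mode, n_perm, n_boot, seeds.
#' @exportClass PLSResult
setClass("PLSResult",
  representation(u = "matrix", v = "matrix", d = "numeric", explained = "numeric",
                 brain_scores = "matrix", perm_p = "numeric", bsr = "matrix",
                 score_behavior = "data.frame", meta = "list")
)

setValidity("PLSResult", function(object) {
  msgs <- character()
  if (length(object@d) && is.unsorted(rev(object@d)))
    msgs <- c(msgs, "singular values must be decreasing")
  if (length(object@explained) && abs(sum(object@explained) - 1) > 1e-8)
    msgs <- c(msgs, "explained covariance must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Bilinear DCM model structure
#'
#' Connectivity structure of one dynamic causal model over an ordered region
#' set: which intrinsic connections exist (A), which connections each input
#' modulates (B), and which regions each input drives (C). Models carry two
#' family labels: the modulatory type (bottom-up / top-down / bidirectional /
#' afferent / null) and the regulation family implied by the modulated
#' targets (Emotion / Memory / Parallel).
#'
#' @slot name model label.
#' @slot regions ordered region names.
#' @slot a_mask logical regions x regions: allowed intrinsic couplings
#'   (diagonal always allowed, self-decay).
#' @slot b_masks list of logical regions x regions masks, one per input.
#' @slot c_mask logical regions x inputs: driving entries.
#' @slot modulatory_type one of bottom-up, top-down, bidirectional, afferent, null.
#' @slot regulation_targets character subset of PhC, Hip, Amg (empty for null).
#' @slot regulation_family Emotion, Memory, Parallel, or none.
#' @exportClass DCMModel
setClass("DCMModel",
  representation(name = "character", regions = "character", a_mask = "matrix",
                 b_masks = "list", c_mask = "matrix",
                 modulatory_type = "character", regulation_targets = "character",
                 regulation_family = "character")
)

setValidity("DCMModel", function(object) {
  msgs <- character()
  n <- length(object@regions)
  if (!identical(dim(object@a_mask), c(n, n))) msgs <- c(msgs, "a_mask dims wrong")
  if (!all(diag(object@a_mask))) msgs <- c(msgs, "self-connections must be allowed")
  for (bm in object@b_masks)
    if (!identical(dim(bm), c(n, n))) msgs <- c(msgs, "b_mask dims wrong")
  if (nrow(object@c_mask) != n) msgs <- c(msgs, "c_mask rows must match regions")
  if (length(object@b_masks) && length(object@b_masks) != ncol(object@c_mask))
    msgs <- c(msgs, "one b_mask per input is required")
  if (!object@modulatory_type %in%
      c("bottom-up", "top-down", "bidirectional", "afferent", "null"))
    msgs <- c(msgs, "unknown modulatory_type")
  if (length(msgs)) msgs else TRUE
})

#' Fitted DCM for one subject
#'
#' Posterior parameter summary of a Gauss-Newton / variational-Laplace fit:
#' MAP means and covariance for the free entries of (A, B, C), the free
#' energy (Laplace log-evidence approximation), residual noise variances,
#' and per-input effective connectivity A + B.
#'
#' @slot model the [DCMModel-class] that was fitted.
#' @slot theta named numeric MAP parameter vector.
#' @slot Sigma posterior covariance of theta.
#' @slot A,C posterior mean matrices.
#' @slot B list of posterior mean modulatory matrices, one per input.
#' @slot free_energy Laplace approximation to the log model evidence.
#' @slot sigma2 per-region residual variances.
#' @slot converged logical; FALSE if the iteration budget was exhausted.
#' @exportClass DCMFit
setClass("DCMFit",
  representation(model = "DCMModel", theta = "numeric", Sigma = "matrix",
                 A = "matrix", B = "list", C = "matrix",
                 free_energy = "numeric", sigma2 = "numeric",
                 converged = "logical")
)

setValidity("DCMFit", function(object) {
  msgs <- character()
  if (length(object@free_energy) == 1 && !is.finite(object@free_energy))
    msgs <- c(msgs, "free energy must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Random-effects Bayesian model selection result
#'
#' Dirichlet posterior over model (or family) frequencies from the
#' variational random-effects scheme, with expected posterior probabilities
#' (EPP) and Monte-Carlo exceedance probabilities (EP).
#'
#' @slot alpha Dirichlet posterior counts per model/family.
#' @slot alpha0 prior counts.
#' @slot epp expected posterior probability, alpha / sum(alpha).
#' @slot ep exceedance probability (sums to 1 across compared units).
#' @slot g subjects x models responsibility matrix.
#' @slot families optional named list mapping family -> model indices.
#' @exportClass BMSResult
setClass("BMSResult",
  representation(alpha = "numeric", alpha0 = "numeric", epp = "numeric",
                 ep = "numeric", g = "matrix", families = "list")
)

setValidity("BMSResult", function(object) {
  msgs <- character()
  if (abs(sum(object@epp) - 1) > 1e-6) msgs <- c(msgs, "EPP must sum to 1")
  if (abs(sum(object@ep) - 1) > 1e-6) msgs <- c(msgs, "EP must sum to 1")
  if (any(object@alpha < object@alpha0 - 1e-9))
    msgs <- c(msgs, "alpha must dominate alpha0")
  if (length(msgs)) msgs else TRUE
})
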