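#' Create a Think/No-Think design specification
#'
#' Defaults reproduce the canonical TNT scanning design: 24 subjects, 5
#' sessions x 2 repetitions of 16 Think + 16 No-Think cues (8 per valence),
#' 3 s cues with 0.5-8 s jittered ITIs, and 8 Baseline pairs per valence
#' withheld from the TNT phase, yielding 160 trials per instruction condition
#' per subject and 48 critical face-scene pairs.
#'
#' @param n_subjects,n_sessions,reps_per_session,cues_per_condition_per_valence
#'   design counts, each >= 1.
#' @param cue_duration_s cue duration, seconds.
#' @param iti_range_s length-2 numeric, jittered ITI range in seconds.
#' @param baseline_pairs_per_valence withheld Baseline items per valence.
#' @param seed cohort seed; every generator derives its substreams from it.
#' @return A [DesignSpec-class] object.
#' @examples
#' spec <- designSpec(seed = 1)
#' generateDesign(spec)[1:3, ]
#' @export
designSpec <- function(n_subjects = 24, n_sessions = 5, reps_per_session = 2,
                       cues_per_condition_per_valence = 8, cue_duration_s = 3,
                       iti_range_s = c(0.5, 8), baseline_pairs_per_valence = 8,
                       seed = 1) {
  counts <- c(n_subjects = n_subjects, n_sessions = n_sessions,
              reps_per_session = reps_per_session,
              cues_per_condition_per_valence = cues_per_condition_per_valence,
              baseline_pairs_per_valence = baseline_pairs_per_valence)
  bad <- names(counts)[is.na(counts) | counts < 1]
  if (length(bad))
    stop("invalid design count for field(s): ", paste(bad, collapse = ", "))
  new("DesignSpec",
      n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
      reps_per_session = as.integer(reps_per_session),
      cues_per_condition_per_valence = as.integer(cues_per_condition_per_valence),
      cue_duration_s = as.numeric(cue_duration_s),
      iti_range_s = as.numeric(iti_range_s),
      baseline_pairs_per_valence = as.integer(baseline_pairs_per_valence),
      seed = as.numeric(seed))
}

#' Create ground-truth parameters for a synthetic behavioral cohort
#'
#' The defaults describe a cohort in which intrusion probability starts near
#' 0.45 and declines over sessions (logit slope 0.25 per session, matching
#' the practice-related decline seen in TNT studies and an overall intrusion
#' proportion near 0.35), item norms follow the published picture-set
#' statistics (negative mean 2.8 SD 1.7, neutral mean 5.9 SD 1.7, truncated
#' to 1-9), and a latent correlation of -0.5 is planted between intrusion
#' tendency and affect-suppression aptitude for negative scenes only.
#'
#' @param control_ability optional numeric vector of per-subject latent
#'   control abilities; drawn from the cohort seed when omitted.
#' @param intrusion_intercept,intrusion_decline_slope logit-scale intercept
#'   and per-session decline of intrusion probability.
#' @param planted_rho_negative,planted_rho_neutral latent correlation between
#'   intrusion tendency and affect aptitude, per valence.
#' @param norm_params named numeric: neg_mean, neg_sd, neu_mean, neu_sd.
#' @param affect_effect_size SAM units added to negative No-Think ratings per
#'   SD of affect aptitude.
#' @param noise_sd trial-level rating noise SD (SAM units).
#' @param rt_median_ms,rt_sdlog log-normal recognition RT parameters.
#' @param rt_slowing_ms named numeric (negative, neutral) No-Think RT slowing.
#' @param often_prob probability an intruding trial is reported "often".
#' @param missing_rate probability of a missing report (default 0).
#' @return A [CohortTruth-class] object.
#' @export
cohortTruth <- function(control_ability = numeric(),
                        intrusion_intercept = -0.2,
                        intrusion_decline_slope = 0.25,
                        planted_rho_negative = -0.5,
                        planted_rho_neutral = 0,
                        norm_params = c(neg_mean = 2.8, neg_sd = 1.7,
                                        neu_mean = 5.9, neu_sd = 1.7),
                        affect_effect_size = 1.0,
                        noise_sd = 0.6,
                        rt_median_ms = 1400, rt_sdlog = 0.25,
                        rt_slowing_ms = c(negative = 130, neutral = 10),
                        often_prob = 0.3, missing_rate = 0) {
  new("CohortTruth",
      control_ability = as.numeric(control_ability),
      intrusion_intercept = intrusion_intercept,
      intrusion_decline_slope = intrusion_decline_slope,
      planted_rho_negative = planted_rho_negative,
      planted_rho_neutral = planted_rho_neutral,
      norm_params = norm_params,
      affect_effect_size = affect_effect_size,
      noise_sd = noise_sd,
      rt_median_ms = rt_median_ms, rt_sdlog = rt_sdlog,
      rt_slowing_ms = rt_slowing_ms,
      often_prob = often_prob, missing_rate = missing_rate)
}

#' Create a planted latent brain structure
#'
#' Builds a rank-1 voxel salience vector over `n_voxels`: a block of control
#' (MFG) voxels with positive salience, blocks of medial-temporal voxels
#' (hippocampus, amygdala, parahippocampal) with negative salience, and
#' background voxels with zero salience; scaled to unit sum of squares.
#' The sign convention mirrors the direction typically reported for
#' intrusion-control patterns: prefrontal upregulation, MTL downregulation.
#'
#' @param n_voxels total voxel count.
#' @param n_mfg,n_mtl voxels assigned to the MFG block and to each of the
#'   three MTL blocks respectively.
#' @param signal_scale scalar multiplying the rank-1 signal component.
#' @param voxel_noise_sd iid Gaussian noise SD per voxel.
#' @return A [LatentBrainTruth-class] object.
#' @export
latentBrainTruth <- function(n_voxels = 2000, n_mfg = 100, n_mtl = 34,
                             signal_scale = 3, voxel_noise_sd = 0.1) {
  if (n_mfg + 3 * n_mtl > n_voxels)
    stop("labelled voxels exceed n_voxels")
  labels <- c(rep("MFG", n_mfg),
              rep("hippocampus", n_mtl), rep("amygdala", n_mtl),
              rep("parahippocampal", n_mtl),
              rep("background", n_voxels - n_mfg - 3 * n_mtl))
  sal <- numeric(n_voxels)
  sal[labels == "MFG"] <- 1
  sal[labels %in% c("hippocampus", "amygdala", "parahippocampal")] <- -1
  sal <- sal / sqrt(sum(sal^2))
  new("LatentBrainTruth", salience_vector = sal, signal_scale = signal_scale,
      voxel_noise_sd = voxel_noise_sd, roi_labels = labels)
}

#' Construct a BrainMatrix from a subjects x voxels matrix
#'
#' @param x subjects x voxels numeric matrix of contrast values.
#' @param coords optional voxels x 3 matrix of voxel coordinates.
#' @param roi_labels optional character per voxel.
#' @param subjects optional subject identifiers (defaults to rownames of x).
#' @return A [BrainMatrix-class] (voxels as rows, subjects as columns).
#' @export
brainMatrix <- function(x, coords = NULL, roi_labels = NULL, subjects = NULL) {
  x <- as.matrix(x)
  nv <- ncol(x)
  if (is.null(coords)) coords <- cbind(x = seq_len(nv), y = 1L, z = 1L)
  if (is.null(roi_labels)) roi_labels <- rep("background", nv)
  if (nrow(coords) != nv || length(roi_labels) != nv)
    stop("voxel metadata does not match the number of voxels")
  subjects <- subjects %||% rownames(x) %||% paste0("sub", seq_len(nrow(x)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(contrast = t(x)),
    rowData = S4Vectors::DataFrame(x = coords[, 1], y = coords[, 2],
                                   z = coords[, 3], roi_label = roi_labels),
    colData = S4Vectors::DataFrame(subject = subjects, row.names = subjects))
  new("BrainMatrix", se)
}

#' Construct a statistic map
#'
#' @param values numeric array (2-D input is promoted to a one-slice 3-D grid).
#' @param mask logical array of the same dimensions; defaults to all finite
#'   voxels.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners). 26 is the
#'   default neighbourhood for region growing.
#' @return A [StatMap-class] object.
#' @export
statMap <- function(values, mask = NULL, connectivity = 26) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (is.null(mask)) mask <- array(is.finite(values), dim(values))
  mask <- as.array(mask)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  storage.mode(mask) <- "logical"
  values[!mask] <- NA_real_
  values[mask & !is.finite(values)] <- NA_real_
  if (any(is.na(values[mask]))) stop("non-finite statistic inside the mask")
  new("StatMap", values = values, mask = mask,
      connectivity = as.integer(connectivity))
}
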