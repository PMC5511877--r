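#' Generate behavioral measurements for a synthetic cohort
#'
#' Simulates the two behavioral tables of a TNT study from known ground
#' truth:
#' \describe{
#'   \item{tnt}{trial-level intrusion reports for the TNT phase. Each
#'     No-Think trial intrudes with a logistic probability that declines over
#'     sessions (practice) and is shifted by the subject's latent intrusion
#'     tendency; intruding trials are reported "briefly" or "often" (the
#'     analysis collapses these to a binary intrusion), non-intruding trials
#'     "never". Think trials receive high-probability awareness reports.}
#'   \item{final}{item-level final tests: SAM valence ratings (integer 1-9,
#'     item norm + condition effect + noise, rounded and clipped) and
#'     log-normal recognition RTs with a configurable No-Think slowing, for
#'     Think, No-Think and Baseline items.}
#' }
#'
#' The cross-subject correlation between intrusion proportion and affect
#' suppression is planted through the latent bivariate-normal pair
#' (intrusion tendency, affect aptitude) with correlation
#' `planted_rho_negative` (negative scenes) and `planted_rho_neutral`
#' (neutral scenes): the affect aptitude scales the rating shift of negative
#' (resp. neutral) No-Think items by `affect_effect_size`.
#'
#' @param design trial table from [generateDesign()].
#' @param truth a [CohortTruth-class].
#' @param seed seed for the behavioral substreams (defaults to the design's
#'   subjects as units under stage "behavior").
#' @return list with elements `tnt` (design plus columns report, missing,
#'   intrusion), `final` (subject, condition, valence, item, norm, rating,
#'   adjusted, rt_ms) and `latents` (per-subject ground truth).
#' @export
generateBehavior <- function(design, truth = cohortTruth(), seed = 1) {
  stopifnot(is(truth, "CohortTruth"))
  validObject(truth)
  subjects <- sort(unique(design$subject))
  n <- length(subjects)

  if (abs(truth@planted_rho_negative) > 0 && truth@affect_effect_size == 0)
    warning("planted correlation is infeasible: affect_effect_size is 0")

  # latent pairs; control_ability = -intrusion tendency
  lat <- withSeed(deriveSeed(seed, "behavior", 0), {
    m <- if (length(truth@control_ability)) -truth@control_ability else rnorm(n)
    a_neg <- truth@planted_rho_negative * m +
      sqrt(1 - truth@planted_rho_negative^2) * rnorm(n)
    a_neu <- truth@planted_rho_neutral * m +
      sqrt(1 - truth@planted_rho_neutral^2) * rnorm(n)
    data.frame(subject = subjects, intrusion_tendency = m,
               control_ability = -m, affect_aptitude_negative = a_neg,
               affect_aptitude_neutral = a_neu)
  })

  items <- designItems(designSpecFromDesign(design))

  tnt_list <- vector("list", n)
  fin_list <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subjects[i]
    d <- design[design$subject == s, , drop = FALSE]
    withSeed(deriveSeed(seed, "behavior", s), {
      nothink <- d$condition == "NoThink"
      p <- ifelse(nothink,
                  plogis(truth@intrusion_intercept -
                           truth@intrusion_decline_slope * (d$session - 1) +
                           lat$intrusion_tendency[i]),
                  plogis(2.5))
      aware <- rbinom(nrow(d), 1L, p) == 1L
      often <- aware & (runif(nrow(d)) < truth@often_prob)
      report <- ifelse(!aware, "never", ifelse(often, "often", "briefly"))
      missing <- runif(nrow(d)) < truth@missing_rate
      report[missing] <- NA_character_
      d$report <- report
      d$missing <- missing
      d$intrusion <- ifelse(missing, NA, as.integer(aware))

      f <- items
      f$subject <- s
      neg <- f$valence == "negative"
      f$norm <- NA_real_
      f$norm[neg] <- rtruncnorm(sum(neg), truth@norm_params["neg_mean"],
                                truth@norm_params["neg_sd"], 1, 9)
      f$norm[!neg] <- rtruncnorm(sum(!neg), truth@norm_params["neu_mean"],
                                 truth@norm_params["neu_sd"], 1, 9)
      effect <- numeric(nrow(f))
      nt <- f$condition == "NoThink"
      effect[nt & neg] <- truth@affect_effect_size * lat$affect_aptitude_negative[i]
      effect[nt & !neg] <- truth@affect_effect_size * lat$affect_aptitude_neutral[i]
      rating <- f$norm + effect +
        if (truth@noise_sd > 0) rnorm(nrow(f), 0, truth@noise_sd) else 0
      f$rating <- pmin(9, pmax(1, round(rating)))
      f$adjusted <- f$rating / f$norm
      slow <- numeric(nrow(f))
      slow[nt] <- truth@rt_slowing_ms[ifelse(neg[nt], "negative", "neutral")]
      f$rt_ms <- rlnorm(nrow(f), log(truth@rt_median_ms), truth@rt_sdlog) + slow
      fin_list[[i]] <- f[, c("subject", "condition", "valence", "item",
                             "norm", "rating", "adjusted", "rt_ms")]
      tnt_list[[i]] <- d
    })
  }
  list(tnt = do.call(rbind, tnt_list),
       final = do.call(rbind, fin_list),
       latents = lat)
}

# Reconstruct the design counts needed for the item inventory from a trial
# table (used so generateBehavior needs only the design table).
designSpecFromDesign <- function(design) {
  k <- length(unique(design$item[design$condition == "Think" &
                                   design$valence == "negative"]))
  designSpec(n_subjects = length(unique(design$subject)),
             n_sessions = max(design$session),
             reps_per_session = max(design$rep),
             cues_per_condition_per_valence = max(1L, k),
             baseline_pairs_per_valence = max(1L, k))
}

#' Generate a synthetic subjects x voxels contrast matrix
#'
#' Builds `X = scale * s v' + E`: a rank-1 brain-behavior structure in which
#' the subject score `s` is the (standardized affect suppression minus
#' standardized intrusion proportion) / sqrt(2) — so that voxels with
#' positive planted salience activate more in subjects with good affect
#' suppression and few intrusions — `v` is the planted unit-norm salience of
#' `truth`, and `E` is iid Gaussian noise with SD `voxel_noise_sd`.
#'
#' @param subject_scores data.frame with one row per subject and columns
#'   `subject`, `intrusion_proportion`, `affect_suppression`.
#' @param truth a [LatentBrainTruth-class].
#' @param seed RNG seed for the noise field.
#' @return A [BrainMatrix-class]; attribute `"score"` carries the latent
#'   subject scores s.
#' @export
generateBrain <- function(subject_scores, truth = latentBrainTruth(), seed = 1) {
  stopifnot(is(truth, "LatentBrainTruth"))
  validObject(truth)
  need <- c("subject", "intrusion_proportion", "affect_suppression")
  if (!all(need %in% names(subject_scores)))
    stop("subject_scores must carry columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(subject_scores$subject))
    stop("one score row per subject is required")
  v <- truth@salience_vector
  nvox <- length(v)
  zi <- as.numeric(scale(subject_scores$intrusion_proportion))
  za <- as.numeric(scale(subject_scores$affect_suppression))
  s <- (za - zi) / sqrt(2)
  X <- withSeed(deriveSeed(seed, "brain", 0), {
    truth@signal_scale * tcrossprod(s, v) +
      if (truth@voxel_noise_sd > 0)
        matrix(rnorm(length(s) * nvox, 0, truth@voxel_noise_sd),
               length(s), nvox) else 0
  })
  rownames(X) <- subject_scores$subject
  dims <- gridDims(nvox)
  coords <- arrayInd(seq_len(nvox), dims)
  colnames(coords) <- c("x", "y", "z")
  bm <- brainMatrix(X, coords = coords, roi_labels = truth@roi_labels,
                    subjects = as.character(subject_scores$subject))
  attr(bm, "score") <- s
  bm
}

gridDims <- function(nvox) {
  nx <- ceiling(nvox^(1 / 3))
  ny <- ceiling(sqrt(nvox / nx))
  nz <- ceiling(nvox / (nx * ny))
  c(nx, ny, nz)
}
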