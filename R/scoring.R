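#' Classify intrusion reports as binary intrusions
#'
#' A trial counts as an intrusion when the associated memory entered
#' awareness ("briefly" or "often" report) and as a non-intrusion for a
#' "never" report. "frequent" is accepted as a synonym of "often". Missing
#' reports are returned as NA; they are excluded (never imputed) by
#' [intrusionProportion()].
#'
#' @param report character vector of reports.
#' @return integer vector of 0/1 with NA for missing reports.
#' @examples
#' classifyIntrusion(c("never", "briefly", "often"))
#' @export
classifyIntrusion <- function(report) {
  out <- rep(NA_integer_, length(report))
  known <- c(never = 0L, briefly = 1L, often = 1L, frequent = 1L)
  idx <- !is.na(report)
  bad <- idx & !(report %in% names(known))
  if (any(bad))
    stop("unknown intrusion report label(s): ",
         paste(unique(report[bad]), collapse = ", "))
  out[idx] <- known[report[idx]]
  out
}

#' Two-level intrusion proportion
#'
#' Computes the per-subject intrusion proportion as the mean over repetition
#' blocks of the within-block mean of binary intrusion reports: reports are
#' first averaged across the items of each repetition of the condition, and
#' these per-repetition proportions are then averaged across repetitions.
#' Missing-response trials are dropped from both numerator and denominator of
#' their repetition; a repetition with no valid trial is omitted from the
#' outer mean with a warning.
#'
#' @param trials trial table with columns subject, valence, block, condition
#'   and report (or a precomputed binary `intrusion` column).
#' @param condition which instruction condition to score (default "NoThink").
#' @param by grouping columns for the result (default subject and valence).
#' @param per_block if TRUE, return the per-repetition proportions instead of
#'   their mean.
#' @return data.frame with the grouping columns, `intrusion_proportion`,
#'   `n_trials` (valid trials used) and `n_intrusions`.
#' @export
intrusionProportion <- function(trials, condition = "NoThink",
                                by = c("subject", "valence"),
                                per_block = FALSE) {
  t0 <- trials[trials$condition == condition, , drop = FALSE]
  if (!nrow(t0)) stop("no trials in condition ", condition)
  bin <- if ("report" %in% names(t0)) classifyIntrusion(t0$report)
         else t0$intrusion
  keyb <- t0[, c(by, "block"), drop = FALSE]
  id <- factor(do.call(paste, c(keyb, sep = "\r")))
  valid <- !is.na(bin)
  n_valid <- tapply(valid, id, sum)
  n_intr <- tapply(ifelse(valid, bin, 0L), id, sum)
  blk <- keyb[!duplicated(id), , drop = FALSE]
  ord <- match(levels(id), id[!duplicated(id)])
  blk <- blk[ord, , drop = FALSE]
  blk$intrusion_proportion <- as.numeric(n_intr / n_valid)
  blk$n_trials <- as.integer(n_valid)
  blk$n_intrusions <- as.integer(n_intr)
  if (any(blk$n_trials == 0)) {
    warning(sum(blk$n_trials == 0), " repetition(s) without valid trials omitted")
    blk <- blk[blk$n_trials > 0, , drop = FALSE]
  }
  if (per_block) {
    rownames(blk) <- NULL
    return(blk)
  }
  id2 <- factor(do.call(paste, c(blk[, by, drop = FALSE], sep = "\r")))
  out <- blk[!duplicated(id2), by, drop = FALSE]
  out <- out[match(levels(id2), id2[!duplicated(id2)]), , drop = FALSE]
  out$intrusion_proportion <- as.numeric(tapply(blk$intrusion_proportion, id2, mean))
  out$n_trials <- as.integer(tapply(blk$n_trials, id2, sum))
  out$n_intrusions <- as.integer(tapply(blk$n_intrusions, id2, sum))
  rownames(out) <- NULL
  out[order(out[[by[1]]]), , drop = FALSE]
}

#' Norm-adjusted valence rating
#'
#' Expresses a SAM valence rating relative to the item's normative valence as
#' the dimensionless ratio rating / norm (condition means of this quantity
#' fall around 0.76-1.16 for realistic inputs).
#'
#' @param rating numeric SAM ratings (1-9 scale).
#' @param norm positive normative valence values.
#' @return rating / norm.
#' @examples
#' adjustValence(4.5, 5)  # 0.9
#' @export
adjustValence <- function(rating, norm) {
  if (any(!is.finite(norm)) || any(norm <= 0))
    stop("normative valence must be positive")
  rating / norm
}

#' Median absolute deviation scale estimate
#'
#' b * median(|x - median(x)|) with b = 1.4826, the constant that makes the
#' estimate consistent for the standard deviation under normality. A thin
#' wrapper over [stats::mad()].
#'
#' @param x numeric values (at least one finite value).
#' @param b consistency constant.
#' @return scale estimate.
#' @examples
#' madScale(c(1, 2, 3, 4, 5))  # 1.4826
#' @export
madScale <- function(x, b = 1.4826) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("madScale requires at least one finite value")
  stats::mad(x, constant = b)
}

#' Single-pass MAD outlier trimming
#'
#' Drops values farther than `k` MAD units from the median. When the MAD is
#' zero (e.g. constant input) no trimming is applied. Trimming is a single
#' pass: the rule is applied once to the original values, not iterated.
#'
#' @param values numeric vector.
#' @param k rejection multiple (default 2, i.e. > 2 x MAD from the median).
#' @return list with `kept` (values), `kept_idx` and `rejected_idx`.
#' @examples
#' trimOutliers(c(10, 11, 12, 11, 100))$rejected_idx  # 5
#' @export
trimOutliers <- function(values, k = 2) {
  idx <- which(is.finite(values))
  if (!length(idx))
    return(list(kept = numeric(), kept_idx = integer(), rejected_idx = integer()))
  m <- median(values[idx])
  s <- madScale(values[idx])
  rej <- if (s > 0) idx[abs(values[idx] - m) > k * s] else integer()
  keep <- setdiff(idx, rej)
  list(kept = values[keep], kept_idx = keep, rejected_idx = as.integer(rej))
}

# Trimmed condition mean of a per-item measure; NA when nothing survives.
trimmedMean <- function(x, trim = TRUE, k = 2) {
  if (trim) x <- trimOutliers(x, k)$kept else x <- x[is.finite(x)]
  if (!length(x)) NA_real_ else mean(x)
}

#' Affect suppression score
#'
#' Mean adjusted No-Think rating minus mean adjusted Baseline rating, per
#' subject and valence, after single-pass MAD trimming within each condition.
#' Positive values for negative scenes indicate reduced negativity after
#' suppression. By default ratings are norm-adjusted first and trimming is
#' applied to the adjusted values (set `adjust_first = FALSE` to trim raw
#' ratings before adjustment).
#'
#' @param final item-level final-test table with columns subject, condition,
#'   valence, rating, norm (as produced by [generateBehavior()]).
#' @param trim apply MAD trimming within condition (default TRUE).
#' @param k trimming multiple.
#' @param adjust_first adjust before trimming (default TRUE).
#' @return data.frame subject, valence, nothink_mean, baseline_mean,
#'   affect_suppression, and a `degenerate` flag set when a condition had no
#'   surviving items.
#' @export
affectSuppression <- function(final, trim = TRUE, k = 2, adjust_first = TRUE) {
  conditionDifference(final, value_fun = function(d) {
    if (adjust_first) adjustValence(d$rating, d$norm)
    else d$rating  # trimmed raw, adjusted after trimming below
  }, post_fun = if (adjust_first) NULL else function(vals, d, kept)
    adjustValence(vals, d$norm[kept]),
  trim = trim, k = k, score_name = "affect_suppression")
}

#' Recognition-RT suppression effect
#'
#' Mean No-Think recognition RT minus mean Baseline RT per subject and
#' valence, after single-pass MAD trimming within each condition. Positive
#' values indicate suppression-induced slowing.
#'
#' @inheritParams affectSuppression
#' @return data.frame subject, valence, nothink_mean, baseline_mean,
#'   rt_suppression, degenerate flag.
#' @export
rtSuppression <- function(final, trim = TRUE, k = 2) {
  conditionDifference(final, value_fun = function(d) d$rt_ms,
                      trim = trim, k = k, score_name = "rt_suppression")
}

conditionDifference <- function(final, value_fun, post_fun = NULL,
                                trim = TRUE, k = 2, score_name) {
  keys <- unique(final[, c("subject", "valence")])
  keys <- keys[order(keys$subject, keys$valence), , drop = FALSE]
  res <- lapply(seq_len(nrow(keys)), function(i) {
    cond_mean <- function(cond) {
      d <- final[final$subject == keys$subject[i] &
                   final$valence == keys$valence[i] &
                   final$condition == cond, , drop = FALSE]
      if (!nrow(d)) return(NA_real_)
      vals <- value_fun(d)
      tr <- if (trim) trimOutliers(vals, k) else
        list(kept = vals[is.finite(vals)], kept_idx = which(is.finite(vals)))
      vals <- tr$kept
      if (!is.null(post_fun)) vals <- post_fun(vals, d, tr$kept_idx)
      if (!length(vals)) NA_real_ else mean(vals)
    }
    nt <- cond_mean("NoThink"); bl <- cond_mean("Baseline")
    data.frame(subject = keys$subject[i], valence = keys$valence[i],
               nothink_mean = nt, baseline_mean = bl,
               score = nt - bl, degenerate = is.na(nt) || is.na(bl))
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "score"] <- score_name
  if (any(out$degenerate))
    warning("undefined score for ", sum(out$degenerate),
            " subject x valence cell(s): no surviving items in a condition")
  rownames(out) <- NULL
  out
}

#' Per-subject derived behavioral scores
#'
#' Convenience wrapper combining [intrusionProportion()],
#' [affectSuppression()] and [rtSuppression()] into one table with one row
#' per subject x valence.
#'
#' @param behavior list with `tnt` and `final` tables as produced by
#'   [generateBehavior()] (or equivalent real tables).
#' @param trim,k MAD trimming options passed through.
#' @return data.frame subject, valence, intrusion_proportion, n_trials,
#'   n_intrusions, affect_suppression, rt_suppression plus condition means.
#' @export
scoreSubjects <- function(behavior, trim = TRUE, k = 2) {
  ip <- intrusionProportion(behavior$tnt)
  af <- affectSuppression(behavior$final, trim = trim, k = k)
  rt <- rtSuppression(behavior$final, trim = trim, k = k)
  out <- merge(ip, af[, c("subject", "valence", "nothink_mean",
                          "baseline_mean", "affect_suppression")],
               by = c("subject", "valence"))
  out <- merge(out, rt[, c("subject", "valence", "rt_suppression")],
               by = c("subject", "valence"))
  out[order(out$subject, out$valence), ]
}

#' Median split by memory-control ability
#'
#' Splits subjects into high- and low-control groups by a median split on the
#' overall No-Think intrusion proportion (lower intrusion proportion = better
#' control). Ties are broken by subject identifier order, so the split is
#' deterministic; group sizes are equal when the number of subjects is even
#' (the high-control group receives the extra subject otherwise).
#'
#' @param scores data.frame with columns subject and intrusion_proportion
#'   (one row per subject; average across valences first if needed).
#' @return the input with an added `group` column ("high_control" /
#'   "low_control").
#' @export
splitByControl <- function(scores) {
  if (anyDuplicated(scores$subject))
    stop("one row per subject is required (average across valences first)")
  if (nrow(scores) < 2) stop("need at least 2 subjects to split")
  ord <- order(scores$intrusion_proportion, scores$subject)
  n_high <- ceiling(nrow(scores) / 2)
  grp <- rep("low_control", nrow(scores))
  grp[ord[seq_len(n_high)]] <- "high_control"
  if (anyDuplicated(scores$intrusion_proportion))
    message("ties in intrusion proportion broken by subject identifier order")
  scores$group <- grp
  scores
}

#' Exclude subjects with insufficient intrusions
#'
#' Applies the low-intrusion exclusion rule used before brain-behavior
#' analyses: subjects with fewer than `min_trials` intrusive trials (5% of 80
#' No-Think trials per valence = 4 trials in the default design) in any
#' valence condition are dropped.
#'
#' @param scores per-subject table with columns subject, valence,
#'   n_intrusions (e.g. from [scoreSubjects()]).
#' @param min_trials minimum intrusive trials per valence (default 4).
#' @return list with `kept` (subject ids), `excluded` (subject ids) and the
#'   filtered `scores`.
#' @export
excludeLowIntrusion <- function(scores, min_trials = 4) {
  bad <- unique(scores$subject[scores$n_intrusions < min_trials])
  keep <- setdiff(unique(scores$subject), bad)
  if (length(bad))
    message(length(bad), " subject(s) excluded with < ", min_trials,
            " intrusive trials in a valence condition")
  list(kept = keep, excluded = bad,
       scores = scores[scores$subject %in% keep, , drop = FALSE])
}
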