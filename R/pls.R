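# Behavioral partial least squares: preprocessing, cross-block SVD,
# permutation tests, bootstrap standard ratios.

#' Preprocess the brain and behavior blocks for PLS
#'
#' Two modes are provided because "mean-center, then normalize each subject
#' row to unit sum of squares" leaves the columns slightly de-centered:
#' \describe{
#'   \item{"center-then-normalize"}{(default) column mean-center X and Y, then
#'     scale each row of X to unit sum of squares — the stated order.}
#'   \item{"rows-first"}{row-normalize X first, then column-center both, which
#'     leaves X columns exactly centered.}
#' }
#' The numerical difference between the modes is O(1/N_voxels). When
#' `correlation = TRUE` (default) Y columns are additionally scaled to unit
#' variance so the cross-block matrix is a correlation-like matrix.
#'
#' @param X subjects x voxels matrix.
#' @param Y subjects x measures matrix.
#' @param mode preprocessing order (see above).
#' @param correlation scale Y columns to unit SD.
#' @return list with X and Y (preprocessed).
#' @export
plsPreprocess <- function(X, Y,
                          mode = c("center-then-normalize", "rows-first"),
                          correlation = TRUE) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (anyNA(X) || anyNA(Y)) stop("missing entries are not allowed")
  ysd <- apply(Y, 2, sd)
  if (any(ysd == 0)) stop("zero-variance Y column")
  rowNorm <- function(M) {
    ss <- sqrt(rowSums(M^2))
    if (any(ss == 0)) stop("all-zero X row cannot be normalized")
    M / ss
  }
  if (mode == "center-then-normalize") {
    X <- rowNorm(scale(X, center = TRUE, scale = FALSE))
    Y <- scale(Y, center = TRUE, scale = FALSE)
  } else {
    X <- scale(rowNorm(X), center = TRUE, scale = FALSE)
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  if (correlation) Y <- scale(Y, center = FALSE, scale = apply(Y, 2, sd))
  list(X = unclass(X)[, , drop = FALSE], Y = unclass(Y)[, , drop = FALSE])
}

#' Cross-block matrix
#'
#' R = Y' X (measures x voxels) on preprocessed blocks.
#'
#' @param Xp,Yp preprocessed matrices from [plsPreprocess()].
#' @return measures x voxels matrix.
#' @export
crossBlock <- function(Xp, Yp) crossprod(Yp, Xp)

#' Singular value decomposition of the cross-block matrix
#'
#' Thin SVD with LVs ordered by decreasing singular value and a deterministic
#' sign convention: within each LV, the behavioral-salience element of
#' largest magnitude is made positive.
#'
#' @param R cross-block matrix (measures x voxels).
#' @return list u (measures x LVs), d (singular values), v (voxels x LVs),
#'   explained (d^2 / sum d^2).
#' @export
plsDecompose <- function(R) {
  s <- svd(R)
  for (k in seq_along(s$d)) {
    j <- which.max(abs(s$u[, k]))
    if (s$u[j, k] < 0) {
      s$u[, k] <- -s$u[, k]
      s$v[, k] <- -s$v[, k]
    }
  }
  list(u = s$u, d = s$d, v = s$v,
       explained = if (sum(s$d^2) > 0) s$d^2 / sum(s$d^2) else s$d)
}

plsCore <- function(X, Y, mode, correlation) {
  pp <- plsPreprocess(X, Y, mode = mode, correlation = correlation)
  dec <- plsDecompose(crossBlock(pp$X, pp$Y))
  dec$Xp <- pp$X; dec$Yp <- pp$Y
  dec
}

#' Permutation test for PLS latent variables
#'
#' Permutes the rows of Y (reassigning subjects' brain data to behavioral
#' measurements), re-runs the full preprocessing and SVD per permutation, and
#' compares singular values rank-matched (k-th permuted vs k-th observed).
#' p = (1 + #exceedances) / (1 + n_perm), so p is never exactly zero.
#'
#' @param X,Y raw (unpreprocessed) input blocks.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param mode,correlation passed to [plsPreprocess()].
#' @return numeric vector of p values, one per LV.
#' @export
plsPermutation <- function(X, Y, n_perm = 5000, seed = 1,
                           mode = "center-then-normalize", correlation = TRUE) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- plsCore(X, Y, mode, correlation)
  n <- nrow(as.matrix(Y))
  exceed <- numeric(length(obs$d))
  withSeed(deriveSeed(seed, "perm", n), {
    for (b in seq_len(n_perm)) {
      Yp <- as.matrix(Y)[sample.int(n), , drop = FALSE]
      d <- plsCore(X, Yp, mode, correlation)$d
      m <- seq_len(min(length(d), length(exceed)))
      exceed[m] <- exceed[m] + (d[m] >= obs$d[m])
    }
  })
  (1 + exceed) / (1 + n_perm)
}

#' Bootstrap standard ratios for voxel saliences
#'
#' Resamples subjects with replacement, re-runs preprocessing and SVD, aligns
#' each bootstrap solution to the original by per-LV sign (dot product with
#' the original voxel salience; full orthogonal Procrustes alignment via
#' `align = "procrustes"`), and returns BSR = original salience / bootstrap
#' SE. |BSR| > 1.96 is conventionally treated as significant. A small SE
#' floor (1e-12) guards noise-free degenerate inputs where the bootstrap SE
#' collapses to zero. Bootstrap draws containing a single unique subject are
#' redrawn.
#'
#' @param X,Y raw input blocks.
#' @param n_boot bootstrap draws (>= 100).
#' @param seed RNG seed.
#' @param align "sign" (default) or "procrustes".
#' @param mode,correlation passed to [plsPreprocess()].
#' @return list: `bsr` (voxels x LVs), `se`, `v` (original saliences),
#'   `boot_scores_r` unused slots reserved.
#' @export
plsBootstrapBSR <- function(X, Y, n_boot = 5000, seed = 1,
                            align = c("sign", "procrustes"),
                            mode = "center-then-normalize", correlation = TRUE) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  align <- match.arg(align)
  obs <- plsCore(X, Y, mode, correlation)
  n <- nrow(as.matrix(X))
  nlv <- length(obs$d)
  sum1 <- matrix(0, nrow(obs$v), nlv)
  sum2 <- matrix(0, nrow(obs$v), nlv)
  used <- 0L
  withSeed(deriveSeed(seed, "boot", n), {
    b <- 0L
    while (b < n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < 2) next  # degenerate draw: redraw
      Xb <- as.matrix(X)[idx, , drop = FALSE]
      Yb <- as.matrix(Y)[idx, , drop = FALSE]
      dec <- tryCatch(plsCore(Xb, Yb, mode, correlation),
                      error = function(e) NULL)
      if (is.null(dec)) next
      Vb <- dec$v[, seq_len(min(nlv, ncol(dec$v))), drop = FALSE]
      if (ncol(Vb) < nlv) next
      if (align == "sign") {
        sgn <- sign(colSums(Vb * obs$v))
        sgn[sgn == 0] <- 1
        Vb <- sweep(Vb, 2, sgn, `*`)
      } else {
        s <- svd(crossprod(Vb, obs$v))
        Vb <- Vb %*% (s$u %*% t(s$v))
      }
      sum1 <- sum1 + Vb
      sum2 <- sum2 + Vb^2
      used <- used + 1L
      b <- b + 1L
    }
  })
  se <- sqrt(pmax(0, sum2 / used - (sum1 / used)^2)) * sqrt(used / (used - 1))
  se <- pmax(se, 1e-12)
  list(bsr = obs$v / se, se = se, v = obs$v, n_boot = used)
}

#' Brain-score / behavior correlations with bootstrap CIs
#'
#' Pearson correlation between each LV's brain scores and each behavioral
#' measure, with percentile bootstrap CIs over subject resampling.
#'
#' @param scores subjects x LVs brain-score matrix.
#' @param Y subjects x measures behavioral matrix.
#' @param n_boot bootstrap draws (0 skips CIs).
#' @param seed RNG seed.
#' @param level CI level in percent.
#' @return data.frame lv, measure, r, ci_low, ci_high.
#' @export
scoreBehaviorCorrelations <- function(scores, Y, n_boot = 1000, seed = 1,
                                      level = 95) {
  scores <- as.matrix(scores); Y <- as.matrix(Y)
  meas <- colnames(Y) %||% paste0("measure", seq_len(ncol(Y)))
  n <- nrow(scores)
  alpha <- 1 - level / 100
  out <- expand.grid(lv = seq_len(ncol(scores)), measure = meas,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  for (i in seq_len(nrow(out))) {
    k <- out$lv[i]; j <- match(out$measure[i], meas)
    out$r[i] <- cor(scores[, k], Y[, j])
    if (n_boot > 0) {
      rb <- withSeed(deriveSeed(seed, "boot", i), {
        vapply(seq_len(n_boot), function(b) {
          idx <- sample.int(n, n, replace = TRUE)
          if (sd(scores[idx, k]) == 0 || sd(Y[idx, j]) == 0) NA_real_
          else cor(scores[idx, k], Y[idx, j])
        }, numeric(1))
      })
      rb <- rb[is.finite(rb)]
      ci <- quantile(rb, c(alpha / 2, 1 - alpha / 2), type = 6)
      out$ci_low[i] <- ci[1]; out$ci_high[i] <- ci[2]
    }
  }
  out
}

#' Behavioral PLS analysis
#'
#' Full behavioral PLS: preprocessing, cross-block SVD, optional permutation
#' test per LV, optional bootstrap standard ratios per voxel, brain scores
#' (X_preprocessed %*% V) and brain-score/behavior correlations.
#'
#' @param X subjects x voxels contrast matrix, or a [BrainMatrix-class].
#' @param Y subjects x measures matrix (e.g. intrusion proportion and affect
#'   suppression), or data.frame.
#' @param n_perm permutations for LV significance (0 skips).
#' @param n_boot bootstrap draws for BSR and score/behavior CIs (0 skips).
#' @param seed RNG seed.
#' @param mode,correlation preprocessing options, see [plsPreprocess()].
#' @return A [PLSResult-class].
#' @export
behavioralPLS <- function(X, Y, n_perm = 5000, n_boot = 5000, seed = 1,
                          mode = "center-then-normalize", correlation = TRUE) {
  if (is(X, "BrainMatrix")) X <- brainX(X)
  Y <- as.matrix(Y)
  obs <- plsCore(X, Y, mode, correlation)
  scores <- obs$Xp %*% obs$v
  perm_p <- rep(NA_real_, length(obs$d))
  if (n_perm > 0)
    perm_p <- plsPermutation(X, Y, n_perm = n_perm, seed = seed,
                             mode = mode, correlation = correlation)
  bsr <- matrix(numeric(), 0, 0)
  if (n_boot > 0)
    bsr <- plsBootstrapBSR(X, Y, n_boot = n_boot, seed = seed,
                           mode = mode, correlation = correlation)$bsr
  sb <- scoreBehaviorCorrelations(scores, Y,
                                  n_boot = if (n_boot > 0) min(n_boot, 1000) else 0,
                                  seed = seed)
  new("PLSResult", u = obs$u, v = obs$v, d = obs$d, explained = obs$explained,
      brain_scores = scores, perm_p = perm_p, bsr = bsr, score_behavior = sb,
      meta = list(mode = mode, correlation = correlation, n_perm = n_perm,
                  n_boot = n_boot, seed = seed))
}
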