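# Random-effects Bayesian model selection, family inference, BMA, and
# coupling bootstraps.

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the hierarchical Dirichlet-multinomial model
#' over model frequencies: iterate subject responsibilities
#' g_nk proportional to exp(F_nk + log alpha_k - log sum(alpha)) and
#' alpha_k = alpha0_k + sum_n g_nk until convergence. The expected posterior
#' probability (EPP) is alpha / sum(alpha); the exceedance probability (EP)
#' is estimated by Monte-Carlo sampling of the Dirichlet posterior as the
#' fraction of draws in which each model has the largest frequency.
#'
#' The responsibility update weights models by the posterior mean frequency
#' (log alpha) rather than its geometric-mean counterpart (digamma alpha).
#' The two coincide for alpha well above 1 and under any uniform prior, but
#' the digamma form is degenerate under the size-corrected (non-uniform)
#' family priors of [familyInference()]: with equal evidence it funnels all
#' responsibility into the largest-prior model, where exact inference leaves
#' the prior untouched. The mean form preserves that exact symmetry.
#'
#' @param F subjects x models matrix of log-evidence approximations (free
#'   energies).
#' @param alpha0 Dirichlet prior counts; scalar or per-model vector.
#' @param n_samples Monte-Carlo draws for the EP (>= 1e5 recommended).
#' @param seed RNG seed for the EP sampling.
#' @param tol,max_iter convergence controls for the variational loop.
#' @return A [BMSResult-class].
#' @export
rfxBMS <- function(F, alpha0 = 1, n_samples = 1e5, seed = 1,
                   tol = 1e-8, max_iter = 500) {
  F <- as.matrix(F)
  if (any(!is.finite(F))) stop("free energies must be finite")
  K <- ncol(F); N <- nrow(F)
  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0 + N / K
  g <- matrix(1 / K, N, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(F, 2, log(alpha) - log(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  epp <- alpha / sum(alpha)
  ep <- dirichletExceedance(alpha, n_samples, seed)
  new("BMSResult", alpha = as.numeric(alpha), alpha0 = as.numeric(alpha0),
      epp = as.numeric(epp), ep = ep, g = g, families = list())
}

dirichletExceedance <- function(alpha, n_samples, seed, groups = NULL) {
  K <- length(alpha)
  if (K == 1) return(1)
  withSeed(deriveSeed(seed, "bms", K), {
    draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                    n_samples, K)
    if (!is.null(groups)) {
      agg <- vapply(groups, function(ix) rowSums(draws[, ix, drop = FALSE]),
                    numeric(n_samples))
      wins <- max.col(agg, ties.method = "first")
      tabulate(wins, length(groups)) / n_samples
    } else {
      wins <- max.col(draws, ties.method = "first")
      tabulate(wins, K) / n_samples
    }
  })
}

#' Family-level Bayesian model selection
#'
#' Runs [rfxBMS()] with per-model prior counts scaled inversely to family
#' size (so every family carries equal prior mass), then aggregates the
#' sampled Dirichlet frequencies within families: the family exceedance
#' probability is the probability that the family's summed frequency is the
#' largest, and the family EPP is the summed model EPP.
#'
#' @param F subjects x models free-energy matrix.
#' @param families named list mapping family name to model column indices; a
#'   non-overlapping cover of all models.
#' @param n_samples,seed,tol,max_iter passed to the underlying scheme.
#' @return A [BMSResult-class] at the family level (slot `families` carries
#'   the partition; slot `g` the subjects x models responsibilities).
#' @export
familyInference <- function(F, families, n_samples = 1e5, seed = 1,
                            tol = 1e-8, max_iter = 500) {
  F <- as.matrix(F)
  K <- ncol(F)
  all_idx <- sort(unname(unlist(families)))
  if (anyDuplicated(all_idx))
    stop("overlapping families")
  if (!identical(as.integer(all_idx), seq_len(K)))
    stop("families must partition all models")
  sizes <- vapply(families, length, 1L)
  alpha0 <- numeric(K)
  for (f in seq_along(families)) alpha0[families[[f]]] <- 1 / sizes[f]
  fit <- rfxBMS(F, alpha0 = alpha0, n_samples = n_samples, seed = seed,
                tol = tol, max_iter = max_iter)
  fam_alpha <- vapply(families, function(ix) sum(fit@alpha[ix]), numeric(1))
  fam_alpha0 <- vapply(families, function(ix) sum(alpha0[ix]), numeric(1))
  fam_epp <- vapply(families, function(ix) sum(fit@epp[ix]), numeric(1))
  fam_ep <- dirichletExceedance(fit@alpha, n_samples, seed, groups = families)
  names(fam_ep) <- names(families)
  new("BMSResult", alpha = fam_alpha, alpha0 = fam_alpha0,
      epp = fam_epp, ep = fam_ep, g = fit@g, families = families)
}

#' Bayesian model averaging of DCM parameters within a family
#'
#' For each subject, averages the fitted A, B and C matrices over the family
#' members, weighted by that subject's posterior model probabilities (free
#' energies restricted to the family and renormalized). Entries absent from a
#' model's structure contribute zero, as in standard BMA over structures.
#'
#' @param fits list over subjects; each element a list of [DCMFit-class] for
#'   the family members (same order across subjects).
#' @return list over subjects, each with averaged `A`, `B` (list per input),
#'   `C`, and `weights`.
#' @export
bmaParameters <- function(fits) {
  lapply(fits, function(subject_fits) {
    Fv <- vapply(subject_fits, freeEnergy, numeric(1))
    w <- exp(Fv - max(Fv)); w <- w / sum(w)
    A <- Reduce(`+`, Map(function(f, wi) wi * f@A, subject_fits, w))
    nin <- length(subject_fits[[1]]@B)
    B <- lapply(seq_len(nin), function(j)
      Reduce(`+`, Map(function(f, wi) wi * f@B[[j]], subject_fits, w)))
    C <- Reduce(`+`, Map(function(f, wi) wi * f@C, subject_fits, w))
    list(A = A, B = B, C = C, weights = w)
  })
}

#' Extract effective-connectivity couplings from BMA results
#'
#' Builds the subjects x parameters matrix of effective connectivity
#' (A + B) for the couplings from a source region to each target region
#' under each modulatory input — e.g. the 12 parameters (3 MTL targets x
#' 2 valences x 2 awareness levels) when four modulatory inputs are modelled.
#'
#' @param bma list from [bmaParameters()].
#' @param source source region name (default "MFG").
#' @param targets target region names.
#' @param inputs indices of the modulatory inputs to report.
#' @return subjects x (targets x inputs) numeric matrix with descriptive
#'   column names.
#' @export
couplingMatrix <- function(bma, source = "MFG", targets = c("PhC", "Hip", "Amg"),
                           inputs = NULL) {
  regions <- rownames(bma[[1]]$A)
  inputs <- inputs %||% seq_along(bma[[1]]$B)[-1]
  cols <- expand.grid(target = targets, input = inputs, stringsAsFactors = FALSE)
  out <- t(vapply(bma, function(s) {
    vapply(seq_len(nrow(cols)), function(i) {
      tg <- cols$target[i]; j <- cols$input[i]
      s$A[tg, source] + s$B[[j]][tg, source]
    }, numeric(1))
  }, numeric(nrow(cols))))
  colnames(out) <- sprintf("%s<-%s:u%d", cols$target, source, cols$input)
  out
}

#' Bootstrap confidence intervals for coupling parameters
#'
#' Resamples subjects with replacement, takes the mean of each parameter per
#' draw, and reports percentile CIs at the Bonferroni-corrected level
#' [correctedCILevel()] for the stated number of comparisons. A parameter is
#' flagged significant when its CI excludes zero. Optionally drops subjects
#' with any parameter more than `outlier_sd` SDs from the cohort mean before
#' resampling.
#'
#' @param params subjects x parameters matrix (e.g. from [couplingMatrix()]).
#' @param n_boot bootstrap draws.
#' @param n_comparisons comparisons for the Bonferroni-corrected CI level.
#' @param seed RNG seed.
#' @param exclude_outliers apply the aberrant-subject rule.
#' @param outlier_sd SD multiple for the exclusion rule.
#' @return data.frame parameter, mean, ci_low, ci_high, significant;
#'   attributes `"level"` and `"excluded"` (row indices dropped).
#' @export
couplingBootstrap <- function(params, n_boot = 5000, n_comparisons = 12,
                              seed = 1, exclude_outliers = FALSE,
                              outlier_sd = 4) {
  params <- as.matrix(params)
  excluded <- integer()
  if (exclude_outliers) {
    mu <- colMeans(params); sdv <- apply(params, 2, sd)
    sdv[sdv == 0] <- Inf
    z <- abs(sweep(sweep(params, 2, mu), 2, sdv, `/`))
    excluded <- which(apply(z, 1, max) > outlier_sd)
    if (length(excluded)) params <- params[-excluded, , drop = FALSE]
  }
  n <- nrow(params)
  if (n < 5) stop("need at least 5 subjects")
  level <- correctedCILevel(n_comparisons)
  alpha <- 1 - as.numeric(level) / 100
  means <- withSeed(deriveSeed(seed, "boot", n), {
    t(vapply(seq_len(n_boot), function(b) {
      colMeans(params[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(params))))
  })
  ci <- apply(means, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2), type = 6)
  out <- data.frame(parameter = colnames(params) %||% paste0("p", seq_len(ncol(params))),
                    mean = colMeans(params),
                    ci_low = ci[1, ], ci_high = ci[2, ])
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  rownames(out) <- NULL
  attr(out, "level") <- as.numeric(level)
  attr(out, "excluded") <- excluded
  out
}
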