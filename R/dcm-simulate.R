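# Bilinear DCM forward model: neural integration + canonical HRF observation.

#' Canonical double-gamma hemodynamic response function
#'
#' h(t) = g(t; 6, 1) - g(t; 16, 1) / 6 with gamma densities g, sampled on a
#' grid of step `dt` over `duration` seconds and scaled to unit peak. This
#' fixed linear observation kernel replaces a full biophysical hemodynamic
#' model: the coupling questions the engine addresses concern signs and
#' family identity of the neural parameters, for which a known linear
#' observation map is sufficient and keeps estimation fast and testable.
#'
#' @param dt grid step in seconds.
#' @param duration kernel support in seconds.
#' @return numeric kernel (first element at t = 0).
#' @export
canonicalHRF <- function(dt = 0.1, duration = 30) {
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

checkStability <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  worst <- which.max(Re(ev))
  if (Re(ev[worst]) >= 0)
    stop(sprintf("unstable intrinsic matrix: eigenvalue %s has non-negative real part",
                 format(ev[worst], digits = 4)))
  invisible(ev)
}

#' Simulate a bilinear DCM
#'
#' Integrates the bilinear neural state equation
#' dz/dt = (A + sum_j u_j B_j) z + C u with classical 4th-order Runge-Kutta
#' on the input grid (inputs are piecewise constant boxcars), convolves the
#' neural states with the canonical double-gamma HRF, samples at the scanner
#' TR and optionally adds iid Gaussian observation noise.
#'
#' @param A regions x regions intrinsic coupling (Hz); all real parts of its
#'   eigenvalues must be negative.
#' @param B list of regions x regions modulatory matrices, one per input
#'   column (use zero matrices for non-modulatory inputs).
#' @param C regions x inputs driving weights.
#' @param inputs input set from [dcmInputs()].
#' @param TR sampling interval of the observed series (seconds).
#' @param noise_sd observation noise SD (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param z0 initial neural state (default zeros).
#' @param conv_dt grid step used for the HRF convolution; neural states are
#'   block-averaged to this resolution first (the HRF is smooth at 0.5 s).
#' @param check verify stability of A (skipped by the estimator, which has
#'   already screened the proposal).
#' @return list: `bold` (scans x regions), `time` (scan times), `neural`
#'   (fine-grid states), `inputs`.
#' @export
dcmSimulate <- function(A, B, C, inputs, TR = 2, noise_sd = 0, seed = 1,
                        z0 = NULL, conv_dt = 0.5, check = TRUE) {
  A <- as.matrix(A)
  nr <- nrow(A)
  if (check) checkStability(A)
  U <- inputs$U
  nin <- ncol(U)
  if (is.matrix(B)) B <- list(B)
  if (length(B) < nin) B <- c(B, rep(list(matrix(0, nr, nr)), nin - length(B)))
  C <- as.matrix(C)
  if (ncol(C) != nin) stop("C must have one column per input")
  z0 <- z0 %||% numeric(nr)
  Bcube <- array(unlist(lapply(B[seq_len(nin)], as.matrix)), c(nr, nr, nin))

  Z <- .dcmIntegrate(A, Bcube, C, U, z0, inputs$dt)

  # block-average to the convolution grid, convolve, then sample at TR
  m <- max(1L, round(conv_dt / inputs$dt))
  nblk <- floor(nrow(Z) / m)
  Zc <- if (m > 1) {
    colMeans(array(Z[seq_len(nblk * m), , drop = FALSE], c(m, nblk, ncol(Z))))
  } else Z
  dt2 <- inputs$dt * m
  kern <- canonicalHRF(dt = dt2) * dt2
  Bold_fine <- .dcmConvolve(as.matrix(Zc), kern)
  t_fine <- (seq_len(nblk) - 0.5) * dt2
  scan_times <- seq(TR, t_fine[nblk], by = TR)
  sidx <- pmin(nblk, pmax(1L, as.integer(round(scan_times / dt2 + 0.5))))
  bold <- Bold_fine[sidx, , drop = FALSE]
  colnames(bold) <- rownames(A) %||% paste0("r", seq_len(nr))
  if (noise_sd > 0)
    bold <- bold + withSeed(deriveSeed(seed, "dcm", nrow(bold)), {
      matrix(rnorm(length(bold), 0, noise_sd), nrow(bold), ncol(bold))
    })
  list(bold = bold, time = scan_times, neural = Z, inputs = inputs)
}

#' Generate synthetic region time series from a known DCM
#'
#' Convenience wrapper around [dcmSimulate()] that accepts a
#' [DCMModel-class] plus true parameter values and returns a tidy
#' time-by-region table, as consumed by [dcmEstimate()].
#'
#' @param model a [DCMModel-class].
#' @param params list with matrices `A`, `B` (list per input) and `C`; entries
#'   outside the model's masks must be zero.
#' @param inputs input set from [dcmInputs()].
#' @param noise_sd observation noise SD.
#' @param seed RNG seed.
#' @param TR sampling interval.
#' @return data.frame with column `time` followed by one column per region;
#'   attribute `"inputs"` carries the input set.
#' @export
generateDCMTimeseries <- function(model, params, inputs, noise_sd = 0.05,
                                  seed = 1, TR = 2) {
  stopifnot(is(model, "DCMModel"))
  sim <- dcmSimulate(params$A, params$B, params$C, inputs, TR = TR,
                     noise_sd = noise_sd, seed = seed)
  out <- data.frame(time = sim$time, sim$bold, check.names = FALSE)
  colnames(out)[-1] <- model@regions
  attr(out, "inputs") <- inputs
  out
}
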