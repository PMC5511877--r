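# Peak-seeded contiguous ROI selection on statistic maps.

neighborOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# lexicographic rank on (x, y, z) used for all tie-breaking
lexRank <- function(coords, dims) {
  (coords[, 1] - 1) * dims[2] * dims[3] + (coords[, 2] - 1) * dims[3] +
    coords[, 3]
}

#' Find the peak voxel of a statistic map
#'
#' Returns the mask voxel with the largest (direction "max") or smallest
#' (direction "min") statistic. Ties are broken by lexicographic coordinate
#' order (x, then y, then z).
#'
#' @param map a [StatMap-class].
#' @param direction "max" or "min".
#' @return integer vector c(x, y, z).
#' @export
findPeak <- function(map, direction = c("max", "min")) {
  stopifnot(is(map, "StatMap"))
  direction <- match.arg(direction)
  idx <- which(map@mask)
  if (!length(idx)) stop("empty mask")
  vals <- map@values[idx]
  best <- if (direction == "max") max(vals) else min(vals)
  cand <- idx[vals == best]
  coords <- arrayInd(cand, dim(map@values))
  coords[which.min(lexRank(coords, dim(map@values))), ]
}

#' Grow a contiguous ROI from a peak
#'
#' Greedy region growing: starting from the peak voxel, repeatedly adds the
#' frontier voxel (a mask voxel neighbouring the current region under the
#' map's connectivity) with the most significant statistic in the given
#' direction, until the region reaches `max(1, round(fraction * mask size))`
#' voxels (round half up). The output is connected and contains the peak;
#' frontier ties are broken lexicographically. If the connected component of
#' the peak is smaller than the target, the whole component is returned with
#' a warning.
#'
#' @param map a [StatMap-class].
#' @param peak integer c(x, y, z), inside the mask (e.g. from [findPeak()]).
#' @param fraction target ROI size as a fraction of the mask size (0 < f <= 1).
#' @param direction "max": grow towards large statistics; "min": small.
#' @return integer matrix of voxel coordinates (one row per voxel, in
#'   inclusion order), with attribute `"target_size"`.
#' @export
growROI <- function(map, peak, fraction, direction = c("max", "min")) {
  stopifnot(is(map, "StatMap"))
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  dims <- dim(map@values)
  peak <- as.integer(peak)
  if (length(peak) == 2L) peak <- c(peak, 1L)
  if (!map@mask[peak[1], peak[2], peak[3]]) stop("peak is outside the mask")
  target <- max(1L, as.integer(floor(fraction * sum(map@mask) + 0.5)))
  offs <- neighborOffsets(map@connectivity)
  sgn <- if (direction == "max") 1 else -1

  in_region <- array(FALSE, dims)
  in_frontier <- array(FALSE, dims)
  region <- matrix(peak, nrow = 1)
  in_region[peak[1], peak[2], peak[3]] <- TRUE

  # frontier kept as a running matrix of candidate coords
  frontier <- matrix(integer(), 0, 3)
  push_neighbors <- function(vox) {
    nb <- sweep(offs, 2, vox, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) return(invisible())
    keep <- map@mask[nb] & !in_region[nb] & !in_frontier[nb]
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb)) {
      in_frontier[nb] <<- TRUE
      frontier <<- rbind(frontier, nb)
    }
    invisible()
  }
  push_neighbors(peak)

  while (nrow(region) < target) {
    if (!nrow(frontier)) {
      warning("connected component of the peak (", nrow(region),
              " voxels) is smaller than the target size ", target)
      break
    }
    vals <- sgn * map@values[frontier]
    best <- which(vals == max(vals))
    if (length(best) > 1)
      best <- best[which.min(lexRank(frontier[best, , drop = FALSE], dims))]
    vox <- frontier[best, ]
    frontier <- frontier[-best, , drop = FALSE]
    in_frontier[vox[1], vox[2], vox[3]] <- FALSE
    in_region[vox[1], vox[2], vox[3]] <- TRUE
    region <- rbind(region, vox)
    push_neighbors(vox)
  }
  dimnames(region) <- list(NULL, c("x", "y", "z"))
  attr(region, "target_size") <- target
  region
}

#' Per-subject mean contrast within an ROI
#'
#' Averages contrast values over the ROI voxels for each subject. The ROI may
#' be given as voxel row indices into a [BrainMatrix-class] or as a
#' coordinate matrix matched against the BrainMatrix voxel coordinates.
#'
#' @param brain a [BrainMatrix-class] (or plain subjects x voxels matrix).
#' @param roi integer voxel indices, or a matrix of voxel coordinates with
#'   columns x, y, z.
#' @return named numeric vector, one mean per subject.
#' @export
roiContrast <- function(brain, roi) {
  X <- if (is(brain, "BrainMatrix")) brainX(brain) else as.matrix(brain)
  if (is.matrix(roi) && ncol(roi) >= 3) {
    if (!is(brain, "BrainMatrix"))
      stop("coordinate ROIs require a BrainMatrix with voxel coordinates")
    vi <- voxelInfo(brain)
    key <- paste(vi$x, vi$y, vi$z, sep = ",")
    idx <- match(paste(roi[, 1], roi[, 2], roi[, 3], sep = ","), key)
    if (any(is.na(idx))) stop("ROI voxels not found in the data")
    roi <- idx
  }
  roi <- as.integer(roi)
  if (!length(roi)) stop("ROI is empty")
  if (any(roi < 1 | roi > ncol(X))) stop("ROI is disjoint from the data")
  rowMeans(X[, roi, drop = FALSE])
}
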