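# Shared fixtures and independent oracles for the test suite.

# Small cohort: n subjects, default design unless overridden.
makeCohort <- function(n_subjects = 24, seed = 1, truth = cohortTruth(), ...) {
  spec <- designSpec(n_subjects = n_subjects, seed = seed, ...)
  design <- generateDesign(spec)
  behavior <- generateBehavior(design, truth, seed = seed + 1)
  list(spec = spec, design = design, behavior = behavior)
}

# Hand-built No-Think trial table: one subject, one valence, n_items x
# n_blocks, with a per-block intrusion count (first `count` items intrude).
makeTrialTable <- function(counts, n_items = 8, valence = "negative",
                           subject = 1) {
  do.call(rbind, lapply(seq_along(counts), function(b) {
    data.frame(subject = subject, valence = valence, block = b,
               condition = "NoThink",
               item = sprintf("it%02d", seq_len(n_items)),
               report = c(rep("briefly", counts[b]),
                          rep("never", n_items - counts[b])))
  }))
}

# Independent brute-force oracle for greedy ROI growth: at every step,
# re-enumerate the full frontier from scratch by scanning all region voxels'
# neighbourhoods, then take the best (ties: lexicographic on x, y, z).
bruteForceGrow <- function(values, mask, peak, target, connectivity = 26,
                           direction = "max") {
  dims <- dim(values)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  sgn <- if (direction == "max") 1 else -1
  region <- matrix(peak, nrow = 1)
  repeat {
    if (nrow(region) >= target) break
    frontier <- NULL
    for (i in seq_len(nrow(region))) {
      nb <- sweep(offs, 2, region[i, ], `+`)
      for (j in seq_len(nrow(nb))) {
        v <- nb[j, ]
        if (any(v < 1) || any(v > dims)) next
        if (!mask[v[1], v[2], v[3]]) next
        in_reg <- any(region[, 1] == v[1] & region[, 2] == v[2] &
                        region[, 3] == v[3])
        if (in_reg) next
        frontier <- rbind(frontier, v)
      }
    }
    if (is.null(frontier)) break
    frontier <- unique(frontier)
    vals <- sgn * values[frontier]
    best <- which(vals == max(vals))
    if (length(best) > 1) {
      lex <- (frontier[best, 1] - 1) * dims[2] * dims[3] +
        (frontier[best, 2] - 1) * dims[3] + frontier[best, 3]
      best <- best[which.min(lex)]
    }
    region <- rbind(region, frontier[best, ])
  }
  region
}

# Random statistic map on a masked grid (seeded).
randomStatMap <- function(dims, seed, p_mask = 0.9, connectivity = 26) {
  set.seed(seed)
  vals <- array(rnorm(prod(dims)), dims)
  mask <- array(runif(prod(dims)) < p_mask, dims)
  # ensure a non-empty mask
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  vals[!mask] <- NA
  statMap(array(ifelse(mask, vals, 0), dims), mask, connectivity = connectivity)
}
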