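#' @rdname brainX
#' @export
setGeneric("brainX", function(object) standardGeneric("brainX"))

#' Extract the subjects x voxels matrix from a BrainMatrix
#'
#' @param object a [BrainMatrix-class].
#' @return numeric matrix, subjects in rows, voxels in columns.
#' @rdname brainX
#' @export
setMethod("brainX", "BrainMatrix", function(object) {
  t(SummarizedExperiment::assay(object, "contrast"))
})

#' @rdname voxelInfo
#' @export
setGeneric("voxelInfo", function(object) standardGeneric("voxelInfo"))

#' Voxel metadata (coordinates and ROI labels)
#'
#' @param object a [BrainMatrix-class].
#' @return data.frame with columns x, y, z, roi_label.
#' @rdname voxelInfo
#' @export
setMethod("voxelInfo", "BrainMatrix", function(object) {
  as.data.frame(SummarizedExperiment::rowData(object))
})

#' @rdname pls-accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' Accessors for PLSResult
#'
#' `singularValues()` returns the singular values, `explainedCovariance()` the
#' proportion of squared cross-block covariance per LV, `brainScores()` the
#' subjects x LVs score matrix, `voxelSaliences()` the voxel singular vectors,
#' `behavioralSaliences()` the behavioral singular vectors, `permutationP()`
#' the per-LV permutation p values and `bsrMap()` the bootstrap standard
#' ratios.
#'
#' @param object a [PLSResult-class].
#' @name pls-accessors
#' @rdname pls-accessors
#' @export
setMethod("singularValues", "PLSResult", function(object) object@d)

#' @rdname pls-accessors
#' @export
setGeneric("explainedCovariance", function(object) standardGeneric("explainedCovariance"))
#' @rdname pls-accessors
#' @export
setMethod("explainedCovariance", "PLSResult", function(object) object@explained)

#' @rdname pls-accessors
#' @export
setGeneric("brainScores", function(object) standardGeneric("brainScores"))
#' @rdname pls-accessors
#' @export
setMethod("brainScores", "PLSResult", function(object) object@brain_scores)

#' @rdname pls-accessors
#' @export
setGeneric("voxelSaliences", function(object) standardGeneric("voxelSaliences"))
#' @rdname pls-accessors
#' @export
setMethod("voxelSaliences", "PLSResult", function(object) object@v)

#' @rdname pls-accessors
#' @export
setGeneric("behavioralSaliences", function(object) standardGeneric("behavioralSaliences"))
#' @rdname pls-accessors
#' @export
setMethod("behavioralSaliences", "PLSResult", function(object) object@u)

#' @rdname pls-accessors
#' @export
setGeneric("permutationP", function(object) standardGeneric("permutationP"))
#' @rdname pls-accessors
#' @export
setMethod("permutationP", "PLSResult", function(object) object@perm_p)

#' @rdname pls-accessors
#' @export
setGeneric("bsrMap", function(object) standardGeneric("bsrMap"))
#' @rdname pls-accessors
#' @export
setMethod("bsrMap", "PLSResult", function(object) object@bsr)

#' @rdname bms-accessors
#' @export
setGeneric("exceedanceProb", function(object) standardGeneric("exceedanceProb"))

#' Accessors for BMSResult
#'
#' `exceedanceProb()` returns the exceedance probabilities and
#' `expectedPosteriorProb()` the expected posterior probabilities
#' (Dirichlet means).
#'
#' @param object a [BMSResult-class].
#' @name bms-accessors
#' @rdname bms-accessors
#' @export
setMethod("exceedanceProb", "BMSResult", function(object) object@ep)

#' @rdname bms-accessors
#' @export
setGeneric("expectedPosteriorProb", function(object) standardGeneric("expectedPosteriorProb"))
#' @rdname bms-accessors
#' @export
setMethod("expectedPosteriorProb", "BMSResult", function(object) object@epp)

#' @rdname dcm-accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))

#' Accessors for DCMFit
#'
#' `freeEnergy()` returns the Laplace log-evidence approximation;
#' `effectiveConnectivity()` returns A + B for a given input (condition),
#' i.e. the coupling in effect while that input is on.
#'
#' @param object a [DCMFit-class].
#' @param input input index (1-based) selecting which modulatory matrix is
#'   added to A.
#' @name dcm-accessors
#' @rdname dcm-accessors
#' @export
setMethod("freeEnergy", "DCMFit", function(object) object@free_energy)

#' @rdname dcm-accessors
#' @export
setGeneric("effectiveConnectivity",
           function(object, input = 1L) standardGeneric("effectiveConnectivity"))
#' @rdname dcm-accessors
#' @export
setMethod("effectiveConnectivity", "DCMFit", function(object, input = 1L) {
  if (input > length(object@B)) stop("model has no input ", input)
  object@A + object@B[[input]]
})

setMethod("show", "DesignSpec", function(object) {
  cat("DesignSpec:", object@n_subjects, "subjects,",
      object@n_sessions, "sessions x", object@reps_per_session, "reps,",
      object@cues_per_condition_per_valence, "cues/condition/valence\n")
  cat("  cue", object@cue_duration_s, "s, ITI",
      paste(object@iti_range_s, collapse = "-"), "s,",
      object@baseline_pairs_per_valence, "baseline pairs/valence, seed",
      object@seed, "\n")
})

setMethod("show", "StatMap", function(object) {
  cat("StatMap:", paste(dim(object@values), collapse = " x "),
      "grid,", sum(object@mask), "mask voxels,",
      object@connectivity, "-neighbourhood\n", sep = " ")
})

setMethod("show", "SkippedCorrelation", function(object) {
  cat(sprintf("Skipped correlation: r = %.3f (n = %d, %d outlier%s removed)\n",
              object@r, object@n_used, length(object@outlier_indices),
              if (length(object@outlier_indices) == 1) "" else "s"))
  if (!any(is.na(object@ci)))
    cat(sprintf("  %.1f%% percentile bootstrap CI [%.3f, %.3f] (%d draws)\n",
                object@level, object@ci[1], object@ci[2], object@n_boot))
  if (length(object@significant) && !is.na(object@significant))
    cat("  significant:", object@significant, "\n")
})

setMethod("show", "PLSResult", function(object) {
  cat("Behavioral PLS:", length(object@d), "LV(s),",
      nrow(object@brain_scores), "subjects,", nrow(object@v), "voxels\n")
  for (k in seq_along(object@d))
    cat(sprintf("  LV%d: singular value %.4g, %.1f%% covariance%s\n", k,
                object@d[k], 100 * object@explained[k],
                if (!is.na(object@perm_p[k]))
                  sprintf(", perm p = %.4f", object@perm_p[k]) else ""))
})

setMethod("show", "DCMModel", function(object) {
  cat("DCMModel", object@name, "(", paste(object@regions, collapse = ", "), ")\n")
  cat("  modulation:", object@modulatory_type,
      if (length(object@regulation_targets))
        paste("on", paste(object@regulation_targets, collapse = "+")) else "",
      "| family:", object@regulation_family, "\n")
})

setMethod("show", "DCMFit", function(object) {
  cat("DCMFit of", object@model@name, "- F =", format(object@free_energy),
      if (object@converged) "(converged)\n" else "(budget exhausted)\n")
})

setMethod("show", "BMSResult", function(object) {
  cat("Random-effects BMS over", length(object@alpha), "units\n")
  cat("  EP :", paste(sprintf("%.3f", object@ep), collapse = " "), "\n")
  cat("  EPP:", paste(sprintf("%.3f", object@epp), collapse = " "), "\n")
})
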