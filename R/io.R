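# Delimited-text and JSON-sidecar I/O for every stage artifact.

#' Write / read a behavioral table
#'
#' Tab-delimited text with a fixed header row; missing values written as NA.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `readBehaviorTable` returns a data.frame.
#' @export
writeBehaviorTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehaviorTable
#' @export
readBehaviorTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a BrainMatrix as delimited text plus JSON sidecar
#'
#' The matrix is written subjects x voxels as tab-delimited text; voxel
#' coordinates and ROI labels go to a `.json` sidecar next to it.
#'
#' @param brain a [BrainMatrix-class].
#' @param path path of the `.tsv` file.
#' @return `readBrainMatrix` returns a [BrainMatrix-class].
#' @export
writeBrainMatrix <- function(brain, path) {
  X <- brainX(brain)
  write.table(data.frame(subject = rownames(X), X, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  vi <- voxelInfo(brain)
  jsonlite::write_json(list(voxels = vi), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBrainMatrix
#' @export
readBrainMatrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(X) <- list(tab$subject, NULL)
  vi <- meta$voxels
  brainMatrix(X, coords = cbind(vi$x, vi$y, vi$z), roi_labels = vi$roi_label,
              subjects = as.character(tab$subject))
}

#' Write region time series with a JSON header
#'
#' Time x regions tab-delimited table; TR and input onsets recorded in a
#' `.json` sidecar.
#'
#' @param series data.frame from [generateDCMTimeseries()].
#' @param path path of the `.tsv` file.
#' @param TR repetition time in seconds.
#' @export
writeTimeseries <- function(series, path, TR = 2) {
  write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  inputs <- attr(series, "inputs")
  hdr <- list(TR = TR, dt = inputs$dt %||% NA,
              n_inputs = if (!is.null(inputs)) ncol(inputs$U) else 0)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# JSON results sidecar for resampled procedures (n_iter, seed, level, values).
writeResultsJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
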