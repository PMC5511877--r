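# DCM model-space construction.

dcmRegions <- c("MFG", "PhC", "Hip", "Amg")
dcmMTL <- c("PhC", "Hip", "Amg")

#' Construct a single DCM model structure
#'
#' All models share a fully bidirectional intrinsic backbone: the three MTL
#' regions (parahippocampal cortex, hippocampus, amygdala) are mutually and
#' bidirectionally connected, and the MFG is bidirectionally connected to
#' each MTL region. Input 1 is the driving input (Think + No-Think cues
#' entering MFG). Remaining inputs are modulatory: depending on
#' `modulatory_type` they scale the MFG->target ("top-down"), target->MFG
#' ("bottom-up"), or both ("bidirectional") connections for the regulation
#' targets; "afferent" models place extra driving entries on the targets
#' instead of modulating connections (joint entry to all targets); "null"
#' models have no modulation at all.
#'
#' @param modulatory_type one of bottom-up, top-down, bidirectional,
#'   afferent, null.
#' @param regulation_targets character subset of PhC, Hip, Amg (ignored and
#'   empty for "null").
#' @param n_mod_inputs number of modulatory inputs (e.g. 4 for the
#'   Negative/Neutral x Intrusion/Non-Intrusion No-Think epochs, 1 for a
#'   collapsed No-Think input).
#' @param regions ordered region names; the first is the control source.
#' @param name optional model label.
#' @return A [DCMModel-class].
#' @export
dcmModel <- function(modulatory_type, regulation_targets = character(),
                     n_mod_inputs = 1, regions = dcmRegions, name = NULL) {
  nr <- length(regions)
  src <- regions[1]
  if (modulatory_type == "null") regulation_targets <- character()
  else if (modulatory_type != "null" && !length(regulation_targets))
    stop("empty regulation-target subset requested")
  if (!all(regulation_targets %in% regions[-1]))
    stop("regulation targets must be non-source regions")
  a_mask <- matrix(TRUE, nr, nr, dimnames = list(regions, regions))
  n_inputs <- 1 + n_mod_inputs
  c_mask <- matrix(FALSE, nr, n_inputs,
                   dimnames = list(regions, c("driving",
                                              paste0("mod", seq_len(n_mod_inputs)))))
  c_mask[src, 1] <- TRUE
  empty <- matrix(FALSE, nr, nr, dimnames = list(regions, regions))
  b_masks <- rep(list(empty), n_inputs)
  for (j in seq_len(n_mod_inputs) + 1L) {
    if (modulatory_type %in% c("top-down", "bidirectional"))
      b_masks[[j]][regulation_targets, src] <- TRUE
    if (modulatory_type %in% c("bottom-up", "bidirectional"))
      b_masks[[j]][src, regulation_targets] <- TRUE
    if (modulatory_type == "afferent")
      c_mask[regulation_targets, j] <- TRUE
  }
  fam <- regulationFamily(regulation_targets)
  name <- name %||% paste0(modulatory_type,
                           if (length(regulation_targets))
                             paste0(":", paste(regulation_targets, collapse = "+"))
                           else "")
  new("DCMModel", name = name, regions = regions, a_mask = a_mask,
      b_masks = b_masks, c_mask = c_mask, modulatory_type = modulatory_type,
      regulation_targets = regulation_targets, regulation_family = fam)
}

regulationFamily <- function(targets) {
  if (!length(targets)) return("none")
  has_amg <- "Amg" %in% targets
  has_mem <- any(c("PhC", "Hip") %in% targets)
  if (has_amg && has_mem) "Parallel"
  else if (has_amg) "Emotion"
  else "Memory"
}

#' Enumerate the DCM model space
#'
#' Builds the grid of models over modulatory types and regulation-target
#' subsets: for each modulated type, the 7 non-empty subsets of
#' \{PhC, Hip, Amg\} grouped into the Emotion (Amg only), Memory (PhC, Hip,
#' PhC+Hip) and Parallel (Amg+Hip, Amg+PhC, all three) regulation families,
#' plus an optional null model. The full grid over the four modulated types
#' plus null enumerates 29 models; restricting to the top-down and
#' bidirectional types gives the 14-model top-down subfamily.
#'
#' @param modulatory_types types to enumerate.
#' @param target_sets list of target subsets (default: all 7 non-empty
#'   subsets of PhC/Hip/Amg).
#' @param include_null include the unmodulated null model.
#' @param n_mod_inputs modulatory inputs per model.
#' @param regions ordered region names.
#' @return list of [DCMModel-class] objects.
#' @examples
#' length(buildModelSpace())  # 29
#' length(buildModelSpace(c("top-down", "bidirectional"), include_null = FALSE))  # 14
#' @export
buildModelSpace <- function(modulatory_types = c("bottom-up", "top-down",
                                                 "bidirectional", "afferent"),
                            target_sets = NULL, include_null = TRUE,
                            n_mod_inputs = 1, regions = dcmRegions) {
  if (is.null(target_sets)) {
    target_sets <- list("Amg", "Hip", "PhC", c("Hip", "PhC"),
                        c("Amg", "Hip"), c("Amg", "PhC"),
                        c("Amg", "Hip", "PhC"))
  }
  if (any(vapply(target_sets, length, 1L) == 0))
    stop("empty regulation-target subset requested")
  models <- list()
  for (ty in modulatory_types)
    for (ts in target_sets)
      models <- c(models, dcmModel(ty, ts, n_mod_inputs = n_mod_inputs,
                                   regions = regions))
  if (include_null)
    models <- c(models, dcmModel("null", n_mod_inputs = n_mod_inputs,
                                 regions = regions))
  models
}

#' Regulation-family partition of a model list
#'
#' @param models list of [DCMModel-class].
#' @return named list mapping family name to model indices.
#' @export
modelFamilies <- function(models) {
  fam <- vapply(models, function(m) m@regulation_family, character(1))
  split(seq_along(models), fam)
}

#' Build boxcar input functions on a fine time grid
#'
#' @param duration_s total duration in seconds.
#' @param dt grid step (<= 0.1 s).
#' @param events list, one element per input, each a data.frame with columns
#'   `onset` and optionally `duration` (default 3 s boxcars).
#' @param input_names optional input names.
#' @return list with `U` (time x inputs matrix), `dt`, `time`.
#' @export
dcmInputs <- function(duration_s, dt = 0.1, events = list(), input_names = NULL) {
  if (dt > 0.1 + 1e-12) stop("inputs must live on a fine grid (dt <= 0.1 s)")
  time <- seq(0, duration_s - dt / 2, by = dt)
  U <- matrix(0, length(time), length(events))
  for (j in seq_along(events)) {
    ev <- events[[j]]
    dur <- if ("duration" %in% names(ev)) ev$duration else rep(3, nrow(ev))
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset[i]
      idx <- which(time >= on - 1e-9 & time < on + dur[i] - 1e-9)
      U[idx, j] <- 1
    }
  }
  colnames(U) <- input_names %||%
    (if (length(events)) paste0("u", seq_along(events) - 1) else character())
  list(U = U, dt = dt, time = time)
}
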