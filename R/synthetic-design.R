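#' Generate a Think/No-Think trial table
#'
#' Builds the TNT-phase trial table for every subject in the design: each
#' session contains `reps_per_session` repetition blocks, each presenting all
#' Think and No-Think cues (8 per valence by default) in randomized order,
#' with strictly increasing onsets separated by the cue duration plus a
#' jittered ITI. Baseline items are withheld from this phase by construction
#' (they appear only in the final-test tables produced by
#' [generateBehavior()]). With the default design this yields 160 Think and
#' 160 No-Think trials per subject (32 trials x 5 sessions per condition).
#'
#' The table is a pure function of the specification: the same `spec`
#' (including its seed) reproduces the identical table.
#'
#' @param spec a [DesignSpec-class].
#' @return data.frame with columns subject, session, rep (within-session
#'   repetition), block (global repetition index), trial (within-block
#'   position), condition ("Think"/"NoThink"), valence ("negative"/"neutral"),
#'   item (stable item identifier) and onset_s.
#' @export
generateDesign <- function(spec) {
  stopifnot(is(spec, "DesignSpec"))
  validObject(spec)
  k <- spec@cues_per_condition_per_valence
  items <- expand.grid(condition = c("Think", "NoThink"),
                       valence = c("negative", "neutral"),
                       idx = seq_len(k), stringsAsFactors = FALSE)
  items$item <- sprintf("%s_%s_%02d", tolower(items$condition),
                        substr(items$valence, 1, 3), items$idx)
  per_block <- nrow(items)  # 32 in the default design

  one_subject <- function(s) {
    rows <- vector("list", spec@n_sessions * spec@reps_per_session)
    bi <- 0L
    withSeed(deriveSeed(spec@seed, "design", s), {
      for (sess in seq_len(spec@n_sessions)) {
        t_now <- 0
        for (rep_i in seq_len(spec@reps_per_session)) {
          bi <- bi + 1L
          ord <- sample.int(per_block)
          iti <- runif(per_block, spec@iti_range_s[1], spec@iti_range_s[2])
          onset <- t_now + cumsum(c(0, head(spec@cue_duration_s + iti, -1)))
          t_now <- onset[per_block] + spec@cue_duration_s + iti[per_block]
          rows[[bi]] <- data.frame(
            subject = s, session = sess, rep = rep_i, block = bi,
            trial = seq_len(per_block),
            condition = items$condition[ord], valence = items$valence[ord],
            item = items$item[ord], onset_s = onset,
            stringsAsFactors = FALSE)
        }
      }
    })
    do.call(rbind, rows)
  }
  out <- do.call(rbind, lapply(seq_len(spec@n_subjects), one_subject))
  rownames(out) <- NULL
  out
}

#' Item inventory implied by a design
#'
#' Enumerates the critical face-scene pairs: Think, No-Think and Baseline
#' items per valence. With the default design this is 3 x 2 x 8 = 48 pairs.
#'
#' @param spec a [DesignSpec-class].
#' @return data.frame with columns condition, valence, item.
#' @export
designItems <- function(spec) {
  stopifnot(is(spec, "DesignSpec"))
  k <- spec@cues_per_condition_per_valence
  kb <- spec@baseline_pairs_per_valence
  g <- rbind(
    expand.grid(condition = c("Think", "NoThink"), valence = c("negative", "neutral"),
                idx = seq_len(k), stringsAsFactors = FALSE),
    expand.grid(condition = "Baseline", valence = c("negative", "neutral"),
                idx = seq_len(kb), stringsAsFactors = FALSE))
  g$item <- sprintf("%s_%s_%02d", tolower(g$condition), substr(g$valence, 1, 3), g$idx)
  g[order(g$condition, g$valence, g$idx), c("condition", "valence", "item")]
}
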