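# Internal helpers: seed substreams and local RNG scoping.

# All randomness in the package flows from one user-supplied seed. Substreams
# for (stage, unit) pairs are derived with a multiplicative hash so that stages
# are independently reproducible; kept below 2^31 - 1.
deriveSeed <- function(seed, stage, unit = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stage_codes <- c(design = 11L, behavior = 23L, brain = 37L, dcm = 47L,
                   boot = 59L, perm = 61L, split = 71L, mcd = 83L, bms = 97L)
  code <- if (is.character(stage)) {
    if (!stage %in% names(stage_codes)) stop("unknown stage: ", stage)
    stage_codes[[stage]]
  } else as.integer(stage)
  ((as.double(seed) * 1103515245 + code * 12345 + as.double(unit) * 2654435761) %%
      2147483629) + 1
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Truncated normal by rejection; bounds are wide relative to sd in all uses.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
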