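# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so library calls never perturb a user's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# One user-facing seed fans out to fixed per-stage streams so that stages
# (split, init, shuffle, dropout, simulation) can be re-run independently
# and still be jointly reproducible. Offsets are arbitrary fixed constants;
# results stay below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  offsets <- c(split = 101L, init = 202L, shuffle = 303L, dropout = 404L,
               simulate = 505L, batch = 606L, finetune = 707L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]",
         call. = FALSE)
  invisible(x)
}
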