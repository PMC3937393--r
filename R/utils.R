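#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of (parameters, seed).
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage, per-unit seed from a global seed
#'
#' A declared counter scheme: the derived seed depends only on the global
#' seed, a stage name and a unit index, so adding subjects to a cohort never
#' perturbs the data of existing subjects.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character), e.g. `"trials"`, `"behavior"`, `"bold"`.
#' @param unit Non-negative integer unit index (e.g. subject number), default 0.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' deriveSeed(1, "bold", 3)
deriveSeed <- function(seed, stage, unit = 0L) {
  stages <- c(trials = 1, behavior = 2, bold = 3, cohort = 4,
              mc = 5, group = 6, gci = 7, pipeline = 8)
  code <- stages[[match.arg(stage, names(stages))]]
  base <- as.double(as.integer(seed)) %% 2147483647
  # modular linear mix; all intermediates stay below 2^53
  s <- (base * 48271) %% 2147483647
  s <- (s + code * 2246822519) %% 2147483647
  s <- (s + as.double(unit) * 2654435761) %% 2147483647
  as.integer(s %% 2147483646)
}

# stop() with a consistent prefix for user-input errors
.fail <- function(...) stop(sprintf(...), call. = FALSE)
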