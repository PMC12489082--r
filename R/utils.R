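# Shared internal helpers: error signalling, seeded evaluation, logging.

#' @keywords internal
mwi_stop <- function(msg, class = "mwi_error", ...) {
  stop(structure(
    class = c(class, "mwi_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded stages do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' All stage-level randomness flows from one root seed; each stage draws its
#' own substream so reordering stages never changes another stage's stream.
#'
#' @param root integer root seed.
#' @param name character substream name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(root, name) {
  stopifnot(is_number(root), is.character(name), length(name) == 1L)
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u) * 104729)
  as.integer((abs(root) * 7919 + h) %% 2147483647)
}

# Structured stage logging to stderr; silenced unless option is set.
mwi_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("mwibelt.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Timer wrapper used by the pipeline driver.
mwi_stage <- function(stage, code) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(code), error = function(e) {
    mwi_stop("stage '%s' failed: %s", "mwi_stage_error", stage, conditionMessage(e))
  })
  mwi_log(stage, "done in %.2fs", proc.time()[["elapsed"]] - t0)
  out
}
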