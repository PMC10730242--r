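# Internal helpers shared across the pipeline.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator/model calls do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Stop with a consistent error class so callers/tests can target failures.
abort_endo <- function(msg, class = "endotyper_error") {
  rlang::abort(msg, class = class)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_endo(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort_endo(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

# Derive a stream-specific 32-bit sub-seed from a master seed so that
# independent stages never share an RNG stream.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(cohort = 11L, survival = 29L, null = 47L, encoder = 71L,
               stack = 101L, shap = 131L, boot = 163L, misc = 197L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 2654435.0 + off * 97.0) %% 2147483647)
}
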