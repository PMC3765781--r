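# Internal helpers: structured validation errors, seed derivation, RNG scoping.

#' @importFrom stats median p.adjust rbinom rhyper rlnorm rmultinom rnbinom
#'   rnorm rpois runif var fisher.test dbinom
#' @importFrom utils read.delim write.table
NULL

# Validation failures get their own condition class so callers (and the CLI,
# which maps them to exit code 2) can distinguish bad input from runtime bugs.
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("compexr_validation_error", "error"),
                      call = call))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort_validation(msg, call = sys.call(-1))
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

# Stable 31-bit hash of string labels, folded with the master seed.  Gives
# every simulated sample its own reproducible stream, so adding a sample to
# an experiment never perturbs the counts of existing samples.
derive_seed <- function(master, ...) {
  label <- paste(c(...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

# Run `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
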