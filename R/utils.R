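# Internal helpers shared across modules.

#' Derive a reproducible child seed from a base seed and a salt
#'
#' Linear-congruential mixing keeps derived seeds inside the 32-bit integer
#' range so that a single top-level seed can deterministically drive every
#' randomised stage (simulation, baseline frame selection, replicates).
#'
#' @param seed Integer base seed.
#' @param salt Integer salt distinguishing the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483629) * 48271 + 11 + (as.numeric(salt) %% 2147483629) * 7919
  as.integer(s %% 2147483629)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
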