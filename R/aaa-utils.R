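#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package randomness never perturbs the
# user's session stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-subject seed derived from a cohort seed and a subject
# index, so cohorts are extensible without perturbing existing subjects.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 9973
  as.integer(s %% m) + 1L
}

stop_invalid <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("eegdan_invalid_argument", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

stop_degenerate <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("eegdan_degenerate_input", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid("`", name, "` must be positive")
  if (nonneg && x < 0) stop_invalid("`", name, "` must be nonnegative")
  invisible(x)
}

CHANNEL_NAMES <- c("Fp1", "Fpz", "Fp2")
CLASS_LEVELS <- c("healthy", "depressed")
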