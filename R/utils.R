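# Internal helpers shared across modules.

mdfa_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mdfa_error"), call = call))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number stream set from `seed`, then
#' restores the previous stream so seeded helpers do not perturb the caller's
#' randomness.  With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    mdfa_stop("'seed' must be a single finite integer or NULL", "mdfa_validation_error")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed stream from a master seed; keeps values
# within 32-bit integer range.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + as.integer(salt)) %% 100000L * 10000L + seq_len(n)
}

check_finite_values <- function(values, what = "values") {
  if (length(values) < 1L) {
    mdfa_stop(sprintf("'%s' must have length >= 1", what), "mdfa_validation_error")
  }
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    mdfa_stop(sprintf("'%s' must be finite numeric values", what),
              "mdfa_validation_error")
  }
  invisible(TRUE)
}

# FNV-1a 32-bit hash of a character scalar, for config fingerprints in logs.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
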