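# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package route through this
# so that identical (config, seed) pairs give identical outputs.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stream-specific child seed from a master seed. Offsets keep the
# generator stages (expression, networks, survival, drugs, ...) on
# non-overlapping deterministic streams.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_input(sprintf("'%s' must be numeric in [0, 1]", name))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(x == floor(x)) &&
    all(x >= if (positive) 1 else 0)
  if (!ok) {
    stop_input(sprintf("'%s' must be %s integer(s)", name,
                       if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
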