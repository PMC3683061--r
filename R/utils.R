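# Internal helpers shared across modules.

# Classed errors so callers (and tests) can match failure modes precisely.
pm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("pmfuse_error_", class),
                                     "pmfuse_error", "error"),
                      call = call))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a master seed by a fixed offset, kept inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + as.numeric(offset)) %% 2147483629L)
}

is_finite_matrix <- function(x) is.numeric(x) && all(is.finite(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
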