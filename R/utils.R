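# Internal helpers shared across modules.

# Evaluate `expr` with a local RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# thread seeds through this; none touch global RNG state permanently.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive k child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# 2D cross product of row-wise vectors.
cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
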