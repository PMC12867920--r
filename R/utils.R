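# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# Shift matrix rows forward in time by s (zeros enter at the top).
shift_rows <- function(x, s) {
  n <- nrow(x)
  if (s == 0L) return(x)
  out <- matrix(0, n, ncol(x))
  if (s < n) out[(s + 1L):n, ] <- x[1:(n - s), , drop = FALSE]
  out
}

# Adjoint of shift_rows: rows move back by s (zeros enter at the bottom).
unshift_rows <- function(x, s) {
  n <- nrow(x)
  if (s == 0L) return(x)
  out <- matrix(0, n, ncol(x))
  if (s < n) out[1:(n - s), ] <- x[(s + 1L):n, , drop = FALSE]
  out
}

# Largest-remainder apportionment of n into proportions p (sums exactly to n).
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
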