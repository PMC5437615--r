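# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All package errors carry a subclass of `"obg_error"` so callers (and the
#' CLI) can react programmatically.
#' @noRd
obg_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "obg_error", "error", "condition")))
}

#' Run an expression with a temporary RNG seed, restoring global RNG state.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Format an offset as a plain (non-scientific) integer string.
fmt_int <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

# TRUE iff `sub` occurs as an (ordered, not necessarily contiguous)
# subsequence of `vec`.
is_subsequence <- function(sub, vec) {
  if (length(sub) == 0L) return(TRUE)
  j <- 1L
  for (v in vec) {
    if (v == sub[j]) {
      j <- j + 1L
      if (j > length(sub)) return(TRUE)
    }
  }
  FALSE
}

# TRUE iff `sub` occurs as a contiguous sublist of `vec`.
is_contiguous_sublist <- function(sub, vec) {
  k <- length(sub)
  n <- length(vec)
  if (k == 0L) return(TRUE)
  if (k > n) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (all(vec[i:(i + k - 1L)] == sub)) return(TRUE)
  }
  FALSE
}

# Index pairs (i, j) of one longest common subsequence of two character
# vectors, computed by standard dynamic programming. Used to anchor the
# local-distance segment decomposition.
lcs_pairs <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 0L || m == 0L) return(matrix(integer(0), ncol = 2))
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L else max(L[i + 1L, j], L[i, j + 1L])
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j]) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (L[i + 1L, j] >= L[i, j + 1L]) {
      j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  pairs
}
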