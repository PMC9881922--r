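# Internal helpers shared across modules.

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# 0-based half-open intervals as a two-column matrix or data.frame with
# columns start, end.  IRanges is 1-based closed; these adapters keep the
# conversion in one place.
to_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

from_iranges <- function(ir) {
  if (length(ir) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

interval_len <- function(df) sum(df$end - df$start)

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

geometric_mean <- function(x) exp(mean(log(x)))

stop_bad_arg <- function(msg) abort(msg, class = "lobulex_error")
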