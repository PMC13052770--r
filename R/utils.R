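# Internal helpers shared across modules.

#' @importFrom stats median rnorm runif setNames quantile
#' @importFrom utils head tail
NULL

# let data.table's [ dispatch see this package as data.table-aware
.datatable.aware <- TRUE

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Indices of strict-or-plateau local maxima of a numeric vector.
# A run of equal values counts once, at its first index; endpoints excluded.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Topographic prominence of the peak at index `i`: height above the higher of
# the two minima separating it from the nearest taller point (or trace end).
peak_prominence_at <- function(v, i) {
  left <- v[seq_len(i - 1L)]
  right <- v[seq.int(i + 1L, length(v))]
  lb <- which(left > v[i])
  left_min <- if (length(lb)) min(left[seq.int(max(lb), length(left))]) else min(left)
  rb <- which(right > v[i])
  right_min <- if (length(rb)) min(right[seq_len(min(rb))]) else min(right)
  v[i] - max(left_min, right_min)
}

# Centered moving average; window is forced odd, edges use shrunken windows.
moving_average <- function(v, window) {
  window <- as.integer(window)
  if (window <= 1L) return(v)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

# format doubles so fread() round-trips them bit-exactly
fmt_full <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
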