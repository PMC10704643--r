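# Internal numeric helpers. All lattice computations run in natural-log
# domain; these primitives keep -Inf (zero probability) well behaved.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Elementwise log(exp(a) + exp(b)) for equal-shaped arrays.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(-abs(a - b)))
  bad <- !is.finite(m)
  r[bad] <- m[bad]
  r
}

# Row-wise logsumexp of a matrix; rows that are entirely -Inf map to -Inf.
# Column loop instead of apply(): these matrices are tall and narrow and sit
# inside per-sample DP loops.
row_logsumexp <- function(m) {
  nc <- ncol(m)
  mx <- m[, 1L]
  if (nc > 1L) for (j in 2:nc) mx <- pmax(mx, m[, j])
  ok <- is.finite(mx)
  out <- mx
  if (any(ok)) {
    s <- exp(m[ok, 1L] - mx[ok])
    if (nc > 1L) for (j in 2:nc) s <- s + exp(m[ok, j] - mx[ok])
    out[ok] <- mx[ok] + log(s)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
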