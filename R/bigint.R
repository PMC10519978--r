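# Exact non-negative big-integer arithmetic on little-endian limb vectors,
# base 2^24, limbs stored as doubles. Every intermediate stays below 2^53,
# so all operations are exact in IEEE double arithmetic. Only the handful of
# operations the combinadic codec needs are provided; no floating-point
# logarithms anywhere on the ranking path.

BI_BASE <- 2^24

bi_norm <- function(x) {
  n <- length(x)
  while (n > 1L && x[n] == 0) n <- n - 1L
  x[seq_len(n)]
}

bi_from_num <- function(n) {
  stopifnot(n >= 0, n < 2^53, n == floor(n))
  if (n == 0) return(0)
  limbs <- numeric(0)
  while (n > 0) {
    limbs <- c(limbs, n %% BI_BASE)
    n <- n %/% BI_BASE
  }
  limbs
}

bi_is_zero <- function(a) length(a) == 1L && a[1L] == 0

# -1, 0, 1 as a <, ==, > b
bi_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  x <- c(a, numeric(n - length(a)))
  y <- c(b, numeric(n - length(b)))
  s <- x + y
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= BI_BASE) 1 else 0
    if (carry) s[i] <- s[i] - BI_BASE
  }
  if (carry) s <- c(s, 1)
  s
}

# requires a >= b
bi_sub <- function(a, b) {
  stopifnot(bi_cmp(a, b) >= 0L)
  n <- length(a)
  x <- a
  y <- c(b, numeric(n - length(b)))
  borrow <- 0
  for (i in seq_len(n)) {
    d <- x[i] - y[i] - borrow
    borrow <- if (d < 0) 1 else 0
    if (borrow) d <- d + BI_BASE
    x[i] <- d
  }
  stopifnot(borrow == 0)
  bi_norm(x)
}

# multiply by a small non-negative integer (< 2^24) and add a small term
bi_mul_small <- function(a, s, add = 0) {
  stopifnot(s >= 0, s < BI_BASE, add >= 0, add < BI_BASE)
  p <- a * s
  carry <- add
  for (i in seq_along(p)) {
    v <- p[i] + carry
    carry <- v %/% BI_BASE
    p[i] <- v %% BI_BASE
  }
  while (carry > 0) {
    p <- c(p, carry %% BI_BASE)
    carry <- carry %/% BI_BASE
  }
  bi_norm(p)
}

# integer division by a small positive integer (< 2^24); returns q and r
bi_divmod_small <- function(a, d) {
  stopifnot(d >= 1, d < BI_BASE)
  q <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * BI_BASE + a[i]
    q[i] <- cur %/% d
    rem <- cur %% d
  }
  list(q = bi_norm(q), r = rem)
}

# number of bits in the binary representation (0 -> 0)
bi_bitlen <- function(a) {
  if (bi_is_zero(a)) return(0L)
  top <- a[length(a)]
  nb <- 0L
  while (top > 0) {
    top <- top %/% 2
    nb <- nb + 1L
  }
  (length(a) - 1L) * 24L + nb
}

# bits: integer vector of 0/1, most-significant first
bi_from_bits <- function(bits) {
  a <- 0
  for (b in bits) a <- bi_mul_small(a, 2, b)
  a
}

# fixed-width bit vector, most-significant first
bi_to_bits <- function(a, nbits) {
  stopifnot(bi_bitlen(a) <= nbits)
  bits <- integer(nbits)
  idx <- nbits
  for (limb in a) {
    v <- limb
    for (j in 1:24) {
      if (idx < 1L) break
      bits[idx] <- v %% 2
      v <- v %/% 2
      idx <- idx - 1L
    }
  }
  bits
}

# approximate double value (exact below 2^53); used for display/reporting only
bi_to_num <- function(a) sum(a * BI_BASE^(seq_along(a) - 1))

bi_to_decimal <- function(a) {
  if (bi_is_zero(a)) return("0")
  out <- character(0)
  while (!bi_is_zero(a)) {
    dm <- bi_divmod_small(a, 1e7)
    a <- dm$q
    out <- c(out, if (bi_is_zero(a)) as.character(dm$r)
             else sprintf("%07d", dm$r))
  }
  paste(rev(out), collapse = "")
}

# --- Pascal-triangle binomial cache (exact, addition-only) -------------------

.binom_cache <- new.env(parent = emptyenv())

# list of rows 0..m; row n is a list of big integers C(n, 0..n)
binom_rows <- function(m) {
  have <- get0("rows", envir = .binom_cache, ifnotfound = list())
  if (length(have) >= m + 1L) return(have)
  if (length(have) == 0L) have <- list(list(1))
  for (n in seq.int(length(have), m)) {
    prev <- have[[n]]
    row <- vector("list", n + 1L)
    row[[1L]] <- 1
    row[[n + 1L]] <- 1
    if (n >= 2L) {
      for (j in 2:n) row[[j]] <- bi_add(prev[[j - 1L]], prev[[j]])
    }
    have[[n + 1L]] <- row
  }
  assign("rows", have, envir = .binom_cache)
  have
}

binom_bi <- function(n, k) {
  if (k < 0 || k > n) return(0)
  binom_rows(n)[[n + 1L]][[k + 1L]]
}
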