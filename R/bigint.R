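# Arbitrary-precision nonnegative integers as little-endian limb vectors in
# base 1e6. Chosen so that limb products (<= 1e12) and their accumulated
# convolution sums stay far below 2^53, keeping every intermediate exact in
# doubles. Internal only; the user-facing surface is the counting functions.

.BIG_BASE <- 1e6

big_from_num <- function(x) {
  stopifnot(length(x) == 1L, x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% .BIG_BASE)
    x <- (x - x %% .BIG_BASE) / .BIG_BASE
  }
  limbs
}

# propagate carries until every limb < base; borrow-free input assumed
big_norm <- function(x) {
  repeat {
    carry <- floor(x / .BIG_BASE)
    if (all(carry == 0)) break
    x <- x - carry * .BIG_BASE
    x <- c(x, 0)
    idx <- seq_along(carry) + 1L
    x[idx] <- x[idx] + carry
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# a - b, requires a >= b
big_sub <- function(a, b) {
  n <- max(length(a), length(b))
  x <- c(a, numeric(n - length(a))) - c(b, numeric(n - length(b)))
  i <- 1L
  while (i <= length(x)) {
    if (x[i] < 0) {
      borrow <- ceiling(-x[i] / .BIG_BASE)
      x[i] <- x[i] + borrow * .BIG_BASE
      if (i == length(x)) stop("big_sub: negative result", call. = FALSE)
      x[i + 1L] <- x[i + 1L] - borrow
    }
    i <- i + 1L
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

# multiply by a small nonnegative double k with k < 2^53 / base
big_mul_small <- function(a, k) {
  stopifnot(k >= 0, k == floor(k), k < 2^53 / .BIG_BASE)
  if (k == 0) return(0)
  big_norm(a * k)
}

big_mul <- function(a, b) {
  if (identical(a, 0) || identical(b, 0)) return(0)
  res <- numeric(length(a) + length(b))
  # schoolbook with per-row normalization: each row sum stays exact because
  # limb products <= (1e6-1)^2 and rows are normalized before accumulation
  for (j in seq_along(b)) {
    if (b[j] == 0) next
    row <- big_mul_small(a, b[j])
    idx <- seq_along(row) + j - 1L
    if (max(idx) > length(res)) res <- c(res, numeric(max(idx) - length(res)))
    res[idx] <- res[idx] + row
    res <- big_norm(res)
  }
  big_norm(res)
}

big_pow <- function(a, n) {
  stopifnot(n >= 0, n == floor(n))
  res <- 1
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) res <- big_mul(res, base)
    n <- n %/% 2
    if (n > 0) base <- big_mul(base, base)
  }
  res
}

big_is_zero <- function(a) length(a) == 1L && a[1] == 0

# -1 / 0 / +1 comparison
big_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

# natural log of a big integer, accurate to double precision
big_log <- function(a) {
  if (big_is_zero(a)) stop("log of zero", call. = FALSE)
  n <- length(a)
  top <- a[n]
  if (n >= 2) top <- top + a[n - 1L] / .BIG_BASE
  if (n >= 3) top <- top + a[n - 2L] / .BIG_BASE^2
  log(top) + (n - 1) * log(.BIG_BASE)
}

big_to_decimal <- function(a) {
  digits <- sprintf("%06.0f", rev(a))
  out <- sub("^0+", "", paste(digits, collapse = ""))
  if (out == "") "0" else out
}

big_from_decimal <- function(s) {
  stopifnot(grepl("^[0-9]+$", s))
  n <- nchar(s)
  ends <- seq(n, 1, by = -6L)  # right-to-left 6-digit chunks, little-endian
  limbs <- vapply(ends, function(i) {
    as.numeric(substr(s, max(1L, i - 5L), i))
  }, numeric(1))
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) limbs <- limbs[-length(limbs)]
  limbs
}

big_to_num <- function(a) sum(a * .BIG_BASE^(seq_along(a) - 1))

# exact binomial coefficient as big integer (multiplicative formula, exact
# division at each step since C(n, 0..k) are integers)
big_choose <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(0)
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) {
    res <- big_mul_small(res, n - i + 1)
    res <- big_div_small(res, i)
  }
  res
}

# exact division by small integer; remainder must be zero
big_div_small <- function(a, k) {
  stopifnot(k >= 1, k == floor(k), k < 2^53 / .BIG_BASE)
  rem <- 0
  out <- numeric(length(a))
  for (i in rev(seq_along(a))) {
    cur <- rem * .BIG_BASE + a[i]
    out[i] <- floor(cur / k)
    rem <- cur - out[i] * k
  }
  if (rem != 0) stop("big_div_small: inexact division", call. = FALSE)
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_factorial <- function(n) {
  res <- 1
  if (n >= 2) for (i in 2:n) res <- big_mul_small(res, i)
  res
}
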