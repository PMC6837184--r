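#' Exact counts of token strings with a fixed unique alphabet
#'
#' `count_subalphabet(t, a, a_prime)` counts the length-`t` strings over a
#' designated `a`-letter alphabet that use *exactly* `a_prime` distinct
#' letters. `count_exact(t, a)` is the diagonal case `a_prime = a`: the number
#' of strings in which every one of the `a` letters appears at least once (a
#' surjection-type count). The natural log of this count is the
#' Hartley-Shannon information content of a component of length `t` with
#' unique alphabet `a`, see [het_information()].
#'
#' Counts are computed by the recursion
#' \deqn{N(t, a; a) = a^t - \sum_{i=1}^{a-1} \binom{a}{i} N(t, i; i)}
#' with \eqn{N(t, 1; 1) = 1}, in exact arbitrary-precision integer
#' arithmetic: double-precision floats fail beyond roughly `t, a` of 30, and
#' the partition identity \eqn{\sum_{a'} \binom{a}{a'} N(t, a'; a') = a^t}
#' must hold exactly.
#'
#' @param t Component length in tokens (integer, >= 1).
#' @param a Size of the designated alphabet (integer, >= 1).
#' @param a_prime Number of distinct letters actually used (1 <= a_prime <= a).
#' @return An exact integer of class `cohsi_bigint`. Coerce with
#'   `as.character()` (always exact) or `as.numeric()` (exact below 2^53).
#' @examples
#' count_subalphabet(5, 2, 2)  # 30
#' count_exact(5, 5)           # 120 = 5!
#' @seealso [count_closed_form()] for the independent inclusion-exclusion
#'   oracle, [enumerate_strings()] for brute-force enumeration.
#' @export
count_subalphabet <- function(t, a, a_prime) {
  check_count_args(t, a)
  if (a_prime < 1 || a_prime > a || a_prime != floor(a_prime)) {
    stop("`a_prime` must be an integer in [1, a]", call. = FALSE)
  }
  new_bigint(count_sub_limbs(t, a, a_prime))
}

#' @rdname count_subalphabet
#' @export
count_exact <- function(t, a) {
  check_count_args(t, a)
  new_bigint(count_exact_limbs(t, a))
}

#' Inclusion-exclusion surjection count
#'
#' Independent closed-form evaluation of [count_exact()]:
#' \eqn{N(t, a) = \sum_{k=0}^{a-1} (-1)^k \binom{a}{k} (a-k)^t}. Implemented
#' without the recursion (positive and negative parts accumulated separately
#' in exact integers, then subtracted) so that the two routes cross-validate
#' one another permanently.
#'
#' @inheritParams count_subalphabet
#' @return An exact integer of class `cohsi_bigint`.
#' @export
count_closed_form <- function(t, a) {
  check_count_args(t, a)
  pos <- 0
  neg <- 0
  for (k in 0:(a - 1)) {
    term <- big_mul(big_choose(a, k), big_pow(big_from_num(a - k), t))
    if (k %% 2 == 0) pos <- big_add(pos, term) else neg <- big_add(neg, term)
  }
  if (big_cmp(pos, neg) < 0) {
    # t < a: the signed sum is zero (no surjections); guard exact zero
    return(new_bigint(0))
  }
  new_bigint(big_sub(pos, neg))
}

#' Enumerate all strings with an exact alphabet usage
#'
#' Brute-force generation of every length-`t` string over `alphabet` that
#' uses exactly `exact_usage` distinct tokens, lexicographically sorted
#' (C locale). Guarded to desk scale; its cardinality equals
#' [count_subalphabet()] and serves as the ground-truth oracle in tests.
#'
#' @param t String length (<= 12).
#' @param alphabet Character vector of single-character tokens.
#' @param exact_usage Required number of distinct tokens.
#' @return Sorted character vector.
#' @export
enumerate_strings <- function(t, alphabet, exact_usage) {
  alphabet <- as.character(alphabet)
  a <- length(alphabet)
  stopifnot(t >= 1, a >= 1, exact_usage >= 1)
  if (t > 12 || a^t > 1e7) {
    stop("enumeration guard exceeded: need t <= 12 and |alphabet|^t <= 1e7",
         call. = FALSE)
  }
  strings <- ""
  for (i in seq_len(t)) strings <- paste0(rep(strings, each = a), alphabet)
  nuniq <- vapply(strsplit(strings, "", fixed = TRUE),
                  function(ch) length(unique(ch)), integer(1))
  sort(strings[nuniq == exact_usage], method = "radix")
}

#' Hartley-Shannon information content of a component
#'
#' `het_information(t, a)` is the natural log of [count_exact()]: the
#' information content in nats of a component of `t` tokens whose unique
#' alphabet of `a` tokens must each appear at least once. The log is taken
#' directly on the exact big integer, so it never overflows double range.
#'
#' `het_information_asymptotic(t, a)` is the unconstrained form
#' \eqn{t \log a}, valid when `t >> a`; it always exceeds the exact value
#' (it admits strings that miss letters), with equality only at `a = 1`.
#' The deficit between the two is what bends the predicted length
#' distribution away from a pure power law at short lengths.
#'
#' @inheritParams count_subalphabet
#' @return Information content in nats (double).
#' @examples
#' het_information(5, 2)             # log 30
#' het_information_asymptotic(5, 2)  # log 32
#' @export
het_information <- function(t, a) {
  check_count_args(t, a)
  if (a > t) stop("`a` must not exceed `t`: a component cannot be shorter than its unique alphabet", call. = FALSE)
  big_log(count_exact_limbs(t, a))
}

#' @rdname het_information
#' @export
het_information_asymptotic <- function(t, a) {
  check_count_args(t, a)
  t * log(a)
}

#' System-level totals for a heterogeneous component table
#'
#' Aggregates a component table (one row per component, columns `length_t`
#' and `alphabet_a`) into the system-level quantities of the statistical
#' mechanics treatment: total tokens `total_tokens_T`, component count
#' `n_components_M`, total Hartley-Shannon information `total_info_I`
#' (sum of per-component [het_information()], additive over subsystems),
#' and `log_omega`, the log multinomial count \eqn{\log(T! / \prod_i t_i!)}
#' of ways of arranging the tokens among the components.
#'
#' @param components Data frame with integer columns `length_t`, `alphabet_a`.
#' @return One-row tibble with columns `total_tokens_T`, `n_components_M`,
#'   `total_info_I`, `log_omega`.
#' @export
system_info <- function(components) {
  stopifnot(is.data.frame(components))
  if (nrow(components) == 0) stop("`components` must be nonempty", call. = FALSE)
  stopifnot(all(c("length_t", "alphabet_a") %in% names(components)))
  t_i <- components$length_t
  a_i <- components$alphabet_a
  stopifnot(all(t_i >= 1), all(a_i >= 1), all(a_i <= t_i))
  info <- purrr::map2_dbl(t_i, a_i, het_information)
  T_tot <- sum(t_i)
  tibble::tibble(
    total_tokens_T = T_tot,
    n_components_M = nrow(components),
    total_info_I = sum(info),
    log_omega = lfactorial(T_tot) - sum(lfactorial(t_i))
  )
}

#' Tabulate exact counts over a grid
#'
#' Builds the full table of exact counts N(t, a; a') for `t = 1..t_max`,
#' `a = 1..a_max`, `a' = 1..a`, with counts carried as exact decimal strings
#' (they overflow doubles quickly). Write with [readr::write_tsv()] and
#' re-read losslessly with `col_types = "iiic"`.
#'
#' @param t_max,a_max Grid bounds.
#' @return Tibble with columns `t`, `a`, `a_prime`, `count` (character).
#' @export
count_table <- function(t_max, a_max) {
  stopifnot(t_max >= 1, a_max >= 1)
  rows <- list()
  k <- 1L
  for (t in seq_len(t_max)) {
    for (a in seq_len(a_max)) {
      for (ap in seq_len(a)) {
        rows[[k]] <- c(t, a, ap)
        k <- k + 1L
      }
    }
  }
  m <- do.call(rbind, rows)
  tibble::tibble(
    t = as.integer(m[, 1]), a = as.integer(m[, 2]), a_prime = as.integer(m[, 3]),
    count = purrr::pmap_chr(list(m[, 1], m[, 2], m[, 3]),
                            function(t, a, ap) big_to_decimal(count_sub_limbs(t, a, ap)))
  )
}

## ---- internals -----------------------------------------------------------

check_count_args <- function(t, a) {
  if (length(t) != 1 || length(a) != 1 || is.na(t) || is.na(a) ||
      t < 1 || a < 1 || t != floor(t) || a != floor(a)) {
    stop("`t` and `a` must be positive integers", call. = FALSE)
  }
  invisible(TRUE)
}

# memoized diagonal N(t, a; a) via the recursion, as limb vectors
.count_cache <- new.env(parent = emptyenv())
.power_cache <- new.env(parent = emptyenv())

# a^t with incremental reuse of a^(t-1): grid builds walk t upwards, so the
# cache turns each power into one small multiply
big_power_cached <- function(a, t) {
  key <- paste0(a, "|", t)
  hit <- .power_cache[[key]]
  if (!is.null(hit)) return(hit)
  prev <- if (t >= 2) .power_cache[[paste0(a, "|", t - 1)]] else NULL
  val <- if (!is.null(prev)) big_mul_small(prev, a) else big_pow(big_from_num(a), t)
  .power_cache[[key]] <- val
  val
}

count_exact_limbs <- function(t, a) {
  if (a > t) return(0)
  key <- paste0(t, "|", a)
  hit <- .count_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (a == 1) {
    val <- 1
  } else {
    val <- big_power_cached(a, t)
    for (i in seq_len(a - 1)) {
      ch <- choose(a, i)
      term <- if (ch < 2^53 / .BIG_BASE) {
        big_mul_small(count_exact_limbs(t, i), ch)
      } else {
        big_mul(big_choose(a, i), count_exact_limbs(t, i))
      }
      val <- big_sub(val, term)
    }
  }
  .count_cache[[key]] <- val
  val
}

count_sub_limbs <- function(t, a, a_prime) {
  if (a_prime > t) return(0)
  if (a_prime == a) return(count_exact_limbs(t, a))
  big_mul(big_choose(a, a_prime), count_exact_limbs(t, a_prime))
}

## ---- cohsi_bigint class --------------------------------------------------

new_bigint <- function(limbs) {
  structure(list(limbs = limbs), class = "cohsi_bigint")
}

#' @export
format.cohsi_bigint <- function(x, ...) big_to_decimal(x$limbs)

#' @export
print.cohsi_bigint <- function(x, ...) {
  cat("<exact integer> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.cohsi_bigint <- function(x, ...) big_to_decimal(x$limbs)

#' @export
as.numeric.cohsi_bigint <- function(x, ...) big_to_num(x$limbs)

#' @export
log.cohsi_bigint <- function(x, base = exp(1)) big_log(x$limbs) / log(base)

#' @export
Ops.cohsi_bigint <- function(e1, e2) {
  to_limbs <- function(e) {
    if (inherits(e, "cohsi_bigint")) e$limbs else big_from_num(e)
  }
  a <- to_limbs(e1)
  b <- to_limbs(e2)
  cmp <- big_cmp(a, b)
  switch(.Generic,
    "==" = cmp == 0, "!=" = cmp != 0,
    "<" = cmp < 0, ">" = cmp > 0, "<=" = cmp <= 0, ">=" = cmp >= 0,
    "+" = new_bigint(big_add(a, b)),
    "-" = new_bigint(big_sub(a, b)),
    "*" = new_bigint(big_mul(a, b)),
    stop("unsupported operation for cohsi_bigint: ", .Generic, call. = FALSE)
  )
}
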