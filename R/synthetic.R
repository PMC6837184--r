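#' Uniform draw of a string with an exact unique alphabet
#'
#' Samples uniformly over the `N(t, a)` admissible strings (every one of the
#' `a` designated tokens appears at least once) by rejection from the `a^t`
#' unconstrained strings. Acceptance probability is `N(t, a) / a^t`, which
#' is ample at desk scales; termination is guaranteed for `t >= a`.
#'
#' @param t String length.
#' @param a Unique alphabet size (`a <= t`).
#' @param seed Optional integer seed (scoped locally).
#' @param alphabet Tokens to draw from (first `a` are used); default LETTERS.
#' @return A single string.
#' @export
sample_exact_alphabet_string <- function(t, a, seed = NULL, alphabet = LETTERS) {
  check_count_args(t, a)
  if (a > t) stop("`a` must not exceed `t`", call. = FALSE)
  if (a > length(alphabet)) stop("alphabet too small for `a`", call. = FALSE)
  tokens <- alphabet[seq_len(a)]
  run <- function() {
    repeat {
      draw <- sample(tokens, t, replace = TRUE)
      if (length(unique(draw)) == a) return(paste(draw, collapse = ""))
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Seeded discrete power-law sample
#'
#' I.i.d. draws from the zeta-normalized discrete power law
#' \eqn{p(x) \propto x^{-\alpha}}, `x >= xmin`, by inverse transform on the
#' exact ccdf. The null generator for calibrating the tail-fitting battery:
#' its empirical ccdf is log-log linear with slope `1 - exponent`.
#'
#' @param exponent Pdf exponent (> 1).
#' @param xmin Support minimum (integer >= 1).
#' @param n Sample size.
#' @param seed Optional integer seed (scoped locally).
#' @return Integer-valued numeric vector of length `n`.
#' @export
generate_powerlaw_lengths <- function(exponent, xmin, n, seed = NULL) {
  if (exponent <= 1) stop("`exponent` must exceed 1", call. = FALSE)
  stopifnot(n >= 1, xmin >= 1)
  if (is.null(seed)) {
    draw_discrete_powerlaw(n, exponent, xmin)
  } else {
    withr::with_seed(seed, draw_discrete_powerlaw(n, exponent, xmin))
  }
}

#' Synthetic note-event corpus with a known alphabet power law
#'
#' Generates compositions whose realized alphabets satisfy
#' \eqn{a'' \approx c \, (a')^{\gamma}} with optional multiplicative
#' log-normal noise, then realizes each composition as concrete note events:
#' `a_prime` distinct pitches with `a_doubleprime` distinct pitch-duration
#' pairs distributed as evenly as the 7 duration classes allow. Targets are
#' rounded and clipped to the feasible band `[a', min(7a', 616)]`; the
#' realized alphabets are verified post hoc, so [dual_alphabet_table()] plus
#' [loglog_ols()] recovers `gamma` (exactly, in the noise-free case, up to
#' integer rounding).
#'
#' @param gamma True power-law exponent between the two alphabets.
#' @param c_scale Prefactor `c`.
#' @param n_comps Number of compositions.
#' @param noise_sd Standard deviation of log-normal noise on `a''` (0 = none).
#' @param seed Optional integer seed.
#' @param a_prime_range Range of no-duration alphabet sizes (defaults 9..49,
#'   inside the feasible band for `gamma = 1.5`, `c = 1`).
#' @return Note-event tibble (`composition_id`, `pitch`, `duration_class`).
#' @export
generate_dual_alphabet_corpus <- function(gamma, c_scale = 1, n_comps = 41,
                                          noise_sd = 0, seed = NULL,
                                          a_prime_range = c(9, 49)) {
  stopifnot(n_comps >= 2, gamma > 0, c_scale > 0,
            a_prime_range[1] >= 1, a_prime_range[2] <= 88)
  build <- function() {
    a_prime <- round(seq(a_prime_range[1], a_prime_range[2], length.out = n_comps))
    target <- c_scale * a_prime^gamma
    if (noise_sd > 0) target <- target * exp(stats::rnorm(n_comps, 0, noise_sd))
    a_dp <- pmin(pmax(round(target), a_prime), 7 * a_prime, 616)
    if (any(a_dp < a_prime)) stop("infeasible alphabet targets after clipping", call. = FALSE)
    purrr::map_dfr(seq_len(n_comps), function(i) {
      ap <- a_prime[i]
      add <- a_dp[i]
      base <- add %/% ap
      extra <- add %% ap
      durs_per_pitch <- rep(base, ap) + c(rep(1, extra), rep(0, ap - extra))
      tibble::tibble(
        composition_id = sprintf("comp_%03d", i),
        pitch = rep(seq_len(ap), durs_per_pitch),
        duration_class = unlist(lapply(durs_per_pitch, function(k) .DURATION_CLASSES[seq_len(k)]))
      )
    })
  }
  ev <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  # post-hoc verification of the realized alphabets
  chk <- dual_alphabet_table(ev)
  stopifnot(all(chk$a_prime <= chk$a_doubleprime), all(chk$a_doubleprime <= 7 * chk$a_prime))
  ev
}

#' Exhaustive microstate census of a tiny heterogeneous system
#'
#' Enumerates every composition \eqn{(t_1, \dots, t_M)} with
#' \eqn{\sum t_i = T} and \eqn{t_i \ge a_i}, recording the exact multinomial
#' multiplicity \eqn{T! / \prod t_i!} (the number of microstates realizing
#' that macrostate) and the exact total information
#' \eqn{\sum_i \log N(t_i, a_i)}. The modal composition -- the one with the
#' most microstates -- is flagged: it is the distribution the variational
#' argument singles out as overwhelmingly likely. Guarded to `T <= 12`,
#' `M <= 3`, where exhaustive enumeration is exact and instant.
#'
#' @param T_total Total tokens.
#' @param M Number of components.
#' @param alphabets Integer vector of length `M`: the fixed unique alphabet
#'   of each component.
#' @return Tibble with columns `t_1..t_M`, `multiplicity`, `total_info`,
#'   `modal`.
#' @export
enumerate_microstates <- function(T_total, M, alphabets) {
  stopifnot(length(alphabets) == M, all(alphabets >= 1))
  if (T_total > 12 || M > 3) stop("enumeration guard: T <= 12 and M <= 3", call. = FALSE)
  if (sum(alphabets) > T_total) stop("alphabets cannot fit in T tokens", call. = FALSE)
  parts <- compositions_with_min(T_total, M, alphabets)
  mult <- vapply(parts, function(t) factorial(T_total) / prod(factorial(t)), numeric(1))
  info <- vapply(parts, function(t) {
    sum(purrr::map2_dbl(t, alphabets, het_information))
  }, numeric(1))
  m <- do.call(rbind, parts)
  colnames(m) <- paste0("t_", seq_len(M))
  out <- tibble::as_tibble(m)
  out$multiplicity <- mult
  out$total_info <- info
  out$modal <- mult == max(mult)
  out
}

# all (t_1..t_M) with sum T and t_i >= min_i
compositions_with_min <- function(T_total, M, mins) {
  if (M == 1) {
    if (T_total >= mins[1]) return(list(T_total)) else return(list())
  }
  out <- list()
  hi <- T_total - sum(mins[-1])
  if (hi < mins[1]) return(out)
  for (t1 in mins[1]:hi) {
    rest <- compositions_with_min(T_total - t1, M - 1, mins[-1])
    out <- c(out, lapply(rest, function(r) c(t1, r)))
  }
  out
}
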