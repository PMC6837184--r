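#' Complementary cumulative distribution function
#'
#' `ccdf()` tabulates \eqn{P(X \ge x)} at every distinct observed value.
#' The `>=` convention matches the discrete power-law KS machinery in
#' [fit_power_tail()]; plotted log-log, a power-law sample is straight with
#' slope one less (in magnitude) than the pdf exponent. The ccdf is the
#' standard noise-reducing view of a heavy length distribution.
#'
#' @param values Positive integer observations (e.g. component lengths).
#' @return Tibble of class `cohsi_ccdf` with columns `x` (sorted distinct
#'   values) and `p` (\eqn{P(X \ge x)}); `p` is nonincreasing, starts at 1
#'   and is everywhere positive.
#' @examples
#' ccdf(c(1, 2, 2, 5))
#' @export
ccdf <- function(values) {
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  if (any(values <= 0)) stop("`values` must be positive", call. = FALSE)
  tab <- table(values)
  x <- as.numeric(names(tab))
  n_ge <- rev(cumsum(rev(as.numeric(tab))))
  out <- tibble::tibble(x = x, p = n_ge / length(values))
  stopifnot(all(diff(out$p) <= 0), out$p[1] == 1, all(out$p > 0))
  class(out) <- c("cohsi_ccdf", class(out))
  out
}

#' Exponential (geometric) binning of a heavy tail
#'
#' Bins the values at or above `x_low` into bins with geometric edges
#' `x_low * ratio^k`, balancing bin contents under a power law; the
#' width-normalized density of such bins is log-log linear for power-law
#' data. The last bin is right-closed so the maximum is always covered.
#'
#' @param values Positive observations.
#' @param ratio Edge ratio (> 1).
#' @param x_low Left edge of the first bin (>= min of the binned tail).
#' @return Tibble with columns `bin`, `lower`, `upper`, `mid` (geometric
#'   midpoint), `count`, `density` (count / width).
#' @export
exponential_bin <- function(values, ratio, x_low = min(values)) {
  stopifnot(ratio > 1, length(values) > 0)
  tail_vals <- values[values >= x_low]
  if (length(tail_vals) == 0) stop("no values at or above `x_low`", call. = FALSE)
  n_edges <- ceiling(log(max(tail_vals) / x_low) / log(ratio))
  edges <- x_low * ratio^(0:max(n_edges, 1))
  idx <- findInterval(tail_vals, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  tibble::tibble(
    bin = seq_along(counts),
    lower = edges[-length(edges)],
    upper = edges[-1],
    mid = sqrt(edges[-length(edges)] * edges[-1]),
    count = counts,
    density = counts / diff(edges)
  )
}

#' Recategorize a heterogeneous component table as a homogeneous rank table
#'
#' The same data that yield a length distribution can be consistently
#' recategorized as a homogeneous system: each distinct length becomes a bin,
#' the bin count is the number of components of that length, and bins are
#' rank ordered by count. The homogeneous theory then predicts Zipf-like
#' rank behaviour with a drooping tail for this very same data. Ties in
#' frequency are broken by ascending length (deterministic).
#'
#' @param table Component table (needs a `length_t` column), e.g. from
#'   [read_fasta_components()].
#' @return Tibble with columns `rank`, `frequency`, `representative_value`;
#'   frequencies are nonincreasing and sum to `nrow(table)`.
#' @export
rank_recategorize <- function(table) {
  stopifnot(is.data.frame(table), "length_t" %in% names(table))
  if (nrow(table) == 0) stop("`table` must be nonempty", call. = FALSE)
  out <- table |>
    dplyr::count(.data$length_t, name = "frequency") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$length_t) |>
    dplyr::transmute(
      rank = dplyr::row_number(),
      frequency = .data$frequency,
      representative_value = .data$length_t
    )
  stopifnot(sum(out$frequency) == nrow(table), all(diff(out$frequency) <= 0))
  out
}

#' Pair the two alphabets of a note-event corpus
#'
#' For each composition, pairs the no-duration alphabet `a_prime` (distinct
#' pitches) with the duration alphabet `a_doubleprime` (distinct
#' pitch-duration pairs). If both categorizations of the same music obey the
#' asymptotic power law in length, the two alphabets must themselves be
#' related as a power law, so the log-log scatter of these pairs should be
#' linear; fit it with [loglog_ols()].
#'
#' @param notes Note-event table (`composition_id`, `pitch`,
#'   `duration_class`), see [read_note_events()].
#' @return Tibble with columns `composition_id`, `a_prime`, `a_doubleprime`;
#'   every row satisfies `a_prime <= a_doubleprime <= 7 * a_prime`.
#' @export
dual_alphabet_table <- function(notes) {
  no_dur <- components_from_notes(notes, with_duration = FALSE)
  with_dur <- components_from_notes(notes, with_duration = TRUE)
  if (nrow(no_dur) < 2) {
    stop("need at least 2 compositions to study the alphabet relation", call. = FALSE)
  }
  out <- dplyr::inner_join(
    dplyr::select(no_dur, "component_id", a_prime = "alphabet_a"),
    dplyr::select(with_dur, "component_id", a_doubleprime = "alphabet_a"),
    by = "component_id"
  ) |>
    dplyr::rename(composition_id = "component_id")
  stopifnot(all(out$a_prime <= out$a_doubleprime),
            all(out$a_doubleprime <= 7 * out$a_prime))
  out
}
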