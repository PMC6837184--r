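#' Lagrange parameters for the heterogeneous length equation
#'
#' The implicit heterogeneous equation links component length `t` and unique
#' alphabet `a` through \eqn{\log t = -\alpha - \beta \, dI/dt}, where
#' \eqn{I = \log N(t, a)} and \eqn{\alpha, \beta} are the Lagrange
#' multipliers constraining total size and total information. Taken exactly
#' as written, positive `alpha` with positive `beta` places every root at
#' `t < 1`, outside the physical domain `t >= a >= 1`; the `reflected`
#' convention negates both multipliers so that positive illustrative values
#' yield an admissible locus. `as_printed` applies the equation literally
#' (negative values are allowed and are the natural choice there).
#'
#' @param alpha Size multiplier.
#' @param beta Information multiplier (nonzero).
#' @param convention `"as_printed"` (literal) or `"reflected"` (negate both).
#' @return An object of class `cohsi_het_params`.
#' @export
het_params <- function(alpha, beta, convention = c("as_printed", "reflected")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1, length(beta) == 1)
  if (beta == 0) stop("`beta` must be nonzero", call. = FALSE)
  s <- if (convention == "reflected") -1 else 1
  structure(
    list(alpha = alpha, beta = beta, convention = convention,
         alpha_eff = s * alpha, beta_eff = s * beta),
    class = "cohsi_het_params"
  )
}

#' @export
print.cohsi_het_params <- function(x, ...) {
  cat("<cohsi_het_params> alpha = ", x$alpha, ", beta = ", x$beta,
      " (", x$convention, ")\n", sep = "")
  invisible(x)
}

#' Residual of the implicit heterogeneous equation
#'
#' \eqn{r(t, a) = \log t + \alpha + \beta \, dI/dt} evaluated on the
#' continued information grid; a root `r = 0` is a point of the predicted
#' length-alphabet locus.
#'
#' @param t Length (real, vectorized).
#' @param a Unique alphabet (integer scalar).
#' @param params A [het_params()] object.
#' @param grid A [build_info_grid()] object.
#' @return Residual in log-length units (double).
#' @export
het_residual <- function(t, a, params, grid) {
  stopifnot(inherits(params, "cohsi_het_params"))
  log(t) + params$alpha_eff + params$beta_eff * info_at(grid, t, a)$dlogN_dt
}

#' Solve the heterogeneous equation for its length-alphabet locus
#'
#' For each alphabet line `a` (mode `"t_of_a"`), the residual is scanned
#' along `t` on the grid, sign changes are bracketed and refined by bisection
#' to `|residual| < tol`. All roots on a line are reported; the smallest is
#' flagged `primary` (deterministic tie-break). Lines with no sign change
#' contribute no rows: absence of solutions at small `t` is a genuine feature
#' of the implicit equation, reported honestly (a warning is raised if the
#' whole locus is empty). Mode `"a_of_t"` instead interpolates the root in
#' `a` across integer alphabet lines for each integer `t`.
#'
#' @inheritParams het_residual
#' @param a_range Integer alphabets to scan (default the whole grid).
#' @param mode `"t_of_a"` (default) or `"a_of_t"`.
#' @param tol Residual tolerance (default 1e-6).
#' @return Tibble with columns `a`, `t`, `residual`, `primary`.
#' @export
solve_het_locus <- function(params, grid, a_range = NULL, mode = c("t_of_a", "a_of_t"),
                            tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cohsi_het_params"), inherits(grid, "cohsi_infogrid"))
  if (is.null(a_range)) a_range <- seq_len(grid$a_max)
  stopifnot(all(a_range >= 1), all(a_range <= grid$a_max))
  out <- if (mode == "t_of_a") {
    purrr::map_dfr(a_range, function(a) locus_line_t(a, params, grid, tol))
  } else {
    purrr::map_dfr(seq_len(grid$t_max), function(t) locus_line_a(t, a_range, params, grid))
  }
  if (nrow(out) == 0) {
    warning("no roots found on the scanned domain: empty locus", call. = FALSE)
  }
  out
}

locus_line_t <- function(a, params, grid, tol) {
  ts <- seq(a, grid$t_max)
  if (length(ts) < 2) return(tibble::tibble())
  r <- het_residual(ts, a, params, grid)
  flips <- which(r[-length(r)] * r[-1] <= 0 & is.finite(r[-length(r)]) & is.finite(r[-1]))
  roots <- purrr::map_dbl(flips, function(i) {
    lo <- ts[i]; hi <- ts[i + 1]
    flo <- r[i]
    if (flo == 0) return(lo)
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      fm <- het_residual(mid, a, params, grid)
      # refine past `tol` down to interval width 1e-10 so the root location
      # itself (not just the residual) is resolved
      if (fm == 0 || (hi - lo) < 1e-10) return(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    mid
  })
  roots <- unique(roots)
  if (length(roots) == 0) return(tibble::tibble())
  res <- het_residual(roots, a, params, grid)
  tibble::tibble(
    a = a, t = roots,
    residual = res,
    primary = roots == min(roots)
  )
}

locus_line_a <- function(t, a_range, params, grid) {
  as <- a_range[a_range <= t]
  if (length(as) < 2) return(tibble::tibble())
  r <- vapply(as, function(a) het_residual(t, a, params, grid), numeric(1))
  flips <- which(r[-length(r)] * r[-1] <= 0)
  if (length(flips) == 0) return(tibble::tibble())
  a_root <- vapply(flips, function(i) {
    # linear interpolation between integer alphabet lines
    as[i] + r[i] / (r[i] - r[i + 1]) * (as[i + 1] - as[i])
  }, numeric(1))
  tibble::tibble(a = a_root, t = as.numeric(t), residual = 0, primary = a_root == min(a_root))
}

#' Pure power-law asymptote of the heterogeneous locus
#'
#' In the regime `t >> a` the information derivative collapses to
#' \eqn{\log a} and the implicit equation becomes the explicit power law
#' \eqn{t(a) = \exp(-\alpha - \beta \log a)}, i.e. \eqn{t \sim a^{-\beta}}.
#' The full locus converges onto this asymptote from below as `t/a` grows.
#'
#' @inheritParams het_residual
#' @param a_range Alphabet values (may be real here).
#' @return Tibble with columns `a`, `t`.
#' @export
pure_power_locus <- function(params, a_range) {
  stopifnot(inherits(params, "cohsi_het_params"))
  tibble::tibble(a = a_range, t = exp(-params$alpha_eff - params$beta_eff * log(a_range)))
}

#' Departure of the full locus from its power-law asymptote
#'
#' Joins the full solution locus to the pure power law on their shared
#' alphabet range and reports the per-alphabet gap `t_full - t_pure` and its
#' relative size. Because `dI/dt >= log a`, the gap is one-signed (the full
#' solution never lies above the asymptote for positive effective `beta`)
#' and vanishes as `t/a` grows.
#'
#' @param full Locus tibble from [solve_het_locus()] (primary roots are used).
#' @param pure Tibble from [pure_power_locus()].
#' @return Tibble with columns `a`, `t_full`, `t_pure`, `gap`, `rel_gap`.
#' @export
departure_profile <- function(full, pure) {
  stopifnot(is.data.frame(full), is.data.frame(pure))
  f <- dplyr::filter(full, .data$primary)
  shared <- intersect(f$a, pure$a)
  if (length(shared) == 0) stop("loci share no alphabet values", call. = FALSE)
  dplyr::inner_join(
    dplyr::select(f, "a", t_full = "t"),
    dplyr::select(pure, "a", t_pure = "t"),
    by = "a"
  ) |>
    dplyr::mutate(gap = .data$t_full - .data$t_pure,
                  rel_gap = .data$gap / .data$t_pure)
}
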