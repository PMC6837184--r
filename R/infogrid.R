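#' Gridded Hartley-Shannon information and its length-derivative
#'
#' Builds the real-valued continuation of the exact information function
#' \eqn{I(t, a) = \log N(t, a)} needed by the implicit heterogeneous length
#' equation. `log N` is evaluated exactly (big-integer logs) at every integer
#' node with `a <= t`, and the derivative \eqn{dI/dt} is formed by
#' second-order finite differences on the unit-spaced grid: central in the
#' interior, one-sided second-order at the `t = a` boundary and at `t_max`.
#' Between nodes both fields are continued by monotone piecewise-cubic
#' (Fritsch-Carlson) interpolation, which coincides with the exact values at
#' the integer nodes.
#'
#' The derivative approaches its asymptote \eqn{\log a} from above as `t`
#' grows: the deficit \eqn{dI/dt - \log a} reflects the constraint that all
#' `a` letters must appear, and is the source of the unimodal peak in the
#' predicted length distribution.
#'
#' @param t_max Largest component length on the grid (default 200; guard 500).
#'   The default range is ample to enclose the unimodal peak before the
#'   power-law asymptote takes over.
#' @param a_max Largest unique alphabet on the grid (default 30).
#' @return An object of class `cohsi_infogrid`: matrices `logN` and
#'   `dlogN_dt` (rows t = 1..t_max, cols a = 1..a_max, `NA` where `t < a`)
#'   plus interpolants. Use [info_at()] to evaluate at real-valued `t` and
#'   [generics::tidy()] to get the node table.
#' @examples
#' g <- build_info_grid(t_max = 40, a_max = 5)
#' info_at(g, 5, 2)$logN  # log 30
#' @export
build_info_grid <- function(t_max = 200, a_max = 30) {
  stopifnot(a_max >= 1, a_max <= t_max)
  if (t_max > 500) stop("grid too large: t_max guard is 500", call. = FALSE)
  logN <- matrix(NA_real_, nrow = t_max, ncol = a_max)
  for (a in seq_len(a_max)) {
    for (t in a:t_max) logN[t, a] <- big_log(count_exact_limbs(t, a))
  }
  dlogN <- matrix(NA_real_, nrow = t_max, ncol = a_max)
  for (a in seq_len(a_max)) {
    f <- logN[a:t_max, a]
    n <- length(f)
    d <- rep(NA_real_, n)
    if (n >= 3) {
      mid <- 2:(n - 1)
      d[mid] <- (f[mid + 1] - f[mid - 1]) / 2
      d[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / 2
      d[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / 2
    } else if (n == 2) {
      d <- c(f[2] - f[1], f[2] - f[1])
    } else {
      d <- 0  # single node: flat by convention (only arises when a = t_max)
    }
    dlogN[a:t_max, a] <- d
  }
  g <- structure(
    list(t_max = t_max, a_max = a_max, logN = logN, dlogN_dt = dlogN),
    class = "cohsi_infogrid"
  )
  g$interp <- build_grid_interp(g)
  g
}

build_grid_interp <- function(g) {
  lapply(seq_len(g$a_max), function(a) {
    ts <- a:g$t_max
    if (length(ts) < 2) return(NULL)
    list(
      logN = stats::splinefun(ts, g$logN[ts, a], method = "monoH.FC"),
      dlogN = stats::splinefun(ts, g$dlogN_dt[ts, a], method = "monoH.FC")
    )
  })
}

#' Evaluate the continued information surface at real-valued length
#'
#' Monotone-cubic interpolation of `log N(t, a)` and `dI/dt` at possibly
#' non-integer `t` for a fixed integer alphabet `a`. Exact at integer nodes.
#'
#' @param grid A [build_info_grid()] object.
#' @param t Length (real), vectorized; must satisfy `a <= t <= t_max`.
#' @param a Unique alphabet (integer scalar).
#' @return Tibble with columns `t`, `a`, `logN`, `dlogN_dt`.
#' @export
info_at <- function(grid, t, a) {
  stopifnot(inherits(grid, "cohsi_infogrid"), length(a) == 1L)
  if (a < 1 || a > grid$a_max) stop("`a` outside grid", call. = FALSE)
  if (any(t < a)) stop("domain error: t < a (component shorter than its alphabet)", call. = FALSE)
  if (any(t > grid$t_max)) stop("`t` beyond grid t_max", call. = FALSE)
  itp <- grid$interp[[a]]
  if (is.null(itp)) {
    stopifnot(all(t == a))
    return(tibble::tibble(t = t, a = a, logN = grid$logN[a, a],
                          dlogN_dt = grid$dlogN_dt[a, a]))
  }
  tibble::tibble(t = t, a = a, logN = itp$logN(t), dlogN_dt = itp$dlogN(t))
}

#' @export
print.cohsi_infogrid <- function(x, ...) {
  cat("<cohsi_infogrid> t = 1..", x$t_max, ", a = 1..", x$a_max,
      " (", sum(!is.na(x$logN)), " defined nodes)\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.cohsi_infogrid <- function(x, ...) {
  df <- expand.grid(t = seq_len(x$t_max), a = seq_len(x$a_max))
  out <- tibble::tibble(
    t = as.integer(df$t), a = as.integer(df$a),
    logN = as.vector(x$logN), dlogN_dt = as.vector(x$dlogN_dt)
  )
  dplyr::arrange(dplyr::filter(out, !is.na(.data$logN)), .data$a, .data$t)
}

#' Write / read an information grid as TSV
#'
#' Plain-text round-trip of the grid nodes (`t`, `a`, `logN`, `dlogN_dt`).
#' Reading rebuilds the interpolants from the stored node values without
#' recomputing the exact counts.
#'
#' @param grid A `cohsi_infogrid`.
#' @param path File path.
#' @return `read_info_grid()` returns a `cohsi_infogrid`.
#' @export
write_info_grid <- function(grid, path) {
  readr::write_tsv(tidy(grid), path)
  invisible(path)
}

#' @rdname write_info_grid
#' @export
read_info_grid <- function(path) {
  df <- readr::read_tsv(path, col_types = "iidd", progress = FALSE)
  t_max <- max(df$t)
  a_max <- max(df$a)
  logN <- matrix(NA_real_, t_max, a_max)
  dlogN <- matrix(NA_real_, t_max, a_max)
  logN[cbind(df$t, df$a)] <- df$logN
  dlogN[cbind(df$t, df$a)] <- df$dlogN_dt
  g <- structure(
    list(t_max = t_max, a_max = a_max, logN = logN, dlogN_dt = dlogN),
    class = "cohsi_infogrid"
  )
  g$interp <- build_grid_interp(g)
  g
}
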