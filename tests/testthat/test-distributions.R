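test_that("ccdf follows the >= convention and its structural invariants", {
  cc <- ccdf(c(1, 2, 2, 5))
  expect_equal(cc$x, c(1, 2, 5))
  expect_equal(cc$p, c(1, 0.75, 0.25))
  const <- ccdf(rep(7, 10))
  expect_equal(nrow(const), 1)
  expect_equal(const$p, 1)
  expect_error(ccdf(c(1, -2)), "positive")
  expect_error(ccdf(numeric(0)), "nonempty")
  # invariants on an arbitrary sample
  cc2 <- ccdf(generate_powerlaw_lengths(2.2, 1, 2000, seed = 5))
  expect_true(all(diff(cc2$p) < 0))
  expect_equal(cc2$p[1], 1)
})

test_that("ccdf of an exact power-law pmf has the exponent-minus-one log-log slope", {
  # analytic ccdf of p(x) ~ x^-2.5 by brute summation far past the fit range:
  # the ccdf slope is 1 - exponent
  vs <- 1:5e5
  tailp <- rev(cumsum(rev(vs^(-2.5))))
  cc <- tibble::tibble(x = vs[1:5000], p = (tailp / tailp[1])[1:5000])
  fit <- loglog_ols(cc, range = c(50, 5000))
  expect_equal(fit$slope, -1.5, tolerance = 0.01)
  # ccdf() on weighted finite data reproduces its own truncated analytic form
  # exactly (weights with a hard support cutoff are not the infinite law, so
  # the comparison is construction-exact rather than slope-based)
  x <- 1:200
  w <- round(1e6 * x^(-2.5))
  cc2 <- ccdf(rep(x, times = w))
  expect_equal(cc2$p, rev(cumsum(rev(w[w > 0]))) / sum(w))
})

test_that("exponential binning lays geometric edges and conserves the tail", {
  eb <- exponential_bin(1:1000, ratio = 10, x_low = 1)
  expect_equal(nrow(eb), 3)
  expect_equal(eb$lower, c(1, 10, 100))
  expect_equal(eb$upper, c(10, 100, 1000))
  expect_equal(sum(eb$count), 1000)       # last bin right-closed
  expect_error(exponential_bin(1:5, ratio = 2, x_low = 10), "x_low")
  expect_error(exponential_bin(1:5, ratio = 1))
})

test_that("exponentially binned power-law density is log-log linear with the pdf slope", {
  v <- generate_powerlaw_lengths(2.5, 1, 1e5, seed = 42)
  eb <- exponential_bin(v, ratio = 2, x_low = 1)
  keep <- eb$count >= 10
  fit <- loglog_ols(eb[keep, ], x_col = "mid", y_col = "density")
  expect_equal(fit$slope, -2.5, tolerance = 2 * fit$slope_se + 0.1)
  expect_gt(fit$adj_r2, 0.98)
})

test_that("rank recategorization conserves counts with the documented tie-break", {
  tab <- tibble::tibble(length_t = c(rep(5L, 300), rep(3L, 100), rep(50L, 100)))
  rk <- rank_recategorize(tab)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$frequency, c(300, 100, 100))
  expect_equal(rk$representative_value, c(5L, 3L, 50L))  # ties: ascending length
  expect_equal(sum(rk$frequency), nrow(tab))
  # arbitrary sample: nonincreasing frequencies, exact conservation
  lens <- generate_powerlaw_lengths(2.0, 1, 5000, seed = 8)
  rk2 <- rank_recategorize(tibble::tibble(length_t = lens))
  expect_true(all(diff(rk2$frequency) <= 0))
  expect_equal(sum(rk2$frequency), 5000)
})

test_that("dual alphabet table pairs per-composition alphabets within the 7x band", {
  ev <- generate_dual_alphabet_corpus(gamma = 1.5, c_scale = 1, n_comps = 20, seed = 2)
  tab <- dual_alphabet_table(ev)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$a_prime <= tab$a_doubleprime))
  expect_true(all(tab$a_doubleprime <= 7 * tab$a_prime))
  # single-duration corpus collapses the relation to identity
  mono <- tibble::tibble(
    composition_id = rep(c("a", "b"), each = 3),
    pitch = c(1L, 2L, 3L, 4L, 5L, 4L),
    duration_class = "crotchet"
  )
  tm <- dual_alphabet_table(mono)
  expect_equal(tm$a_prime, tm$a_doubleprime)
  one <- dplyr::filter(mono, composition_id == "a")
  expect_error(dual_alphabet_table(one), "at least 2")
})
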