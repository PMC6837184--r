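test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(generate_powerlaw_lengths(2.5, 1, 500, seed = 3),
                   generate_powerlaw_lengths(2.5, 1, 500, seed = 3))
  expect_identical(sample_exact_alphabet_string(8, 3, seed = 4),
                   sample_exact_alphabet_string(8, 3, seed = 4))
  expect_identical(generate_dual_alphabet_corpus(1.5, seed = 5),
                   generate_dual_alphabet_corpus(1.5, seed = 5))
  # seeding is scoped: the global RNG stream is not consumed
  withr::with_seed(99, {
    before <- stats::runif(1)
  })
  withr::with_seed(99, {
    invisible(generate_powerlaw_lengths(2.5, 1, 10, seed = 3))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("exact-alphabet sampling is uniform over the admissible strings", {
  # chi-squared check of the empirical draw frequencies against the exact
  # enumeration, at the 1% level
  for (cfg in list(c(4, 2), c(5, 2), c(5, 3))) {
    t <- cfg[1]; a <- cfg[2]
    pop <- enumerate_strings(t, LETTERS[1:a], a)
    n_draw <- 120 * length(pop)
    draws <- withr::with_seed(1000 + t * 10 + a, {
      replicate(n_draw, sample_exact_alphabet_string(t, a))
    })
    expect_true(all(draws %in% pop))
    obs <- table(factor(draws, levels = pop))
    chi <- stats::chisq.test(obs)
    expect_gt(chi$p.value, 0.01)
  }
  expect_equal(sample_exact_alphabet_string(6, 1, seed = 1), "AAAAAA")
  perm <- sample_exact_alphabet_string(5, 5, seed = 2)
  expect_setequal(strsplit(perm, "")[[1]], LETTERS[1:5])
  expect_error(sample_exact_alphabet_string(3, 5), "exceed")
})

test_that("power-law length generator has the predicted ccdf decay", {
  v <- generate_powerlaw_lengths(2.5, 1, 1e5, seed = 11)
  expect_true(all(v >= 1))
  expect_true(all(v == floor(v)))
  cc <- ccdf(v)
  fit <- loglog_ols(cc, range = c(3, 300))
  # ccdf exponent is pdf exponent - 1; discreteness bends the small-x end,
  # so agreement is to a band rather than the OLS standard error
  expect_equal(fit$slope, -1.5, tolerance = 0.15)
  expect_equal(length(generate_powerlaw_lengths(2.5, 4, 1, seed = 1)), 1)
  expect_gte(generate_powerlaw_lengths(2.5, 4, 1, seed = 1), 4)
  expect_error(generate_powerlaw_lengths(0.9, 1, 10), "exceed 1")
})

test_that("dual-alphabet corpus recovers its generating exponent", {
  ev <- generate_dual_alphabet_corpus(gamma = 1.5, c_scale = 1, n_comps = 41,
                                      noise_sd = 0, seed = 1)
  tab <- dual_alphabet_table(ev)
  fit <- loglog_ols(tab, x_col = "a_prime", y_col = "a_doubleprime")
  expect_equal(fit$slope, 1.5, tolerance = 1e-2)
  # identity case
  ev1 <- generate_dual_alphabet_corpus(gamma = 1, c_scale = 1, n_comps = 10, seed = 2)
  tab1 <- dual_alphabet_table(ev1)
  expect_equal(tab1$a_prime, tab1$a_doubleprime)
  fit1 <- loglog_ols(tab1, x_col = "a_prime", y_col = "a_doubleprime")
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_equal(fit1$intercept, 0, tolerance = 1e-12)
})

test_that("microstate census finds the multinomial mode and conserves totals", {
  ms <- enumerate_microstates(4, 2, c(1, 1))
  expect_equal(nrow(ms), 3)
  expect_equal(ms$multiplicity[ms$t_1 == 1], 4)
  expect_equal(ms$multiplicity[ms$t_1 == 2], 6)
  expect_true(ms$modal[ms$t_1 == 2])
  expect_equal(sum(ms$multiplicity), 2^4 - 2)   # all 1 <= t_i surjective splits
  # information column agrees with the heterogeneous information function
  ms2 <- enumerate_microstates(8, 2, c(2, 3))
  by_hand <- vapply(seq_len(nrow(ms2)), function(i) {
    het_information(ms2$t_1[i], 2) + het_information(ms2$t_2[i], 3)
  }, numeric(1))
  expect_equal(ms2$total_info, by_hand)
  expect_true(all(ms2$t_1 >= 2), all(ms2$t_2 >= 3))
  expect_error(enumerate_microstates(20, 2, c(1, 1)), "guard")
  expect_error(enumerate_microstates(4, 2, c(3, 3)), "cannot fit")
})
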