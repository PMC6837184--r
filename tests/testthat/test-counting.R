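test_that("worked-example counts are reproduced by recursion, closed form and enumeration", {
  cases <- list(
    list(t = 5, a = 2, ap = 1, n = 2),
    list(t = 5, a = 2, ap = 2, n = 30),
    list(t = 5, a = 3, ap = 3, n = 150),
    list(t = 5, a = 4, ap = 4, n = 240),
    list(t = 5, a = 5, ap = 5, n = 120)
  )
  for (cs in cases) {
    expect_equal(as.numeric(count_subalphabet(cs$t, cs$a, cs$ap)), cs$n)
    if (cs$ap == cs$a) {
      expect_equal(as.numeric(count_exact(cs$t, cs$a)), cs$n)
      expect_equal(as.numeric(count_closed_form(cs$t, cs$a)), cs$n)
    }
    expect_length(enumerate_strings(cs$t, LETTERS[seq_len(cs$a)], cs$ap), cs$n)
  }
  # the unconstrained count admits the letter-missing strings
  expect_equal(het_information_asymptotic(5, 2), log(32))
  # composition terms of the worked example: 1A4B gives 5 strings, 3A2B gives 10
  strings <- enumerate_strings(5, c("A", "B"), 2)
  n_a <- stringr::str_count(strings, "A")
  expect_equal(sum(n_a == 1), 5)
  expect_equal(sum(n_a == 3), 10)
})

test_that("recursion agrees with closed form and brute-force enumeration", {
  for (t in 1:8) {
    for (a in 1:min(t, 4)) {
      n_rec <- as.numeric(count_exact(t, a))
      expect_identical(n_rec, as.numeric(count_closed_form(t, a)))
      expect_identical(n_rec, as.numeric(oracle_count_strings(t, a, a)))
      for (ap in 1:a) {
        expect_identical(as.numeric(count_subalphabet(t, a, ap)),
                         as.numeric(oracle_count_strings(t, a, ap)))
      }
    }
  }
})

test_that("partition identity sums sub-alphabet counts to a^t exactly", {
  # exact big-integer identity well beyond double precision (8^20 > 2^53)
  for (t in c(1, 5, 12, 20)) {
    for (a in 1:8) {
      total <- Reduce(`+`, lapply(1:a, function(ap) count_subalphabet(t, a, ap)))
      expect_true(total == new_pow_bigint(a, t))
    }
  }
})

test_that("bounding and degenerate-case identities hold", {
  expect_equal(as.numeric(count_subalphabet(4, 5, 5)), 0)
  expect_equal(as.numeric(count_closed_form(9, 1)), 1)
  for (a in 2:6) {
    expect_true(count_exact(a, a) == factorial(a))
    expect_true(count_exact(a + 3, a) < new_pow_bigint(a, a + 3))
  }
})

test_that("het_information is the exact log count and increases with length", {
  expect_equal(het_information(5, 2), log(30))
  expect_equal(het_information(5, 5), log(120))
  expect_equal(het_information(7, 1), 0)
  expect_error(het_information(3, 5), "exceed")
  for (a in c(1, 3, 7)) {
    info <- vapply(a:(a + 15), function(t) het_information(t, a), numeric(1))
    if (a > 1) expect_true(all(diff(info) > 0)) else expect_true(all(info == 0))
    asym <- vapply(a:(a + 15), function(t) het_information_asymptotic(t, a), numeric(1))
    expect_true(all(asym - info >= 0))
  }
  # exact log on an integer far beyond double range: the recursion route must
  # agree with the log of the independent inclusion-exclusion route
  expect_equal(het_information(400, 25), log(count_closed_form(400, 25)),
               tolerance = 1e-12)
})

test_that("system_info totals are additive over subsystems", {
  ab <- tibble::tibble(length_t = c(2L, 2L), alphabet_a = c(2L, 2L))
  si <- system_info(ab)
  expect_equal(si$total_tokens_T, 4)
  expect_equal(si$log_omega, log(6))
  one <- system_info(tibble::tibble(length_t = 5L, alphabet_a = 2L))
  expect_equal(one$total_info_I, log(30))
  a_part <- tibble::tibble(length_t = c(5L, 8L), alphabet_a = c(2L, 3L))
  b_part <- tibble::tibble(length_t = c(12L, 4L), alphabet_a = c(4L, 2L))
  expect_equal(
    system_info(rbind(a_part, b_part))$total_info_I,
    system_info(a_part)$total_info_I + system_info(b_part)$total_info_I
  )
  expect_error(system_info(tibble::tibble(length_t = integer(), alphabet_a = integer())),
               "nonempty")
})

test_that("count table serializes counts losslessly as decimal strings", {
  tab <- count_table(6, 3)
  expect_true(all(tab$count[tab$a_prime > tab$t] == "0"))
  row <- tab[tab$t == 5 & tab$a == 2 & tab$a_prime == 2, ]
  expect_equal(row$count, "30")
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  back <- readr::read_tsv(path, col_types = "iiic", progress = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("argument errors are raised for invalid counting inputs", {
  expect_error(count_exact(0, 1))
  expect_error(count_exact(5, -1))
  expect_error(count_subalphabet(5, 2, 3), "a_prime")
  expect_error(enumerate_strings(13, c("A", "B"), 2), "guard")
})
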