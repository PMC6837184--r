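# Independent brute-force oracles, deliberately implemented without the
# package's recursion or closed form.

# count length-t strings over an a-letter alphabet using exactly `usage`
# distinct letters, by enumerating all a^t strings as base-a digit vectors
oracle_count_strings <- function(t, a, usage) {
  total <- a^t
  stopifnot(total <= 2e6)
  hits <- 0L
  for (code in 0:(total - 1)) {
    digs <- integer(t)
    x <- code
    for (j in seq_len(t)) {
      digs[j] <- x %% a
      x <- x %/% a
    }
    if (length(unique(digs)) == usage) hits <- hits + 1L
  }
  hits
}

# truncated zeta sum with integral remainder bracket: returns c(lower, upper)
oracle_hurwitz_bracket <- function(s, q, N = 20000L) {
  head <- sum((q + 0:(N - 1))^(-s))
  lower <- head + (q + N)^(1 - s) / (s - 1)
  upper <- head + (q + N - 1)^(1 - s) / (s - 1)
  c(lower, upper)
}

# exact a^t as a cohsi_bigint via repeated exported arithmetic (independent
# of the package's internal power routine)
new_pow_bigint <- function(a, t) {
  Reduce(function(acc, i) acc * a, seq_len(t), accumulate = FALSE,
         init = count_exact(1, 1))
}

make_note_events <- function() {
  tibble::tibble(
    composition_id = c("c1", "c1", "c1", "c2", "c2"),
    pitch = c(40L, 40L, 44L, 10L, 11L),
    duration_class = c("minim", "quaver", "minim", "breve", "breve")
  )
}

write_temp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("fix", tmpdir = dir, fileext = ".fa")
  writeLines(unlist(purrr::imap(records, function(s, id) c(paste0(">", id), s))), path)
  path
}
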