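.DURATION_CLASSES <- c("breve", "semibreve", "minim", "crotchet",
                       "quaver", "semiquaver", "demisemiquaver")

# the 22 genetically encoded amino acids: the standard 20 plus
# selenocysteine (U) and pyrrolysine (O)
.STRICT_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                      "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "U", "O")

#' Reduce a FASTA file to a component table
#'
#' One row per sequence record: `length_t` is the residue count (multi-line
#' sequences concatenated, whitespace stripped by the FASTA reader) and
#' `alphabet_a` the number of distinct residue characters after uppercasing.
#' Characters are taken verbatim -- the analysis is deliberately
#' token-agnostic, so ambiguity codes (B, Z, X) and the rarer genetically
#' encoded residues (U, O) count as distinct tokens. Set
#' `strict_residues = TRUE` to drop records containing anything outside the
#' 22 genetically encoded amino acids (mirrors curated-database practice).
#' Gzip-compressed files are handled transparently.
#'
#' @param path FASTA file (optionally `.gz`).
#' @param strict_residues Drop records with non-standard residue letters.
#' @return Component table: tibble with columns `component_id`, `length_t`,
#'   `alphabet_a`, `source` (`"fasta"`). Empty records are skipped with a
#'   warning.
#' @export
read_fasta_components <- function(path, strict_residues = FALSE) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- names(seqs)
  ids[is.na(ids) | ids == ""] <- paste0("record_", which(is.na(ids) | ids == ""))
  widths <- Biostrings::width(seqs)
  if (any(widths == 0)) {
    warning(sum(widths == 0), " empty sequence record(s) skipped", call. = FALSE)
    seqs <- seqs[widths > 0]
    ids <- ids[widths > 0]
    widths <- widths[widths > 0]
  }
  if (length(seqs) == 0) {
    return(tibble::tibble(component_id = character(), length_t = integer(),
                          alphabet_a = integer(), source = character()))
  }
  # byte-level counts per record: column j holds byte value j - 1
  freq <- Biostrings::alphabetFrequency(seqs)
  low_idx <- 97:122 + 1L  # 'a'..'z'
  up_idx <- 65:90 + 1L    # 'A'..'Z'
  freq[, up_idx] <- freq[, up_idx] + freq[, low_idx]
  freq[, low_idx] <- 0L
  if (strict_residues) {
    allowed <- utf8ToInt(paste(.STRICT_RESIDUES, collapse = "")) + 1L
    keep <- rowSums(freq[, -allowed, drop = FALSE]) == 0
    ids <- ids[keep]; widths <- widths[keep]
    freq <- freq[keep, , drop = FALSE]
  }
  tibble::tibble(
    component_id = sub("\\s.*$", "", ids),
    length_t = as.integer(widths),
    alphabet_a = as.integer(rowSums(freq > 0)),
    source = "fasta"
  )
}

#' Reduce a whitespace-tokenized stream to a component table
#'
#' One component per line; tokens are whitespace-separated, lines starting
#' with `#` and empty lines are skipped. This is the generic entry point for
#' pre-tokenized corpora (e.g. software functions, one function per line).
#'
#' @param path UTF-8 text file.
#' @return Component table (`source = "tokens"`); `length_t` is the token
#'   count and `alphabet_a` the distinct-token count per line.
#' @export
read_token_stream <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  toks <- stringr::str_split(stringr::str_trim(lines), "\\s+")
  if (length(toks) == 0 || sum(lengths(toks)) == 0) {
    stop("no tokens found in ", path, call. = FALSE)
  }
  tibble::tibble(
    component_id = paste0("line_", line_no),
    length_t = lengths(toks),
    alphabet_a = vapply(toks, function(x) length(unique(x)), integer(1)),
    source = "tokens"
  )
}

#' Read a note-event table
#'
#' TSV with header `composition_id`, `pitch`, `duration_class`. Pitches are
#' integer piano-key indices 1..88 (A0 = 1 .. C8 = 88, see [pitch_to_key()]);
#' durations must be one of the seven standard classes (breve down to
#' demisemiquaver, halving fractions of a whole note). Rarer dotted/tied
#' durations are rejected.
#'
#' @param path Note-event TSV.
#' @return Validated tibble with columns `composition_id`, `pitch`,
#'   `duration_class`.
#' @export
read_note_events <- function(path) {
  ev <- readr::read_tsv(path, col_types = readr::cols(
    composition_id = readr::col_character(),
    pitch = readr::col_integer(),
    duration_class = readr::col_character()
  ), progress = FALSE)
  validate_note_events(ev)
}

validate_note_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("composition_id", "pitch", "duration_class") %in% names(events)))
  bad <- which(!(events$duration_class %in% .DURATION_CLASSES))
  if (length(bad) > 0) {
    stop("unknown duration_class '", events$duration_class[bad[1]],
         "' in row ", bad[1], call. = FALSE)
  }
  bad_p <- which(events$pitch < 1 | events$pitch > 88 |
                   events$pitch != floor(events$pitch))
  if (length(bad_p) > 0) {
    stop("pitch out of piano range 1..88 in row ", bad_p[1], call. = FALSE)
  }
  tibble::as_tibble(events)
}

#' Component table of a note-event corpus under either alphabet
#'
#' Per composition, `length_t` is the event count -- identical whichever way
#' the alphabet is categorized, since recategorization cannot change how many
#' notes a piece contains -- while `alphabet_a` is either the number of
#' distinct pitches (`with_duration = FALSE`, at most 88) or of distinct
#' pitch-duration pairs (`with_duration = TRUE`, at most 88 x 7 = 616).
#'
#' @param events Note-event table (see [read_note_events()]).
#' @param with_duration Categorize by (pitch, duration) pairs instead of
#'   pitch alone.
#' @return Component table (`source` is `"notes_pitch"` or
#'   `"notes_pitch_duration"`).
#' @export
components_from_notes <- function(events, with_duration = FALSE) {
  events <- validate_note_events(events)
  events |>
    dplyr::group_by(.data$composition_id) |>
    dplyr::summarise(
      length_t = dplyr::n(),
      alphabet_a = if (with_duration) {
        dplyr::n_distinct(.data$pitch, .data$duration_class)
      } else {
        dplyr::n_distinct(.data$pitch)
      },
      .groups = "drop"
    ) |>
    dplyr::transmute(
      component_id = .data$composition_id,
      length_t = as.integer(.data$length_t),
      alphabet_a = as.integer(.data$alphabet_a),
      source = if (with_duration) "notes_pitch_duration" else "notes_pitch"
    )
}

#' Map scientific pitch notation to piano-key index
#'
#' `"A0"` is key 1, `"C4"` (middle C) key 40, `"C8"` key 88. Sharps (`#`)
#' and flats (`b`) are accepted.
#'
#' @param pitch Character vector like `"C4"`, `"F#3"`, `"Bb5"`.
#' @return Integer key indices in 1..88.
#' @export
pitch_to_key <- function(pitch) {
  m <- regmatches(pitch, regexec("^([A-Ga-g])([#b]?)(-?[0-9])$", pitch))
  offsets <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  key <- vapply(seq_along(pitch), function(i) {
    parts <- m[[i]]
    if (length(parts) == 0) stop("cannot parse pitch '", pitch[i], "'", call. = FALSE)
    acc <- if (parts[3] == "#") 1L else if (parts[3] == "b") -1L else 0L
    midi <- 12L * (as.integer(parts[4]) + 1L) + offsets[[toupper(parts[2])]] + acc
    midi - 20L
  }, integer(1))
  if (any(key < 1 | key > 88)) stop("pitch outside the 88-key piano range", call. = FALSE)
  key
}

#' Write / read a component table as TSV
#'
#' Plain-text round-trip with header
#' `component_id  length  alphabet  source`.
#'
#' @param table Component table.
#' @param path File path.
#' @return `read_component_table()` returns the tibble.
#' @export
write_component_table <- function(table, path) {
  stopifnot(all(c("component_id", "length_t", "alphabet_a", "source") %in% names(table)))
  out <- dplyr::select(table, component_id = "component_id", length = "length_t",
                       alphabet = "alphabet_a", source = "source")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  df <- readr::read_tsv(path, col_types = "ciic", progress = FALSE)
  out <- tibble::tibble(
    component_id = df$component_id,
    length_t = df$length,
    alphabet_a = df$alphabet,
    source = df$source
  )
  stopifnot(all(out$alphabet_a >= 1), all(out$alphabet_a <= out$length_t))
  out
}
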