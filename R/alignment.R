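#' Forced-alignment timing tables
#'
#' The package's canonical in-memory container for forced-alignment output is
#' a plain tibble with one row per *phone*, carrying its enclosing word and
#' turn. Words whose phone timings are unknown (e.g. out-of-dictionary tokens
#' the aligner emits as `<unk>`) keep a single row with `NA` phone columns.
#' All times are absolute seconds from the start of the audio file, intervals
#' are half-open `[start, end)`, and silence is represented implicitly as the
#' gap between consecutive words, never as a token.
#'
#' Required columns: `file_id`, `turn_id`, `speaker`, `word_index` (1-based
#' within turn), `word_label`, `word_start`, `word_end`, `phone_label`,
#' `phone_start`, `phone_end`.
#'
#' @name alignment-format
NULL

alignment_cols <- c(
  "file_id", "turn_id", "speaker", "word_index", "word_label",
  "word_start", "word_end", "phone_label", "phone_start", "phone_end"
)

#' Collapse an alignment table to one row per word
#'
#' @param alignment An alignment tibble (see [alignment-format]).
#' @return A tibble with one row per word and a `has_phones` flag that is
#'   `FALSE` exactly when the word carries no phone timings.
#' @export
align_words <- function(alignment) {
  assert_cols(alignment, alignment_cols, "alignment")
  alignment |>
    group_by(.data$file_id, .data$turn_id, .data$speaker, .data$word_index,
             .data$word_label, .data$word_start, .data$word_end) |>
    summarise(
      n_phones = sum(!is.na(.data$phone_start)),
      .groups = "drop"
    ) |>
    mutate(has_phones = .data$n_phones > 0) |>
    arrange(.data$file_id, .data$turn_id, .data$word_index)
}

#' Validate alignment invariants
#'
#' Checks that words are positive-duration, ordered and non-overlapping
#' within each turn, and that phones are positive-duration, ordered,
#' non-overlapping and contained in their word's span.
#'
#' @inheritParams align_words
#' @param tol Numeric slack (seconds) for containment/overlap comparisons,
#'   covering 10 ms aligner rounding at interval edges.
#' @return `alignment`, invisibly; aborts with an informative message on the
#'   first violated invariant.
#' @export
validate_alignment <- function(alignment, tol = 1e-6) {
  assert_cols(alignment, alignment_cols, "alignment")
  words <- align_words(alignment)
  bad <- words$word_end <= words$word_start
  if (any(bad)) {
    abort(sprintf("non-positive word duration at file %s turn %s word %d",
                  words$file_id[bad][1], words$turn_id[bad][1],
                  words$word_index[bad][1]))
  }
  ord <- words |>
    group_by(.data$file_id, .data$turn_id) |>
    summarise(
      monotone = all(diff(.data$word_start) > 0) || n() == 1,
      overlap_free = all(.data$word_start[-1] >= .data$word_end[-n()] - tol) || n() == 1,
      .groups = "drop"
    )
  if (any(!ord$monotone)) {
    r <- ord[!ord$monotone, ][1, ]
    abort(sprintf("words not ordered by start in file %s turn %s",
                  r$file_id, r$turn_id))
  }
  if (any(!ord$overlap_free)) {
    r <- ord[!ord$overlap_free, ][1, ]
    abort(sprintf("overlapping words in file %s turn %s", r$file_id, r$turn_id))
  }
  ph <- alignment |> filter(!is.na(.data$phone_start))
  if (nrow(ph) > 0) {
    if (any(ph$phone_end <= ph$phone_start)) {
      abort("non-positive phone duration found")
    }
    out <- ph$phone_start < ph$word_start - tol | ph$phone_end > ph$word_end + tol
    if (any(out)) {
      r <- ph[out, ][1, ]
      abort(sprintf("phone [%s] outside word span at file %s turn %s word %d",
                    r$phone_label, r$file_id, r$turn_id, r$word_index))
    }
    ovl <- ph |>
      group_by(.data$file_id, .data$turn_id, .data$word_index) |>
      summarise(
        ok = n() == 1 ||
          (all(diff(.data$phone_start) > 0) &&
             all(.data$phone_start[-1] >= .data$phone_end[-n()] - tol)),
        .groups = "drop"
      )
    if (any(!ovl$ok)) {
      r <- ovl[!ovl$ok, ][1, ]
      abort(sprintf("phones overlap or are unordered in file %s turn %s word %d",
                    r$file_id, r$turn_id, r$word_index))
    }
  }
  invisible(alignment)
}

#' Read / write the plain tab-separated alignment format
#'
#' One row per phone with columns `file_id`, `turn_id`, `speaker`,
#' `word_index`, `word_label`, `word_start`, `word_end`, `phone_label`,
#' `phone_start`, `phone_end`; phone columns are empty for words lacking
#' phone timings. Times are written at 10 ms-compatible precision (ms).
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return For the reader, a validated alignment tibble.
#' @export
read_alignment_tsv <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      file_id = readr::col_character(),
      turn_id = readr::col_character(),
      speaker = readr::col_character(),
      word_index = readr::col_integer(),
      word_label = readr::col_character(),
      word_start = readr::col_character(),
      word_end = readr::col_character(),
      phone_label = readr::col_character(),
      phone_start = readr::col_double(),
      phone_end = readr::col_double()
    ),
    progress = FALSE
  )
  assert_cols(raw, alignment_cols, basename(path))
  for (col in c("word_start", "word_end")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("malformed %s value '%s' at data row %d of %s",
                    col, raw[[col]][bad[1]], bad[1], basename(path)))
    }
    raw[[col]] <- v
  }
  mono <- raw |>
    distinct(.data$file_id, .data$turn_id, .data$word_index, .data$word_start) |>
    group_by(.data$file_id, .data$turn_id) |>
    summarise(ok = n() == 1 || all(diff(.data$word_start) > 0), .groups = "drop")
  if (any(!mono$ok)) {
    r <- mono[!mono$ok, ][1, ]
    first_row <- which(raw$file_id == r$file_id & raw$turn_id == r$turn_id)[1]
    abort(sprintf("non-monotone word times within file %s turn %s (near data row %d)",
                  r$file_id, r$turn_id, first_row))
  }
  validate_alignment(as_tibble(raw))
}

#' @rdname read_alignment_tsv
#' @param alignment An alignment tibble.
#' @export
write_alignment_tsv <- function(alignment, path) {
  assert_cols(alignment, alignment_cols, "alignment")
  out <- alignment |>
    mutate(across(c("word_start", "word_end", "phone_start", "phone_end"),
                  ~ round(.x, 3)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Group time-ordered words into speaker turns
#'
#' A turn is one speaker's uninterrupted stretch of speech: consecutive words
#' by the same speaker form one turn and a speaker change closes it.
#'
#' @param tokens A tibble of word tokens in time order, one row per phone
#'   (as produced by [read_textgrid()]), with columns `word_label`,
#'   `word_start`, `word_end`, `phone_label`, `phone_start`, `phone_end` and
#'   a word identifier column `word_index` that is constant across a word's
#'   phone rows.
#' @param speakers Character vector with one speaker id per *word* (in word
#'   order), or a single id for a one-speaker recording.
#' @param file_id File identifier stamped on the output.
#' @return An alignment tibble with `turn_id` of the form `"t001"` and
#'   `word_index` renumbered within each turn.
#' @export
assemble_turns <- function(tokens, speakers, file_id = "file1") {
  if (nrow(tokens) == 0) {
    return(tibble(
      file_id = character(), turn_id = character(), speaker = character(),
      word_index = integer(), word_label = character(),
      word_start = double(), word_end = double(),
      phone_label = character(), phone_start = double(), phone_end = double()
    ))
  }
  assert_cols(tokens, c("word_index", "word_label", "word_start", "word_end",
                        "phone_label", "phone_start", "phone_end"), "tokens")
  word_ids <- unique(tokens$word_index)
  n_words <- length(word_ids)
  if (length(speakers) == 1) speakers <- rep(speakers, n_words)
  if (length(speakers) != n_words) {
    abort(sprintf("need one speaker per word: %d words, %d speakers",
                  n_words, length(speakers)))
  }
  turn_of_word <- cumsum(c(TRUE, speakers[-1] != speakers[-n_words]))
  map <- tibble(
    word_index = word_ids,
    speaker = speakers,
    .turn = turn_of_word
  ) |>
    group_by(.data$.turn) |>
    mutate(.new_index = row_number()) |>
    ungroup() |>
    mutate(turn_id = sprintf("t%03d", .data$.turn))
  tokens |>
    left_join(map, by = "word_index") |>
    mutate(file_id = file_id, word_index = .data$.new_index) |>
    select(dplyr::all_of(alignment_cols)) |>
    validate_alignment()
}

#' Read a reference (manual) segmentation
#'
#' Expects a TSV with columns `file_id`, `speaker`, `start`, `end` and an
#' optional `finality` column (`final` / `non-final`); absent finality is
#' recorded as `"unknown"`. Rows are sorted by start time per speaker stream
#' (with a warning if they arrived unordered); overlapping phrases within a
#' stream are an error.
#'
#' @param path Path to the reference TSV.
#' @return A tibble of reference phrases ordered within each
#'   `(file_id, speaker)` stream.
#' @export
read_reference_tsv <- function(path) {
  ref <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  assert_cols(ref, c("file_id", "speaker", "start", "end"), basename(path))
  if (!"finality" %in% names(ref)) ref$finality <- "unknown"
  ref$finality[is.na(ref$finality)] <- "unknown"
  unordered <- ref |>
    group_by(.data$file_id, .data$speaker) |>
    summarise(ok = all(diff(.data$start) >= 0) || n() == 1, .groups = "drop")
  if (any(!unordered$ok)) {
    warn("reference phrases arrived unordered; sorting by start time")
  }
  ref <- ref |>
    mutate(speaker = as.character(.data$speaker),
           file_id = as.character(.data$file_id)) |>
    arrange(.data$file_id, .data$speaker, .data$start)
  ovl <- ref |>
    group_by(.data$file_id, .data$speaker) |>
    summarise(ok = n() == 1 || all(.data$start[-1] >= .data$end[-n()] - 1e-6),
              .groups = "drop")
  if (any(!ovl$ok)) {
    r <- ovl[!ovl$ok, ][1, ]
    abort(sprintf("overlapping reference phrases for speaker %s in file %s",
                  r$speaker, r$file_id))
  }
  as_tibble(ref)
}
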