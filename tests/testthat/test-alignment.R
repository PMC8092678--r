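test_that("TextGrid reader attaches phones by midpoint and skips silence", {
  words <- tibble::tibble(
    xmin = c(0, 0.20, 0.55),
    xmax = c(0.20, 0.55, 1.00),
    text = c("the", "cat", "")
  )
  phones <- tibble::tibble(
    xmin = c(0, 0.08, 0.20, 0.31, 0.44),
    xmax = c(0.08, 0.20, 0.31, 0.44, 0.55),
    text = c("DH", "AH", "K", "AE", "T")
  )
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid_long(tg, words, phones, extra_point_tier = TRUE)
  toks <- read_textgrid(tg)
  expect_equal(length(unique(toks$word_index)), 2)
  expect_equal(sum(toks$word_label == "the"), 2)  # 2 phones
  expect_equal(sum(toks$word_label == "cat"), 3)  # 3 phones
  # the empty-label interval produced no token; it is a 0.45 s gap
  expect_false(any(toks$word_start >= 0.55))

  # short format yields identical tokens
  tg2 <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid_short(tg2, words, phones)
  expect_equal(read_textgrid(tg2), toks)
})

test_that("TextGrid reader reports missing tiers and overlapping words", {
  words <- tibble::tibble(xmin = c(0, 0.15), xmax = c(0.2, 0.4),
                          text = c("a", "b"))
  phones <- tibble::tibble(xmin = 0, xmax = 0.2, text = "AH")
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid_long(tg, words, phones)
  expect_error(read_textgrid(tg, word_tier = "tokens"),
               "available interval tiers: words, phones")
  expect_error(read_textgrid(tg), "overlapping word intervals 1 and 2")
})

test_that("alignment TSV round trip reproduces synthetic turns at 10 ms", {
  corp <- synth_corpus(synth_config(n_files = 2, turns_per_file = 8), seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(corp$alignment, path)
  back <- read_alignment_tsv(path)
  expect_equal(nrow(back), nrow(corp$alignment))
  for (col in c("word_start", "word_end", "phone_start", "phone_end")) {
    expect_lt(max(abs(back[[col]] - corp$alignment[[col]]), na.rm = TRUE),
              0.01)
  }
  expect_identical(back$word_label, corp$alignment$word_label)
  # second round trip is exact (idempotent at the declared resolution)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("alignment TSV reader flags malformed and non-monotone rows", {
  al <- make_turn(c(0.2, 0.25), phone_counts = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(al, path)
  lines <- readLines(path)
  bad <- sub("^(f01\tt001\ts1\t1\tw01\t)[0-9.]+", "\\1oops", lines[2])
  writeLines(c(lines[1], bad, lines[-(1:2)]), path)
  expect_error(read_alignment_tsv(path), "malformed word_start .* row 1")

  swapped <- make_turn(c(0.2, 0.25), phone_counts = 2L)
  swapped$word_start[swapped$word_index == 2] <- -0.5  # out of order in time
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(swapped, path2)
  expect_error(read_alignment_tsv(path2), "non-monotone")
})

test_that("assemble_turns closes a turn on each speaker change", {
  toks <- make_turn(c(0.2, 0.2, 0.2, 0.2), gaps = 0.05, phone_counts = 2L) |>
    dplyr::select(-file_id, -turn_id, -speaker)
  out <- assemble_turns(toks, c("A", "A", "B", "A"), file_id = "fx")
  turns <- align_words(out)
  expect_equal(unique(turns$turn_id), c("t001", "t002", "t003"))
  expect_equal(
    turns |> dplyr::count(turn_id) |> dplyr::pull(n),
    c(2L, 1L, 1L)
  )
  # word_index restarts within each turn
  expect_equal(turns$word_index, c(1L, 2L, 1L, 1L))

  single <- assemble_turns(toks, "A")
  expect_equal(unique(align_words(single)$turn_id), "t001")
  empty <- assemble_turns(toks[0, ], character(0))
  expect_equal(nrow(empty), 0)
})

test_that("reference reader orders phrases and defaults finality to unknown", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    file_id = "f01", speaker = "s1",
    start = c(2.0, 0.0, 1.0), end = c(2.9, 0.9, 1.9)
  ), path)
  expect_warning(ref <- read_reference_tsv(path), "unordered")
  expect_equal(ref$start, c(0, 1, 2))
  expect_true(all(ref$finality == "unknown"))

  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    file_id = "f01", speaker = "s1",
    start = c(0, 0.5), end = c(0.9, 1.2), finality = "final"
  ), path2)
  expect_error(read_reference_tsv(path2), "overlapping reference phrases")
})

test_that("turn time accounting is exact: durations plus gaps span the turn", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 10), seed = 3)
  words <- align_words(corp$alignment)
  acc <- words |>
    dplyr::group_by(file_id, turn_id) |>
    dplyr::summarise(
      total = sum(word_end - word_start) +
        sum(pmax(word_start - dplyr::lag(word_end), 0), na.rm = TRUE),
      span = max(word_end) - min(word_start),
      .groups = "drop"
    )
  expect_lt(max(abs(acc$total - acc$span)), 1e-9)
})

test_that("validation rejects overlapping words and stray phones", {
  al <- make_turn(c(0.2, 0.2), phone_counts = 2L)
  al$word_start[al$word_index == 2] <- 0.1  # overlaps word 1
  expect_error(validate_alignment(al), "overlapping words")
  al2 <- make_turn(c(0.2, 0.2), phone_counts = 2L)
  al2$phone_end[1] <- 0.35  # escapes its word span
  expect_error(validate_alignment(al2), "outside word span")
})
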