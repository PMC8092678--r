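cfg <- detector_config()

test_that("speech rate is the inverse mean phone duration in the window", {
  # one word of 0.3 s holding 3 phones of 0.100 s
  al <- make_turn(0.3, phone_counts = 3L)
  s <- speech_rate_turn(turn_words(al), turn_phones(al), cfg)
  expect_equal(s$rate[1], 10.0)
  expect_equal(s$n_phones_in_window[1], 3L)

  # silence never contributes: a 0.5 s pause after a 0.2 s word leaves only
  # the first word's phones in its window
  al2 <- make_turn(c(0.2, 0.3), gaps = c(0.5, 0), phone_counts = c(2L, 3L))
  s2 <- speech_rate_turn(turn_words(al2), turn_phones(al2), cfg)
  expect_equal(s2$rate[1], 1 / 0.1)   # two phones of 0.1 s
  expect_equal(s2$n_phones_in_window[1], 2L)

  # a turn with no phone timings at all cannot be rated
  al3 <- make_turn(c(0.2, 0.2), phone_counts = 0L)
  expect_error(speech_rate_turn(turn_words(al3), turn_phones(al3), cfg),
               "no phone timings")
})

test_that("rates match a brute-force window enumeration on random turns", {
  set.seed(421)
  for (k in 1:200) {
    al <- random_turn(sprintf("t%03d", k))
    w <- turn_words(al)
    p <- turn_phones(al)
    if (nrow(p) == 0) next
    s <- speech_rate_turn(w, p, cfg)
    expect_equal(s$rate, oracle_speech_rate(w, p, cfg), tolerance = 1e-12)
  }
})

test_that("pass 1 thresholds at 88% of the largest positive difference", {
  # rates [5, 5, 9, 5]: diffs [0, +4, -4]; threshold 3.52; boundary at word 3
  series <- tibble::tibble(
    word_index = 1:4, onset = c(0, 0.3, 0.6, 0.9),
    n_phones_in_window = 3L,
    rate = c(5, 5, 9, 5), defined = TRUE,
    diff = c(NA, 0, 4, -4)
  )
  b <- detect_dsr_pass1(series, cfg)
  expect_equal(b$word_index, 3L)
  expect_equal(b$time, 0.6)
  expect_equal(b$source, "dsr_pass1")

  # strictly decreasing rates give no positive difference, hence no DSR
  series$rate <- c(9, 7, 5, 3)
  series$diff <- c(NA, -2, -2, -2)
  expect_equal(nrow(detect_dsr_pass1(series, cfg)), 0)
})

test_that("the largest positive difference is always flagged", {
  set.seed(99)
  for (k in 1:1000) {
    n <- sample(3:20, 1)
    rate <- runif(n, 2, 20)
    series <- tibble::tibble(
      word_index = seq_len(n), onset = (seq_len(n) - 1) * 0.25,
      n_phones_in_window = 3L, rate = rate, defined = TRUE,
      diff = c(NA, diff(rate))
    )
    b <- detect_dsr_pass1(series, cfg)
    d <- series$diff
    if (any(!is.na(d) & d > 0)) {
      expect_true(which.max(d) %in% b$word_index)
    } else {
      expect_equal(nrow(b), 0)
    }
  }
})

test_that("pass 2 only touches long, word-rich stretches and never duplicates", {
  # 12 words over ~3.6 s with one strong internal jump and no pass-1 boundary
  # strong enough to split it: build rates directly
  al <- make_turn(rep(0.3, 12), phone_counts = 3L)
  w <- turn_words(al)
  s <- speech_rate_turn(w, turn_phones(al), cfg)
  # uniform synthetic turn: no rate variation, pass 2 leaves it alone
  expect_equal(nrow(detect_dsr_pass2(w, s, detect_dsr_pass1(s, cfg), cfg)), 0)

  # two jumps: a dominant one at word 3 (pass 1) and a smaller one at word 9
  # that pass 2 must recover inside the remaining 12-word, 3.6 s stretch
  al14 <- make_turn(rep(0.3, 14), phone_counts = 3L)
  w <- turn_words(al14)
  s2 <- speech_rate_turn(w, turn_phones(al14), cfg)
  s2$rate <- c(5, 5, 12, 5, 5, 5, 5, 5, 9, 5, 5, 5, 5, 5)
  d <- rep(NA_real_, 14); d[2:14] <- diff(s2$rate)
  s2$diff <- d
  p1 <- detect_dsr_pass1(s2, cfg)
  expect_equal(p1$word_index, 3L)
  p2 <- detect_dsr_pass2(w, s2, p1, cfg)
  expect_equal(p2$word_index, 9L)
  expect_equal(p2$source, "dsr_pass2")
  expect_length(intersect(p1$word_index, p2$word_index), 0)

  # a short stretch (2.0 s / 6 words) is untouched even with a jump
  al3 <- make_turn(rep(0.32, 6), phone_counts = 3L)
  w3 <- turn_words(al3)
  s3 <- speech_rate_turn(w3, turn_phones(al3), cfg)
  s3$rate <- c(5, 5, 5, 9, 5, 5)
  s3$diff <- c(NA, diff(s3$rate))
  expect_equal(nrow(detect_dsr_pass2(w3, s3, tibble::tibble(
    word_index = integer(), time = double(), source = character()), cfg)), 0)
})

test_that("pause boundaries use a strict 300 ms inequality", {
  al <- make_turn(c(0.2, 0.2, 0.2), gaps = c(0.300, 0.301, 0),
                  phone_counts = 2L)
  w <- turn_words(al)
  b <- detect_pause_boundaries(w, cfg)
  expect_equal(b$word_index, 3L)  # only the 0.301 s gap
  expect_equal(b$source, "pause")

  off <- detector_config(use_pauses = FALSE)
  expect_equal(nrow(detect_pause_boundaries(w, off)), 0)
})

test_that("merging keeps the speech-rate source on double-flagged words", {
  dsr <- tibble::tibble(word_index = 3L, time = 0.9, source = "dsr_pass1")
  pause <- tibble::tibble(word_index = c(3L, 5L), time = c(0.9, 1.5),
                          source = "pause")
  m <- merge_boundaries(dsr, pause)
  expect_equal(m$word_index, c(3L, 5L))
  expect_equal(m$source, c("dsr_pass1", "pause"))
  expect_equal(nrow(merge_boundaries(dsr[0, ], pause[0, ])), 0)
})

test_that("segmentation partitions words and excludes single-word turns", {
  al <- make_turn(rep(0.2, 6), phone_counts = 2L)
  w <- turn_words(al)
  b <- tibble::tibble(word_index = c(3L, 5L), time = w$word_start[c(3, 5)],
                      source = "dsr_pass1")
  ph <- segment_turn(w, b, cfg)
  expect_equal(ph$n_words, c(2L, 2L, 2L))
  expect_equal(ph$first_word_index, c(1L, 3L, 5L))
  expect_false(any(ph$excluded))
  # phrases cover all words without overlap
  expect_equal(sum(ph$n_words), 6L)

  none <- segment_turn(w, b[0, ], cfg)
  expect_equal(nrow(none), 1)
  expect_equal(none$n_words, 6L)

  single <- make_turn(0.3, phone_counts = 2L)
  sp <- segment_turn(turn_words(single), b[0, ], cfg)
  expect_true(sp$excluded)

  bad <- tibble::tibble(word_index = 99L, time = 1, source = "pause")
  expect_error(segment_turn(w, bad, cfg), "word onset")
})

test_that("a pause opens a gap between consecutive phrases", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 20,
                                    pause_prob = 1), seed = 17)
  det <- suppressWarnings(detect_boundaries(corp$alignment))
  gaps <- det$phrases |>
    dplyr::group_by(file_id, turn_id) |>
    dplyr::mutate(gap = start - dplyr::lag(end)) |>
    dplyr::filter(!is.na(gap))
  expect_true(all(gaps$gap >= -1e-9))
  expect_gt(mean(gaps$gap > 0.3), 0.5)  # most true boundaries carry a pause
})

test_that("full detection equals the brute-force reference on random turns", {
  set.seed(1234)
  turns <- lapply(1:300, function(k) {
    random_turn(sprintf("t%03d", k),
                speaker = sprintf("s%d", k %% 2 + 1))
  })
  al <- dplyr::bind_rows(turns)
  det <- suppressWarnings(detect_boundaries(al, cfg))
  for (k in seq_along(turns)) {
    tid <- sprintf("t%03d", k)
    w <- turn_words(turns[[k]])
    p <- turn_phones(turns[[k]])
    got <- det$boundaries |> dplyr::filter(turn_id == tid)
    exp_b <- tryCatch(oracle_detect_turn(w, p, cfg), error = function(e) NULL)
    if (is.null(exp_b) || nrow(w) < cfg$min_turn_words) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$word_index, exp_b$word_index)
      expect_equal(got$source, exp_b$source)
    }
  }
})

test_that("boundaries always coincide with word onsets (never mid-word)", {
  corp <- synth_corpus(synth_config(n_files = 2, turns_per_file = 20), seed = 8)
  det <- suppressWarnings(detect_boundaries(corp$alignment))
  onsets <- align_words(corp$alignment) |>
    dplyr::transmute(file_id, turn_id, word_index, onset = word_start)
  j <- det$boundaries |>
    dplyr::left_join(onsets, by = c("file_id", "turn_id", "word_index"))
  expect_true(all(abs(j$time - j$onset) < 1e-12))
  # and no boundary time falls strictly inside any word span
  words <- align_words(corp$alignment)
  for (i in seq_len(nrow(det$boundaries))) {
    b <- det$boundaries[i, ]
    w <- words |> dplyr::filter(file_id == b$file_id, turn_id == b$turn_id)
    inside <- b$time > w$word_start + 1e-9 & b$time < w$word_end - 1e-9
    expect_false(any(inside))
  }
})

test_that("every multi-word turn with a positive rate difference gets a DSR", {
  corp <- synth_corpus(synth_config(n_files = 2, turns_per_file = 25), seed = 12)
  det <- suppressWarnings(detect_boundaries(corp$alignment))
  has_pos <- det$rates |>
    dplyr::group_by(file_id, turn_id) |>
    dplyr::summarise(pos = any(diff > 0, na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(pos)
  dsr <- det$boundaries |>
    dplyr::filter(source != "pause") |>
    dplyr::distinct(file_id, turn_id)
  expect_true(all(
    paste(has_pos$file_id, has_pos$turn_id) %in% paste(dsr$file_id, dsr$turn_id)
  ))
})

test_that("disabling pauses yields a subset of the full run's boundaries", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 25), seed = 5)
  full <- suppressWarnings(detect_boundaries(corp$alignment, cfg))
  nop <- suppressWarnings(
    detect_boundaries(corp$alignment, detector_config(use_pauses = FALSE)))
  key <- function(b) paste(b$file_id, b$turn_id, b$word_index)
  dsr_full <- full$boundaries |> dplyr::filter(source != "pause")
  expect_true(all(key(nop$boundaries) %in% key(dsr_full)))
  expect_true(all(key(dsr_full) %in% key(nop$boundaries)))
})

test_that("detection output is byte-identical across repeated runs", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 10), seed = 2)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_phrases_json(suppressWarnings(detect_boundaries(corp$alignment)), p1)
  write_phrases_json(suppressWarnings(detect_boundaries(corp$alignment)), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_phrases_json(p1)
  expect_gt(nrow(back$boundaries), 0)
  expect_equal(nrow(back$phrases) > 0, TRUE)
})

test_that("undefined-rate words are bridged by nearest defined neighbours", {
  # word 2 is <unk> followed by a long pause, so its window holds no phone
  al <- make_turn(c(0.25, 0.2, 0.25), gaps = c(0, 0.6, 0),
                  phone_counts = c(3L, 0L, 3L))
  s <- speech_rate_turn(turn_words(al), turn_phones(al), cfg)
  expect_false(s$defined[2])
  expect_true(is.na(s$diff[2]))
  # the word-3 difference is taken against word 1, the nearest defined one
  expect_equal(s$diff[3], s$rate[3] - s$rate[1])
})
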