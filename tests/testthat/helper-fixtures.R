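# fixture builders shared across test files

# a words-per-row turn: durations/gaps in seconds; phones split evenly unless
# phone_counts given (0 = <unk> word without phone timings)
make_turn <- function(durations, gaps = 0, t0 = 0, phone_counts = 3L,
                      file_id = "f01", turn_id = "t001", speaker = "s1",
                      labels = NULL) {
  n <- length(durations)
  gaps <- rep_len(gaps, n)[seq_len(n)]
  phone_counts <- rep_len(phone_counts, n)
  starts <- t0 + cumsum(c(0, durations[-n] + gaps[-n]))
  ends <- starts + durations
  if (is.null(labels)) labels <- sprintf("w%02d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    k <- phone_counts[i]
    if (k == 0) {
      return(tibble::tibble(
        word_index = i, word_label = "<unk>",
        word_start = starts[i], word_end = ends[i],
        phone_label = NA_character_, phone_start = NA_real_,
        phone_end = NA_real_))
    }
    edges <- seq(starts[i], ends[i], length.out = k + 1)
    tibble::tibble(
      word_index = i, word_label = labels[i],
      word_start = starts[i], word_end = ends[i],
      phone_label = sprintf("p%d", seq_len(k)),
      phone_start = edges[-(k + 1)], phone_end = edges[-1])
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(file_id = file_id, turn_id = turn_id, speaker = speaker,
                  .before = 1)
}

# random small turns for oracle-equivalence checks
random_turn <- function(turn_id, file_id = "f01", speaker = "s1") {
  n <- sample(2:12, 1)
  durations <- runif(n, 0.06, 0.45)
  gaps <- ifelse(runif(n) < 0.6, 0, runif(n, 0, 0.6))
  phone_counts <- sample(0:4, n, replace = TRUE, prob = c(0.08, 0.12, 0.3, 0.3, 0.2))
  if (all(phone_counts == 0)) phone_counts[sample(n, 1)] <- 2L
  make_turn(durations, gaps, t0 = runif(1, 0, 5), phone_counts = phone_counts,
            file_id = file_id, turn_id = turn_id, speaker = speaker)
}

turn_words <- function(alignment) prososeg::align_words(alignment)

turn_phones <- function(alignment) {
  alignment[!is.na(alignment$phone_start), ]
}

# write a minimal long-format TextGrid with words and phones interval tiers
write_textgrid_long <- function(path, words, phones, extra_point_tier = FALSE) {
  xmax <- max(words$xmax)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  n_tiers <- 2 + extra_point_tier
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = 0")
  w("xmax = %g", xmax)
  w("tiers? <exists>")
  w("size = %d", n_tiers)
  w("item []:")
  tier <- function(name, df, idx) {
    w("    item [%d]:", idx)
    w('        class = "IntervalTier"')
    w('        name = "%s"', name)
    w("        xmin = 0")
    w("        xmax = %g", xmax)
    w("        intervals: size = %d", nrow(df))
    for (i in seq_len(nrow(df))) {
      w("        intervals [%d]:", i)
      w("            xmin = %g", df$xmin[i])
      w("            xmax = %g", df$xmax[i])
      w('            text = "%s"', df$text[i])
    }
  }
  tier("words", words, 1)
  tier("phones", phones, 2)
  if (extra_point_tier) {
    w("    item [3]:")
    w('        class = "TextTier"')
    w('        name = "points"')
    w("        xmin = 0")
    w("        xmax = %g", xmax)
    w("        points: size = 1")
    w("        points [1]:")
    w("            number = 0.5")
    w('            mark = "x"')
  }
  invisible(path)
}

# short-format variant of the same content
write_textgrid_short <- function(path, words, phones) {
  xmax <- max(words$xmax)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('"ooTextFile"')
  w('"TextGrid"')
  w("0")
  w("%g", xmax)
  w("<exists>")
  w("2")
  tier <- function(name, df) {
    w('"IntervalTier"')
    w('"%s"', name)
    w("0")
    w("%g", xmax)
    w("%d", nrow(df))
    for (i in seq_len(nrow(df))) {
      w("%g", df$xmin[i])
      w("%g", df$xmax[i])
      w('"%s"', df$text[i])
    }
  }
  tier("words", words)
  tier("phones", phones)
  invisible(path)
}
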