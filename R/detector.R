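#' Detector configuration
#'
#' Parameters of the speech-rate / pause boundary detector. Defaults follow
#' the method's published operating point for spontaneous American English.
#'
#' @param window_s Speech-rate window duration in seconds. 0.300 s
#'   approximates the mean duration of a word; values between 0.250 and
#'   0.500 s behave similarly.
#' @param dsr_threshold_frac First-pass threshold as a fraction of the
#'   largest positive rate difference within a turn (default 0.88).
#' @param second_pass_threshold_frac Second-pass threshold fraction applied
#'   within long boundary-free stretches (default 0.70).
#' @param second_pass_min_duration_s,second_pass_min_words A stretch gets the
#'   second pass only when strictly longer than 3 s *and* holding strictly
#'   more than 10 words.
#' @param min_pause_s Silent gaps strictly longer than this mark a boundary
#'   at the following word onset (default 0.300 s, again about one word).
#' @param use_pauses Disable to detect from speech rate alone.
#' @param min_turn_words Turns with fewer words are returned as a single
#'   excluded phrase (single-unit turns such as backchannels are not
#'   segmented).
#' @param signed_diffs If `TRUE` (default) only positive rate differences —
#'   phrase-initial acceleration — can be discontinuities; if `FALSE`
#'   thresholds apply to absolute differences.
#' @return A `proso_config` list.
#' @export
detector_config <- function(window_s = 0.300,
                            dsr_threshold_frac = 0.88,
                            second_pass_threshold_frac = 0.70,
                            second_pass_min_duration_s = 3.0,
                            second_pass_min_words = 10L,
                            min_pause_s = 0.300,
                            use_pauses = TRUE,
                            min_turn_words = 2L,
                            signed_diffs = TRUE) {
  if (window_s <= 0) abort("window_s must be positive")
  if (min_pause_s < 0) abort("min_pause_s must be non-negative")
  if (!(dsr_threshold_frac > 0 && dsr_threshold_frac <= 1)) {
    abort("dsr_threshold_frac must lie in (0, 1]")
  }
  if (!(second_pass_threshold_frac > 0 &&
        second_pass_threshold_frac <= dsr_threshold_frac)) {
    abort("need 0 < second_pass_threshold_frac <= dsr_threshold_frac")
  }
  structure(
    list(
      window_s = window_s,
      dsr_threshold_frac = dsr_threshold_frac,
      second_pass_threshold_frac = second_pass_threshold_frac,
      second_pass_min_duration_s = second_pass_min_duration_s,
      second_pass_min_words = as.integer(second_pass_min_words),
      min_pause_s = min_pause_s,
      use_pauses = isTRUE(use_pauses),
      min_turn_words = as.integer(min_turn_words),
      signed_diffs = isTRUE(signed_diffs)
    ),
    class = "proso_config"
  )
}

#' @export
print.proso_config <- function(x, ...) {
  cat("<detector config>\n")
  cat(sprintf("  window: %.0f ms | pass 1: %.0f%% of max diff | pass 2: %.0f%% on stretches > %.1f s & > %d words\n",
              x$window_s * 1000, x$dsr_threshold_frac * 100,
              x$second_pass_threshold_frac * 100,
              x$second_pass_min_duration_s, x$second_pass_min_words))
  cat(sprintf("  pauses: %s (> %.0f ms) | min turn words: %d\n",
              if (x$use_pauses) "on" else "off", x$min_pause_s * 1000,
              x$min_turn_words))
  invisible(x)
}

#' Per-word-onset speech rate within a turn
#'
#' Local speech rate is the multiplicative inverse of the mean phone duration
#' inside a fixed window anchored at each word onset: for word onset `t0` the
#' window is `[t0, t0 + window_s)` and a phone contributes its full duration
#' when its midpoint falls inside the window. Silence never contributes
#' (only phones are pooled), so pauses inside the window are excluded from
#' the average. Words whose window captures no phone (e.g. `<unk>` words
#' followed by silence) get an undefined rate, flagged rather than zeroed.
#'
#' The consecutive-difference column `diff` is the rate change from the
#' nearest *preceding defined* rate, attached to the later word; it is `NA`
#' at the first defined word and at undefined-rate words.
#'
#' @param words One-row-per-word tibble for a single turn with `word_index`,
#'   `word_start`, `word_end`.
#' @param phones Tibble of that turn's phones: `phone_start`, `phone_end`
#'   (rows with `NA` are ignored).
#' @param config A [detector_config()].
#' @return A tibble: `word_index`, `onset`, `n_phones_in_window`, `rate`
#'   (1/s), `defined`, `diff`.
#' @export
speech_rate_turn <- function(words, phones, config = detector_config()) {
  phones <- phones |> filter(!is.na(.data$phone_start), !is.na(.data$phone_end))
  if (nrow(phones) == 0) {
    abort("turn has no phone timings at all; speech rate undefined")
  }
  mids <- (phones$phone_start + phones$phone_end) / 2
  durs <- phones$phone_end - phones$phone_start
  onsets <- words$word_start
  stats <- vapply(onsets, function(t0) {
    inw <- mids >= t0 & mids < t0 + config$window_s
    k <- sum(inw)
    c(k, if (k > 0) 1 / mean(durs[inw]) else NA_real_)
  }, numeric(2))
  out <- tibble(
    word_index = words$word_index,
    onset = onsets,
    n_phones_in_window = as.integer(stats[1, ]),
    rate = stats[2, ],
    defined = !is.na(stats[2, ])
  )
  out$diff <- NA_real_
  di <- which(out$defined)
  if (length(di) >= 2) {
    out$diff[di[-1]] <- out$rate[di[-1]] - out$rate[di[-length(di)]]
  }
  out
}

dsr_magnitude <- function(d, signed) if (signed) d else abs(d)

#' First-pass speech-rate discontinuities
#'
#' Thresholds the consecutive rate differences of one turn at
#' `dsr_threshold_frac` times the largest positive difference; every word
#' whose incoming difference strictly exceeds the threshold becomes a
#' boundary at its onset. If no positive difference exists the turn yields
#' no first-pass boundaries. The word attaining the maximum always exceeds
#' 88% of itself, so any turn with a positive difference yields at least one
#' discontinuity.
#'
#' @param series Output of [speech_rate_turn()].
#' @inheritParams speech_rate_turn
#' @return Tibble of boundaries: `word_index`, `time`, `source`.
#' @export
detect_dsr_pass1 <- function(series, config = detector_config()) {
  d <- dsr_magnitude(series$diff, config$signed_diffs)
  pos <- which(!is.na(d) & d > 0)
  if (length(pos) == 0) {
    return(tibble(word_index = integer(), time = double(), source = character()))
  }
  theta <- config$dsr_threshold_frac * max(d[pos])
  hit <- pos[d[pos] > theta]
  tibble(word_index = series$word_index[hit],
         time = series$onset[hit],
         source = "dsr_pass1")
}

#' Second-pass discontinuities within long boundary-free stretches
#'
#' Each stretch between consecutive first-pass boundaries (the turn's start
#' and end act as virtual boundaries) that lasts strictly longer than
#' `second_pass_min_duration_s` — first word onset to last word end — and
#' holds strictly more than `second_pass_min_words` words is re-thresholded
#' at `second_pass_threshold_frac` times the stretch's own largest positive
#' difference. The pass runs exactly once; second-pass boundaries never
#' duplicate first-pass ones.
#'
#' @inheritParams speech_rate_turn
#' @param series Output of [speech_rate_turn()].
#' @param pass1 First-pass boundaries for the same turn.
#' @return Tibble of `dsr_pass2` boundaries.
#' @export
detect_dsr_pass2 <- function(words, series, pass1,
                             config = detector_config()) {
  empty <- tibble(word_index = integer(), time = double(), source = character())
  n <- nrow(words)
  if (n == 0) return(empty)
  starts <- sort(unique(c(words$word_index[1], pass1$word_index)))
  ends <- c(starts[-1] - 1L, words$word_index[n])
  out <- list()
  for (k in seq_along(starts)) {
    idx <- which(words$word_index >= starts[k] & words$word_index <= ends[k])
    if (length(idx) <= config$second_pass_min_words) next
    span <- words$word_end[idx[length(idx)]] - words$word_start[idx[1]]
    if (span <= config$second_pass_min_duration_s) next
    inside <- series$word_index > starts[k] & series$word_index <= ends[k]
    d <- dsr_magnitude(series$diff, config$signed_diffs)
    d[!inside] <- NA_real_
    pos <- which(!is.na(d) & d > 0)
    if (length(pos) == 0) next
    theta <- config$second_pass_threshold_frac * max(d[pos])
    hit <- pos[d[pos] > theta]
    out[[length(out) + 1L]] <- tibble(
      word_index = series$word_index[hit],
      time = series$onset[hit],
      source = "dsr_pass2"
    )
  }
  if (length(out) == 0) empty else bind_rows(out)
}

#' Silent-pause boundaries
#'
#' Every inter-word gap strictly longer than `min_pause_s` yields a boundary
#' at the onset of the following word. Gap timing comes from the word
#' timings alone, so `<unk>` words still delimit silences correctly.
#'
#' @inheritParams speech_rate_turn
#' @return Tibble of `pause` boundaries (empty when `use_pauses` is off).
#' @export
detect_pause_boundaries <- function(words, config = detector_config()) {
  empty <- tibble(word_index = integer(), time = double(), source = character())
  if (!config$use_pauses || nrow(words) < 2) return(empty)
  gap <- words$word_start[-1] - words$word_end[-nrow(words)]
  hit <- which(gap > config$min_pause_s) + 1L
  tibble(word_index = words$word_index[hit],
         time = words$word_start[hit],
         source = "pause")
}

#' Merge speech-rate and pause boundaries
#'
#' Union by word index, sorted by time. When the same word is flagged both
#' by a rate discontinuity and by a pause, the boundary is attributed to
#' speech rate (pass 1 over pass 2 over pause).
#'
#' @param dsr,pause Boundary tibbles (`word_index`, `time`, `source`).
#' @return Deduplicated, time-sorted boundary tibble.
#' @export
merge_boundaries <- function(dsr, pause) {
  all <- bind_rows(dsr, pause)
  if (nrow(all) == 0) return(all)
  priority <- c(dsr_pass1 = 1L, dsr_pass2 = 2L, pause = 3L)
  all <- all[order(all$word_index, priority[all$source]), ]
  all <- all[!duplicated(all$word_index), ]
  all[order(all$time), c("word_index", "time", "source")]
}

#' Cut one turn into phrases at its boundaries
#'
#' Boundaries partition the turn's words; each phrase runs from its first
#' word's onset to its *last word's end*, so trailing silence is excluded
#' and a pause opens a gap between consecutive phrases. Turns shorter than
#' `min_turn_words` come back as a single phrase flagged `excluded` (they
#' never entered detection).
#'
#' @inheritParams speech_rate_turn
#' @param boundaries Merged boundary tibble for this turn; every
#'   `word_index` must be one of the turn's word onsets.
#' @return Tibble of phrases: `phrase_index`, `first_word_index`,
#'   `last_word_index`, `start`, `end`, `n_words`, `duration_s`, `excluded`.
#' @export
segment_turn <- function(words, boundaries, config = detector_config()) {
  n <- nrow(words)
  if (!all(boundaries$word_index %in% words$word_index)) {
    abort("boundary does not coincide with a word onset of this turn")
  }
  if (n < config$min_turn_words) {
    cut_at <- integer(0)
    excluded <- TRUE
  } else {
    cut_at <- setdiff(sort(unique(boundaries$word_index)), words$word_index[1])
    excluded <- FALSE
  }
  firsts <- c(words$word_index[1], cut_at)
  lasts <- c(cut_at - 1L, words$word_index[n])
  ia <- match(firsts, words$word_index)
  ib <- match(lasts, words$word_index)
  start <- words$word_start[ia]
  end <- words$word_end[ib]
  tibble(
    phrase_index = seq_along(firsts),
    first_word_index = as.integer(firsts),
    last_word_index = as.integer(lasts),
    start = start, end = end,
    n_words = ib - ia + 1L,
    duration_s = end - start,
    excluded = excluded
  )
}

detect_turn <- function(words, phones, config) {
  if (nrow(words) < config$min_turn_words) {
    return(list(
      boundaries = tibble(word_index = integer(), time = double(),
                          source = character()),
      phrases = segment_turn(words, tibble(word_index = integer(),
                                           time = double(),
                                           source = character()), config),
      rates = NULL
    ))
  }
  series <- speech_rate_turn(words, phones, config)
  p1 <- detect_dsr_pass1(series, config)
  p2 <- detect_dsr_pass2(words, series, p1, config)
  pa <- detect_pause_boundaries(words, config)
  b <- merge_boundaries(bind_rows(p1, p2), pa)
  list(boundaries = b, phrases = segment_turn(words, b, config), rates = series)
}

#' Detect prosodic phrase boundaries in an alignment table
#'
#' Runs the full training-free detector over every turn: per-word-onset
#' speech rate, first-pass thresholding at 88% of the turn's largest
#' positive rate difference, a second pass at 70% within long boundary-free
#' stretches, silent-pause boundaries, source-priority merging, and phrase
#' assembly. Deterministic given input and configuration. Turns that cannot
#' be processed (e.g. no phone timings anywhere) are kept as single excluded
#' phrases and reported via a warning summary.
#'
#' @param alignment An alignment tibble (see [alignment-format]).
#' @param config A [detector_config()].
#' @return A `proso_detection` object: a list of tibbles `boundaries`
#'   (`file_id`, `turn_id`, `speaker`, `word_index`, `time`, `source`),
#'   `phrases` (per-turn phrase spans) and `rates` (the speech-rate series),
#'   plus the configuration used.
#' @export
detect_boundaries <- function(alignment, config = detector_config()) {
  validate_alignment(alignment)
  words_all <- align_words(alignment)
  turns <- words_all |>
    group_by(.data$file_id, .data$turn_id, .data$speaker) |>
    group_split()
  phone_tab <- alignment |> filter(!is.na(.data$phone_start))
  phone_key <- paste(phone_tab$file_id, phone_tab$turn_id)
  failed <- character(0)
  res <- purrr::map(turns, function(w) {
    key <- paste(w$file_id[1], w$turn_id[1])
    ph <- phone_tab[phone_key == key, , drop = FALSE]
    out <- tryCatch(
      detect_turn(w, ph, config),
      error = function(e) {
        failed <<- c(failed, sprintf("%s/%s: %s", w$file_id[1], w$turn_id[1],
                                     conditionMessage(e)))
        list(
          boundaries = tibble(word_index = integer(), time = double(),
                              source = character()),
          phrases = tibble(
            phrase_index = 1L, first_word_index = w$word_index[1],
            last_word_index = w$word_index[nrow(w)],
            start = w$word_start[1], end = w$word_end[nrow(w)],
            n_words = nrow(w),
            duration_s = w$word_end[nrow(w)] - w$word_start[1],
            excluded = TRUE
          ),
          rates = NULL
        )
      }
    )
    stamp <- function(df) {
      k <- nrow(df)
      df$file_id <- rep(w$file_id[1], k)
      df$turn_id <- rep(w$turn_id[1], k)
      df$speaker <- rep(w$speaker[1], k)
      df[, c("file_id", "turn_id", "speaker",
             setdiff(names(df), c("file_id", "turn_id", "speaker")))]
    }
    list(
      boundaries = stamp(out$boundaries),
      phrases = stamp(out$phrases),
      rates = if (is.null(out$rates)) NULL else stamp(out$rates)
    )
  })
  if (length(failed) > 0) {
    warn(sprintf("%d turn(s) skipped by the detector:\n  %s",
                 length(failed),
                 paste(head(failed, 5), collapse = "\n  ")))
  }
  structure(
    list(
      boundaries = bind_rows(purrr::map(res, "boundaries")),
      phrases = bind_rows(purrr::map(res, "phrases")),
      rates = bind_rows(purrr::compact(purrr::map(res, "rates"))),
      config = config
    ),
    class = "proso_detection"
  )
}

#' @export
print.proso_detection <- function(x, ...) {
  nb <- nrow(x$boundaries)
  np <- nrow(x$phrases)
  cat("<prosodic boundary detection>\n")
  cat(sprintf("  %d boundaries over %d phrases in %d turns (%d files)\n",
              nb, np,
              nrow(distinct(x$phrases, .data$file_id, .data$turn_id)),
              length(unique(x$phrases$file_id))))
  if (nb > 0) {
    src <- table(x$boundaries$source)
    cat("  by source:", paste(sprintf("%s=%d", names(src), src), collapse = ", "), "\n")
  }
  incl <- x$phrases |> filter(!.data$excluded)
  if (nrow(incl) > 0) {
    cat(sprintf("  mean phrase length %.2f words, mean duration %.2f s\n",
                mean(incl$n_words), mean(incl$duration_s)))
  }
  invisible(x)
}

#' Attach phrase membership to words
#'
#' Joins an alignment's words onto detected (or ground-truth) phrases,
#' adding a phrase identifier and the word's position counted from the
#' phrase start and from its end.
#'
#' @param phrases A phrase tibble carrying `file_id`, `turn_id`,
#'   `first_word_index`, `last_word_index` (as in
#'   `detect_boundaries()$phrases`).
#' @param alignment The alignment the phrases refer to.
#' @return One row per word with `phrase_uid`, `position`, `position_from_end`.
#' @export
phrase_words <- function(phrases, alignment) {
  words <- align_words(alignment)
  ph <- phrases |>
    mutate(phrase_uid = paste(.data$file_id, .data$turn_id,
                              .data$first_word_index, sep = ":"))
  words |>
    left_join(
      ph |> select("file_id", "turn_id", "phrase_uid",
                   "first_word_index", "last_word_index",
                   dplyr::any_of(c("excluded", "finality"))),
      by = dplyr::join_by("file_id", "turn_id",
                          dplyr::between(x$word_index, y$first_word_index,
                                         y$last_word_index))
    ) |>
    filter(!is.na(.data$phrase_uid)) |>
    group_by(.data$phrase_uid) |>
    mutate(position = row_number(),
           position_from_end = n() - row_number() + 1L) |>
    ungroup()
}
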