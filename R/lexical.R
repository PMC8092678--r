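#' Word and phone durations by position from the phrase end
#'
#' Pre-boundary lengthening shows up as a rising duration profile towards
#' the last word and last phones of a phrase. Means are computed per audio
#' file and then aggregated across files (mean and s.e.m. over files), for
#' phrases holding `min_words` to `max_words` words.
#'
#' @param phrases Phrase tibble with `file_id`, `turn_id`,
#'   `first_word_index`, `last_word_index` (detector output or ground
#'   truth); rows flagged `excluded` are dropped.
#' @param alignment The alignment carrying the timings.
#' @param min_words,max_words Phrase-length filter (2-20 words).
#' @param n_word_positions,n_phone_positions How far from the end to report.
#' @return A `proso_posdur`: tibbles `words` and `phones` with
#'   `position_from_end` (1 = last), `mean_s`, `sem_s`, `n_files`, `n_obs`.
#' @export
duration_by_position <- function(phrases, alignment, min_words = 2L,
                                 max_words = 20L, n_word_positions = 6L,
                                 n_phone_positions = 12L) {
  if ("excluded" %in% names(phrases)) {
    phrases <- phrases |> filter(!.data$excluded)
  }
  sel <- phrases |>
    filter(.data$n_words >= min_words, .data$n_words <= max_words)
  if (nrow(sel) == 0) abort("no phrases left after the length filter")
  pw <- phrase_words(sel, alignment)
  word_pos <- pw |>
    filter(.data$position_from_end <= n_word_positions) |>
    mutate(duration_s = .data$word_end - .data$word_start)
  per_file_w <- word_pos |>
    group_by(.data$file_id, .data$position_from_end) |>
    summarise(m = mean(.data$duration_s), k = n(), .groups = "drop")
  words <- per_file_w |>
    group_by(position_from_end = .data$position_from_end) |>
    summarise(mean_s = mean(.data$m), sem_s = sem(.data$m),
              n_files = n(), n_obs = sum(.data$k), .groups = "drop")
  phones <- alignment |>
    filter(!is.na(.data$phone_start)) |>
    semi_join(pw, by = c("file_id", "turn_id", "word_index")) |>
    left_join(pw |> select("file_id", "turn_id", "word_index", "phrase_uid"),
              by = c("file_id", "turn_id", "word_index")) |>
    arrange(.data$phrase_uid, .data$phone_start) |>
    group_by(.data$phrase_uid) |>
    mutate(phone_pos_from_end = n() - row_number() + 1L) |>
    ungroup() |>
    filter(.data$phone_pos_from_end <= n_phone_positions) |>
    mutate(duration_s = .data$phone_end - .data$phone_start) |>
    group_by(.data$file_id, .data$phone_pos_from_end) |>
    summarise(m = mean(.data$duration_s), k = n(), .groups = "drop") |>
    group_by(position_from_end = .data$phone_pos_from_end) |>
    summarise(mean_s = mean(.data$m), sem_s = sem(.data$m),
              n_files = n(), n_obs = sum(.data$k), .groups = "drop")
  structure(list(words = words, phones = phones,
                 n_phrases = nrow(sel)),
            class = "proso_posdur")
}

#' @export
print.proso_posdur <- function(x, ...) {
  cat("<durations by position from phrase end>\n")
  w <- x$words
  cat(sprintf("  last word %.0f ms, earlier words %.0f ms (%d phrases)\n",
              1000 * w$mean_s[w$position_from_end == 1],
              1000 * mean(w$mean_s[w$position_from_end > 1]), x$n_phrases))
  invisible(x)
}

#' Phrase length and duration distributions with an exponential tail fit
#'
#' Word-count and duration histograms, per-file means with s.e.m., and an
#' ordinary-least-squares fit of `log(count)` against bin midpoint over the
#' duration tail (bins at and beyond `tail_start_s`), whose negative inverse
#' slope is the exponential time constant.
#'
#' @param phrases Phrase tibble with `file_id`, `n_words`, `duration_s` (or
#'   `start`/`end`); `excluded` rows are dropped.
#' @param bin_width_s Duration histogram bin width.
#' @param tail_start_s First bin midpoint included in the tail fit.
#' @param min_phrases Minimum number of phrases for fitting the tail.
#' @return A `proso_phrasedist`: `lengths` (count histogram), `durations`
#'   (binned histogram), `fit` (`tau_s`, `r2`, `n_bins`, `ok`, `reason`),
#'   `summary` (per-file mean words / duration with s.e.m.).
#' @export
phrase_distributions <- function(phrases, bin_width_s = 0.25,
                                 tail_start_s = 1.0, min_phrases = 100L) {
  if ("excluded" %in% names(phrases)) {
    phrases <- phrases |> filter(!.data$excluded)
  }
  if (!"duration_s" %in% names(phrases)) {
    phrases <- phrases |> mutate(duration_s = .data$end - .data$start)
  }
  if (nrow(phrases) == 0) abort("no phrases to summarise")
  lengths <- phrases |> dplyr::count(n_words = .data$n_words, name = "count")
  breaks <- seq(0, max(phrases$duration_s) + bin_width_s, by = bin_width_s)
  mid <- breaks[-1] - bin_width_s / 2
  counts <- tabulate(findInterval(phrases$duration_s, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(mid))
  durations <- tibble(mid_s = mid, count = counts)
  fit <- list(tau_s = NA_real_, r2 = NA_real_, n_bins = 0L, ok = FALSE,
              reason = "not attempted")
  if (nrow(phrases) < min_phrases) {
    fit$reason <- sprintf("fewer than %d phrases", min_phrases)
  } else {
    tail_bins <- durations |> filter(.data$mid_s >= tail_start_s, .data$count > 0)
    if (nrow(tail_bins) < 3 || sd(log(tail_bins$count)) == 0) {
      fit$reason <- "degenerate tail (too few occupied bins or no decay)"
    } else {
      # weights = counts: log of a Poisson count has variance ~ 1/count, so
      # sparsely populated far-tail bins must not steer the slope
      m <- lm(log(count) ~ mid_s, data = tail_bins, weights = tail_bins$count)
      slope <- coef(m)[["mid_s"]]
      if (slope >= 0) {
        fit$reason <- "tail does not decay"
      } else {
        fit <- list(tau_s = -1 / slope,
                    r2 = summary(m)$r.squared,
                    n_bins = nrow(tail_bins), ok = TRUE, reason = "ok")
      }
    }
  }
  per_file <- phrases |>
    group_by(.data$file_id) |>
    summarise(mw = mean(.data$n_words), md = mean(.data$duration_s),
              .groups = "drop")
  summary <- tibble(
    mean_words = mean(per_file$mw), sem_words = sem(per_file$mw),
    mean_duration_s = mean(per_file$md), sem_duration_s = sem(per_file$md),
    n_phrases = nrow(phrases), n_files = nrow(per_file)
  )
  structure(list(lengths = lengths, durations = durations, fit = fit,
                 summary = summary),
            class = "proso_phrasedist")
}

#' @export
print.proso_phrasedist <- function(x, ...) {
  s <- x$summary
  cat("<phrase length / duration distributions>\n")
  cat(sprintf("  %d phrases: %.2f +/- %.2f words, %.2f +/- %.2f s (per-file mean +/- sem, N = %d)\n",
              s$n_phrases, s$mean_words, s$sem_words, s$mean_duration_s,
              s$sem_duration_s, s$n_files))
  if (x$fit$ok) {
    cat(sprintf("  exponential tail: tau = %.2f s (R2 = %.3f, %d bins)\n",
                x$fit$tau_s, x$fit$r2, x$fit$n_bins))
  } else {
    cat(sprintf("  tail fit skipped: %s\n", x$fit$reason))
  }
  invisible(x)
}

#' Positional word frequencies
#'
#' For each of the first `k_positions` positions in a phrase, the
#' probability of each word at that position (count over the number of
#' phrases reaching the position), ranked. Error bars come from splitting
#' the corpus files into `n_groups` groups and treating each group as an
#' independent measurement.
#'
#' @param phrases Phrase tibble (`file_id`, `turn_id`, `first_word_index`,
#'   `last_word_index`).
#' @param alignment The alignment carrying the word labels.
#' @param k_positions Positions from the phrase start to analyse.
#' @param n_groups File groups for the s.e.m.
#' @param min_phrase_words Keep only phrases with at least this many words.
#' @param top_m Ranked list length for printing.
#' @param include_unk Keep `<unk>` tokens in the ranked tables (they always
#'   count towards position totals).
#' @return A `proso_postable`: `table` (pooled `position`, `word`, `n`,
#'   `prob`, `rank`), `groups` (per-position word probabilities with
#'   group mean and s.e.m.), and the position totals.
#' @export
word_position_frequencies <- function(phrases, alignment, k_positions = 4L,
                                      n_groups = 3L, min_phrase_words = 1L,
                                      top_m = 10L, include_unk = TRUE) {
  if ("excluded" %in% names(phrases)) {
    phrases <- phrases |> filter(!.data$excluded)
  }
  pw <- phrase_words(phrases |> filter(.data$n_words >= min_phrase_words),
                     alignment) |>
    filter(.data$position <= k_positions) |>
    mutate(word = normalize_label(.data$word_label))
  totals <- pw |> dplyr::count(position = .data$position, name = "total")
  tab <- pw |>
    dplyr::count(position = .data$position, word = .data$word, name = "n") |>
    left_join(totals, by = "position") |>
    mutate(prob = .data$n / .data$total)
  if (!include_unk) tab <- tab |> filter(.data$word != "<unk>")
  tab <- tab |>
    group_by(.data$position) |>
    arrange(dplyr::desc(.data$prob), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  files <- sort(unique(pw$file_id))
  grp_of <- setNames(rep(seq_len(n_groups), length.out = length(files)),
                     files)
  groups <- pw |>
    mutate(group = grp_of[.data$file_id]) |>
    group_by(.data$group, position = .data$position) |>
    mutate(total = n()) |>
    group_by(.data$group, .data$position, word = .data$word) |>
    summarise(prob = n() / .data$total[1], .groups = "drop") |>
    # groups where a word never occurs contribute probability 0; the moment
    # formulas below treat absent rows accordingly
    group_by(.data$position, .data$word) |>
    summarise(prob_mean = sum(.data$prob) / n_groups,
              prob_sem = sqrt(pmax(
                sum(.data$prob^2) / n_groups - (sum(.data$prob) / n_groups)^2,
                0) / max(n_groups - 1, 1)),
              .groups = "drop") |>
    group_by(.data$position) |>
    arrange(dplyr::desc(.data$prob_mean), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  structure(list(table = tab, groups = groups, totals = totals,
                 top_m = top_m, k_positions = k_positions),
            class = "proso_postable")
}

#' @export
print.proso_postable <- function(x, ...) {
  cat("<positional word frequencies>\n")
  for (p in seq_len(x$k_positions)) {
    top <- x$table |> filter(.data$position == p) |> head(x$top_m)
    cat(sprintf("  pos %d: %s\n", p,
                paste(sprintf("%s (%.1f%%)", top$word, 100 * top$prob),
                      collapse = ", ")))
  }
  invisible(x)
}
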