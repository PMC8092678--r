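#' Read a pitch-track TSV
#'
#' Columns `file_id`, `speaker`, `time` (seconds), `f0` (Hz; empty cells are
#' unvoiced samples and become `NA`).
#'
#' @param path Path to the TSV.
#' @return A tibble of pitch samples ordered by time within each
#'   `(file_id, speaker)` stream.
#' @export
read_pitch_tsv <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    file_id = readr::col_character(),
    speaker = readr::col_character(),
    time = readr::col_double(),
    f0 = readr::col_double()
  ), progress = FALSE)
  assert_cols(p, c("file_id", "speaker", "time", "f0"), basename(path))
  p |> arrange(.data$file_id, .data$speaker, .data$time)
}

# one stream on a regular grid: median filter on voiced runs, linear fill of
# gaps whose flanking voiced samples are closer than gap_s, then an NA-aware
# Hamming moving average (weights renormalized over available samples, so
# constants pass through unchanged)
preprocess_stream <- function(time, f0, median_k, gap_s, hamming_s) {
  o <- order(time)
  time <- time[o]; f0 <- f0[o]
  dt <- median(diff(time[!duplicated(time)]))
  if (!is.finite(dt) || dt <= 0) dt <- 0.01
  if (dt >= gap_s) {
    abort(sprintf("pitch sample spacing (%.0f ms) must be finer than the %.0f ms gap rule",
                  dt * 1000, gap_s * 1000))
  }
  grid <- seq(time[1], time[length(time)] + dt / 2, by = dt)
  g <- rep(NA_real_, length(grid))
  g[pmin(length(grid), round((time - time[1]) / dt) + 1L)] <- f0

  voiced <- !is.na(g)
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values & runs$lengths >= median_k)) {
    i <- starts[r]:ends[r]
    g[i] <- runmed(g[i], median_k, endrule = "median")
  }
  # fill unvoiced runs whose flanking voiced samples are closer than gap_s
  for (r in which(!runs$values)) {
    a <- starts[r] - 1L; b <- ends[r] + 1L
    if (a < 1 || b > length(g)) next
    if ((grid[b] - grid[a]) < gap_s) {
      i <- starts[r]:ends[r]
      g[i] <- g[a] + (g[b] - g[a]) * (grid[i] - grid[a]) / (grid[b] - grid[a])
    }
  }
  n <- round(hamming_s / dt)
  if (n %% 2 == 0) n <- n + 1L
  if (n >= 3) {
    voiced <- !is.na(g)
    w <- hamming_weights(n)
    pad <- (n - 1L) %/% 2L
    x0 <- c(rep(0, pad), ifelse(voiced, g, 0), rep(0, pad))
    m0 <- c(rep(0, pad), as.numeric(voiced), rep(0, pad))
    num <- stats::filter(x0, w, sides = 2)[(pad + 1L):(pad + length(g))]
    den <- stats::filter(m0, w, sides = 2)[(pad + 1L):(pad + length(g))]
    sm <- ifelse(voiced & den > 0, num / den, NA_real_)
    g <- as.numeric(sm)
  }
  tibble(time = grid, f0 = g)
}

#' Post-process a pitch track
#'
#' Per `(file_id, speaker)` stream: snap samples to a regular grid at the
#' stream's native spacing, apply a running median (spike removal), linearly
#' interpolate unvoiced gaps shorter than `gap_s` (flanking voiced samples
#' closer than 25 ms), and smooth with a Hamming-window moving average of
#' `hamming_s`. Longer gaps remain missing. Constant contours pass through
#' unchanged.
#'
#' @param pitch Pitch samples (`file_id`, `speaker`, `time`, `f0`).
#' @param median_k Running-median length in samples (odd).
#' @param gap_s Maximum gap span to interpolate, seconds.
#' @param hamming_s Smoothing window duration, seconds.
#' @return A tibble on the regular grid with `NA` for unvoiced samples.
#' @export
preprocess_pitch <- function(pitch, median_k = 5L, gap_s = 0.025,
                             hamming_s = 0.025) {
  assert_cols(pitch, c("file_id", "speaker", "time", "f0"), "pitch")
  if (nrow(pitch) == 0) abort("empty pitch track")
  pitch |>
    group_by(.data$file_id, .data$speaker) |>
    group_split() |>
    purrr::map_dfr(function(s) {
      preprocess_stream(s$time, s$f0, median_k, gap_s, hamming_s) |>
        mutate(file_id = s$file_id[1], speaker = s$speaker[1], .before = 1)
    })
}

#' Time- and amplitude-normalize one phrase contour
#'
#' Rescales the phrase span linearly to normalized time `[0, 1]`, resamples
#' the voiced pitch at `n_points` equally spaced grid points (linear
#' interpolation, edge values held constant), and divides by the resampled
#' contour's own mean, so every returned contour has mean 1. Phrases with
#' fewer than `min_voiced` voiced samples or more than `max_missing_frac`
#' unvoiced samples in their span are rejected (`NULL`).
#'
#' @param time,f0 Samples covering the phrase (may extend beyond it).
#' @param start,end Phrase span in seconds.
#' @param n_points Grid length (40 points).
#' @param min_voiced,max_missing_frac Voicing requirements within the span.
#' @return Tibble (`t`, `value`) with `n_points` rows, or `NULL`.
#' @export
normalize_contour <- function(time, f0, start, end, n_points = 40L,
                              min_voiced = 4L, max_missing_frac = 0.5) {
  if (end <= start) abort("phrase span must have positive duration")
  sel <- time >= start & time <= end
  time <- time[sel]; f0 <- f0[sel]
  voiced <- !is.na(f0)
  if (sum(voiced) < min_voiced || length(f0) == 0 ||
      mean(!voiced) > max_missing_frac) {
    return(NULL)
  }
  u <- (time - start) / (end - start)
  grid <- seq(0, 1, length.out = n_points)
  vals <- approx(u[voiced], f0[voiced], xout = grid, rule = 2, ties = mean)$y
  tibble(t = grid, value = vals / mean(vals))
}

#' Normalized pitch contours for a set of phrases
#'
#' @param pitch Pitch samples, ideally already through [preprocess_pitch()]
#'   (set `preprocess = TRUE` to do it here).
#' @param phrases Phrase spans: `file_id`, `speaker`, `start`, `end` (extra
#'   columns are kept on the output, one row per phrase).
#' @param preprocess Run [preprocess_pitch()] first.
#' @inheritParams normalize_contour
#' @return A tibble with `n_points` rows per accepted phrase: `file_id`,
#'   `speaker`, `phrase_uid`, `t`, `value`. The number of rejected phrases
#'   is in `attr(, "n_skipped")`.
#' @export
phrase_pitch_contours <- function(pitch, phrases, preprocess = FALSE,
                                  n_points = 40L, min_voiced = 4L,
                                  max_missing_frac = 0.5) {
  assert_cols(phrases, c("file_id", "speaker", "start", "end"), "phrases")
  if (preprocess) pitch <- preprocess_pitch(pitch)
  streams <- pitch |>
    group_by(.data$file_id, .data$speaker) |>
    group_split()
  names(streams) <- purrr::map_chr(streams, ~ paste(.x$file_id[1], .x$speaker[1]))
  skipped <- 0L
  out <- purrr::map(seq_len(nrow(phrases)), function(i) {
    s <- streams[[paste(phrases$file_id[i], phrases$speaker[i])]]
    if (is.null(s)) { skipped <<- skipped + 1L; return(NULL) }
    nc <- normalize_contour(s$time, s$f0, phrases$start[i], phrases$end[i],
                            n_points, min_voiced, max_missing_frac)
    if (is.null(nc)) { skipped <<- skipped + 1L; return(NULL) }
    nc$file_id <- phrases$file_id[i]
    nc$speaker <- phrases$speaker[i]
    nc$phrase_uid <- sprintf("%s:%s:%0.3f", phrases$file_id[i],
                             phrases$speaker[i], phrases$start[i])
    nc
  })
  res <- bind_rows(purrr::compact(out)) |>
    select("file_id", "speaker", "phrase_uid", "t", "value")
  attr(res, "n_skipped") <- skipped
  res
}

#' Pitch declination, reset, and end-variability statistics
#'
#' Per file: the mean normalized contour across phrases and the
#' across-phrase standard deviation as a function of normalized time. The
#' reset/declination contrast compares the mean pitch in the beginning
#' window (t = 0.15-0.25, just after the reset peak) against the end window
#' (t = 0.85-0.95); boundary-tone variability compares the across-phrase
#' standard deviation at the phrase end (t = 0.9-1) against the first half
#' (t = 0-0.5). Both contrasts are paired one-sided t-tests across files.
#'
#' @param contours Output of [phrase_pitch_contours()].
#' @param begin_window,end_window Normalized-time windows for the mean-pitch
#'   contrast.
#' @param std_first_window,std_end_window Windows for the variability
#'   contrast.
#' @return A `proso_pitch_summary`: `curves` (grand mean/std vs `t`),
#'   `by_file` (per-file window statistics and decline fraction
#'   `1 - end/begin`), `tests` (paired t-tests; absent with fewer than two
#'   files), `decline_frac_est`, `n_files`, `n_contours`.
#' @export
pitch_reset_stats <- function(contours,
                              begin_window = c(0.15, 0.25),
                              end_window = c(0.85, 0.95),
                              std_first_window = c(0, 0.5),
                              std_end_window = c(0.9, 1)) {
  assert_cols(contours, c("file_id", "phrase_uid", "t", "value"), "contours")
  if (nrow(contours) == 0) abort("no contours to summarise")
  per_file_curves <- contours |>
    group_by(.data$file_id, .data$t) |>
    summarise(mean = mean(.data$value), std = sd(.data$value),
              n = dplyr::n_distinct(.data$phrase_uid), .groups = "drop")
  if (any(per_file_curves$n < 2)) {
    warn("some files hold fewer than 2 contours; their std curve is NA")
  }
  win <- function(x, t, w) mean(x[t >= w[1] & t <= w[2]], na.rm = TRUE)
  by_file <- per_file_curves |>
    group_by(.data$file_id) |>
    summarise(
      begin_mean = win(.data$mean, .data$t, begin_window),
      end_mean = win(.data$mean, .data$t, end_window),
      std_first = win(.data$std, .data$t, std_first_window),
      std_end = win(.data$std, .data$t, std_end_window),
      n_contours = .data$n[1],
      .groups = "drop"
    ) |>
    mutate(decline_frac = 1 - .data$end_mean / .data$begin_mean)
  curves <- per_file_curves |>
    group_by(.data$t) |>
    summarise(mean = mean(.data$mean), std = mean(.data$std, na.rm = TRUE),
              .groups = "drop")
  # paired one-sided t-test across files; identical pairs (no effect at all)
  # have an undefined statistic and are reported with p = 1
  paired_t <- function(x, y) {
    if (sd(x - y) < 1e-12) {
      return(list(statistic = NA_real_, df = length(x) - 1L, p = 1))
    }
    ht <- t.test(x, y, paired = TRUE, alternative = "greater")
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
  }
  tests <- NULL
  if (nrow(by_file) >= 2) {
    t1 <- paired_t(by_file$begin_mean, by_file$end_mean)
    t2 <- paired_t(by_file$std_end, by_file$std_first)
    tests <- tibble(
      contrast = c("begin_mean > end_mean", "std_end > std_first_half"),
      statistic = c(t1$statistic, t2$statistic),
      df = c(t1$df, t2$df),
      p_value = c(t1$p, t2$p)
    )
  } else {
    warn("single file: paired t-tests skipped")
  }
  structure(
    list(curves = curves, by_file = by_file, tests = tests,
         decline_frac_est = mean(by_file$decline_frac),
         n_files = nrow(by_file),
         n_contours = dplyr::n_distinct(contours$phrase_uid)),
    class = "proso_pitch_summary"
  )
}

#' @export
print.proso_pitch_summary <- function(x, ...) {
  cat("<phrase pitch summary>\n")
  cat(sprintf("  %d contours in %d files\n", x$n_contours, x$n_files))
  cat(sprintf("  mean begin %.3f vs end %.3f -> decline %.1f%%\n",
              mean(x$by_file$begin_mean), mean(x$by_file$end_mean),
              100 * x$decline_frac_est))
  if (!is.null(x$tests)) {
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("  %s: t(%.0f) = %.2f, p = %.2g\n", x$tests$contrast[i],
                  x$tests$df[i], x$tests$statistic[i], x$tests$p_value[i]))
    }
  }
  invisible(x)
}

#' Random phrase-like spans (negative control)
#'
#' Chops each `(file_id, speaker)` word stream into random consecutive
#' intervals with exponentially distributed durations, ignoring the true
#' phrase structure. Averaging pitch contours over such arbitrary spans
#' should produce a flat mean curve; the contrast with the true
#' segmentation's declining curve is the arbitrariness control for the
#' pitch-reset analysis. Uses the current RNG state.
#'
#' @param alignment An alignment tibble delimiting each stream.
#' @param mean_duration_s Mean span duration (about one phrase).
#' @param min_duration_s Lower bound on span durations.
#' @return A phrase-like tibble: `file_id`, `speaker`, `start`, `end`.
#' @export
random_phrase_spans <- function(alignment, mean_duration_s = 1.0,
                                min_duration_s = 0.3) {
  align_words(alignment) |>
    group_by(.data$file_id, .data$speaker) |>
    summarise(t0 = min(.data$word_start), t1 = max(.data$word_end),
              .groups = "drop") |>
    group_by(.data$file_id, .data$speaker) |>
    group_split() |>
    purrr::map_dfr(function(s) {
      span <- s$t1 - s$t0
      n_max <- ceiling(span / min_duration_s) + 1L
      d <- min_duration_s +
        rexp(n_max, 1 / max(mean_duration_s - min_duration_s, 1e-6))
      cuts <- s$t0 + cumsum(d)
      edges <- c(s$t0, cuts[cuts < s$t1], s$t1)
      tibble(file_id = s$file_id, speaker = s$speaker,
             start = edges[-length(edges)], end = edges[-1])
    }) |>
    filter(.data$end - .data$start >= min_duration_s / 2)
}
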