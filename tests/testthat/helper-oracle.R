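# Independent brute-force reference implementations, written as plain loops
# and kept deliberately separate from the package's vectorized code paths.

oracle_speech_rate <- function(words, phones, cfg) {
  n <- nrow(words)
  rate <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t0 <- words$word_start[i]
    durs <- c()
    for (j in seq_len(nrow(phones))) {
      if (is.na(phones$phone_start[j])) next
      m <- (phones$phone_start[j] + phones$phone_end[j]) / 2
      if (m >= t0 && m < t0 + cfg$window_s) {
        durs <- c(durs, phones$phone_end[j] - phones$phone_start[j])
      }
    }
    if (length(durs) > 0) rate[i] <- 1 / mean(durs)
  }
  rate
}

oracle_detect_turn <- function(words, phones, cfg) {
  n <- nrow(words)
  rate <- oracle_speech_rate(words, phones, cfg)
  if (all(is.na(rate))) stop("no defined rate")
  d <- rep(NA_real_, n)
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (!is.na(rate[i])) {
      if (!is.na(last)) d[i] <- rate[i] - rate[last]
      last <- i
    }
  }
  b1 <- integer(0)
  pos <- which(!is.na(d) & d > 0)
  if (length(pos) > 0) {
    th <- cfg$dsr_threshold_frac * max(d[pos])
    for (i in pos) if (d[i] > th) b1 <- c(b1, i)
  }
  b2 <- integer(0)
  edges <- c(sort(unique(c(1L, b1))), n + 1L)
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]
    b <- edges[k + 1L] - 1L
    if ((b - a + 1L) > cfg$second_pass_min_words &&
        (words$word_end[b] - words$word_start[a]) > cfg$second_pass_min_duration_s) {
      ids <- seq(a + 1L, b)
      posp <- ids[!is.na(d[ids]) & d[ids] > 0]
      if (length(posp) > 0) {
        th2 <- cfg$second_pass_threshold_frac * max(d[posp])
        for (i in posp) if (d[i] > th2) b2 <- c(b2, i)
      }
    }
  }
  bp <- integer(0)
  if (cfg$use_pauses && n >= 2) {
    for (i in 2:n) {
      if (words$word_start[i] - words$word_end[i - 1] > cfg$min_pause_s) {
        bp <- c(bp, i)
      }
    }
  }
  src <- c(rep("dsr_pass1", length(b1)), rep("dsr_pass2", length(b2)),
           rep("pause", length(bp)))
  idx <- c(b1, b2, bp)
  keep <- !duplicated(idx)  # order encodes the source priority
  out <- data.frame(word_index = idx[keep], source = src[keep])
  out[order(out$word_index), ]
}

# textbook chi-square on a contingency table
oracle_chisq <- function(obs, yates = FALSE) {
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (yates) sum((abs(obs - E) - 0.5)^2 / E) else sum((obs - E)^2 / E)
}

# slot marking oracle: each reference time claims its nearest in-tolerance
# slot, nearest pairs first
oracle_mark_slots <- function(onsets, ref_times, tol) {
  marked <- rep(FALSE, length(onsets))
  pairs <- expand.grid(r = seq_along(ref_times), s = seq_along(onsets))
  pairs$d <- abs(ref_times[pairs$r] - onsets[pairs$s])
  pairs <- pairs[pairs$d <= tol, ]
  pairs <- pairs[order(pairs$d, pairs$r), ]
  used_r <- rep(FALSE, length(ref_times))
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$r[i]; s <- pairs$s[i]
    if (used_r[r] || marked[s]) next
    used_r[r] <- TRUE
    marked[s] <- TRUE
  }
  marked
}
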