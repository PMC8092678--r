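# Praat TextGrid interval-tier reader (long and short text formats).
#
# Both formats carry the same token stream once structural decoration is
# stripped: quoted strings, bare numbers, and the <exists> marker, in a fixed
# order. Parsing therefore tokenizes first and walks the stream, which keeps
# one code path for the two dialects.

textgrid_tokens <- function(lines) {
  out <- list()
  push <- function(type, value) out[[length(out) + 1L]] <<- list(type = type, value = value)
  for (line in lines) {
    s <- trimws(line)
    if (s == "") next
    # structural headers like `item [1]:` / `intervals [2]:` carry no data
    if (grepl("^(item|intervals|points)\\s*\\[\\d*\\]\\s*:?\\s*$", s)) next
    if (grepl("=", s, fixed = TRUE)) {
      s <- trimws(sub("^[^=]*=", "", s))
    }
    if (grepl("<exists>", s, fixed = TRUE)) {
      push("marker", "<exists>")
      next
    }
    if (grepl('^"', s)) {
      v <- sub('^"', "", sub('"\\s*$', "", s))
      push("string", gsub('""', '"', v))
      next
    }
    num <- suppressWarnings(as.numeric(sub("\\s.*$", "", s)))
    if (!is.na(num)) push("number", num)
  }
  out
}

#' Read word and phone tiers from a Praat TextGrid
#'
#' Parses a TextGrid (long or short text format), takes the named word and
#' phone interval tiers, drops silence intervals (empty labels and common
#' aligner silence tags), and attaches each phone to the word whose span
#' contains the phone's midpoint, which is robust to 10 ms rounding at word
#' edges. Silences become implicit inter-word gaps; no token is emitted for
#' them.
#'
#' @param path Path to the TextGrid file.
#' @param word_tier,phone_tier Names of the interval tiers holding words and
#'   phones. If `phone_tier` is `NA` or absent words carry no phone rows.
#' @param silence_labels Interval labels treated as silence.
#' @return A token tibble with one row per phone (or one `NA`-phone row for
#'   words with no phones): `word_index`, `word_label`, `word_start`,
#'   `word_end`, `phone_label`, `phone_start`, `phone_end`. Feed it to
#'   [assemble_turns()] to obtain an alignment table.
#' @export
read_textgrid <- function(path, word_tier = "words", phone_tier = "phones",
                          silence_labels = c("", "sil", "sp", "spn", "<sil>")) {
  toks <- textgrid_tokens(readLines(path, warn = FALSE, encoding = "UTF-8"))
  types <- vapply(toks, `[[`, "", "type")
  vals <- lapply(toks, `[[`, "value")
  i <- 1L
  take <- function(type) {
    while (i <= length(toks) && types[i] == "marker") i <<- i + 1L
    if (i > length(toks) || types[i] != type) {
      abort(sprintf("malformed TextGrid %s: expected %s at token %d",
                    basename(path), type, i))
    }
    v <- vals[[i]]
    i <<- i + 1L
    v
  }
  if (!identical(take("string"), "ooTextFile")) {
    abort(sprintf("%s is not an ooTextFile TextGrid", basename(path)))
  }
  if (!identical(take("string"), "TextGrid")) {
    abort(sprintf("%s is not a TextGrid object", basename(path)))
  }
  take("number"); take("number")          # global xmin, xmax
  n_tiers <- take("number")
  tiers <- list()
  for (k in seq_len(n_tiers)) {
    cls <- take("string")
    name <- take("string")
    take("number"); take("number")        # tier xmin, xmax
    n <- take("number")
    if (identical(cls, "IntervalTier")) {
      xmin <- xmax <- numeric(n)
      text <- character(n)
      for (j in seq_len(n)) {
        xmin[j] <- take("number")
        xmax[j] <- take("number")
        text[j] <- take("string")
      }
      tiers[[name]] <- tibble(xmin = xmin, xmax = xmax, text = text)
    } else {                              # point tier: skip (time, mark) pairs
      for (j in seq_len(n)) { take("number"); take("string") }
      tiers[[name]] <- NULL
    }
  }
  for (tier in word_tier) {
    if (!tier %in% names(tiers)) {
      abort(sprintf("tier '%s' not found in %s; available interval tiers: %s",
                    tier, basename(path), paste(names(tiers), collapse = ", ")))
    }
  }
  words <- tiers[[word_tier]] |>
    filter(!tolower(trimws(.data$text)) %in% silence_labels)
  if (nrow(words) > 1 &&
      any(words$xmin[-1] < words$xmax[-nrow(words)] - 1e-9)) {
    idx <- which(words$xmin[-1] < words$xmax[-nrow(words)] - 1e-9)[1]
    abort(sprintf("overlapping word intervals %d and %d in tier '%s' of %s",
                  idx, idx + 1L, word_tier, basename(path)))
  }
  words <- words |>
    mutate(word_index = row_number()) |>
    rename(word_label = "text", word_start = "xmin", word_end = "xmax")
  phones <- NULL
  if (!is.na(phone_tier) && phone_tier %in% names(tiers)) {
    phones <- tiers[[phone_tier]] |>
      filter(!tolower(trimws(.data$text)) %in% silence_labels)
  }
  if (is.null(phones) || nrow(phones) == 0) {
    return(words |>
             mutate(phone_label = NA_character_, phone_start = NA_real_,
                    phone_end = NA_real_) |>
             select("word_index", "word_label", "word_start", "word_end",
                    "phone_label", "phone_start", "phone_end"))
  }
  mid <- (phones$xmin + phones$xmax) / 2
  owner <- vapply(mid, function(m) {
    k <- which(words$word_start <= m & m < words$word_end)
    if (length(k) == 0) NA_integer_ else k[1]
  }, integer(1))
  phones <- phones |>
    mutate(word_index = owner) |>
    filter(!is.na(.data$word_index)) |>
    rename(phone_label = "text", phone_start = "xmin", phone_end = "xmax")
  words |>
    left_join(phones, by = "word_index") |>
    select("word_index", "word_label", "word_start", "word_end",
           "phone_label", "phone_start", "phone_end") |>
    arrange(.data$word_index, .data$phone_start)
}
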