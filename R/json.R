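#' Write detected phrases to JSON
#'
#' Schema: an array of files, each `{file_id, turns: [{turn_id, speaker,
#' boundaries: [{time, word_index, source}], phrases: [{start, end, n_words,
#' first_word_index, last_word_index, excluded}]}]}`. Output is
#' deterministic for a given detection.
#'
#' @param detection A `proso_detection` from [detect_boundaries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phrases_json <- function(detection, path) {
  if (!inherits(detection, "proso_detection")) {
    abort("detection must come from detect_boundaries()")
  }
  files <- lapply(unique(detection$phrases$file_id), function(f) {
    ph_f <- detection$phrases |> filter(.data$file_id == f)
    bd_f <- detection$boundaries |> filter(.data$file_id == f)
    turns <- lapply(unique(ph_f$turn_id), function(tn) {
      ph <- ph_f |> filter(.data$turn_id == tn)
      bd <- bd_f |> filter(.data$turn_id == tn)
      list(
        turn_id = tn,
        speaker = ph$speaker[1],
        boundaries = bd |> select("time", "word_index", "source"),
        phrases = ph |> select("start", "end", "n_words", "first_word_index",
                               "last_word_index", "excluded")
      )
    })
    list(file_id = f, turns = turns)
  })
  jsonlite::write_json(files, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read phrases JSON back into tibbles
#'
#' @param path A file written by [write_phrases_json()].
#' @return A list with `boundaries` and `phrases` tibbles (same columns as
#'   in a `proso_detection`).
#' @export
read_phrases_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  one <- function(field) {
    purrr::map_dfr(seq_len(nrow(js)), function(i) {
      turns <- js$turns[[i]]
      purrr::map_dfr(seq_len(nrow(turns)), function(k) {
        df <- turns[[field]][[k]]
        if (is.null(df) || length(df) == 0 || nrow(as.data.frame(df)) == 0) {
          return(tibble())
        }
        as_tibble(df) |>
          mutate(file_id = js$file_id[i], turn_id = turns$turn_id[k],
                 speaker = turns$speaker[k], .before = 1)
      })
    })
  }
  list(boundaries = one("boundaries"), phrases = one("phrases"))
}
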