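#' Default conversational lexicon for the generator
#'
#' A small function-word-heavy lexicon with a phrase-initial bias: the
#' initial-position weights favour coordinators, pronouns and discourse
#' markers ("and" opens 10% of phrases), mirroring the positional word
#' statistics of spontaneous American English conversation.
#'
#' @return A tibble with `word`, `w_initial` and `w_other` sampling weights
#'   (each column sums to 1).
#' @export
default_lexicon <- function() {
  lex <- tibble(
    word = c(
      "and", "i", "you", "the", "but", "that", "so", "yeah", "well", "oh",
      "a", "to", "it", "was", "know", "he", "she", "they", "we", "of",
      "in", "on", "have", "do", "don't", "just", "really", "think", "said",
      "going", "want", "got", "one", "there", "what", "when", "then",
      "because", "people", "time", "good", "right", "little", "thing",
      "like", "is", "not", "be", "with", "for"
    ),
    w_initial = c(
      0.100, 0.070, 0.050, 0.045, 0.040, 0.035, 0.030, 0.030, 0.025, 0.020,
      # filler tail scaled so the head probabilities above hold exactly
      (0.555 / 0.455) *
        c(rep(0.015, 10), rep(0.012, 10), rep(0.010, 10), rep(0.0085, 10))
    ),
    w_other = c(
      0.015, 0.030, 0.025, 0.035, 0.008, 0.015, 0.008, 0.004, 0.004, 0.004,
      0.025, 0.025, 0.020, 0.020, 0.015, rep(0.018, 10), rep(0.016, 10),
      rep(0.014, 10), rep(0.012, 5)
    )
  )
  lex$w_initial <- lex$w_initial / sum(lex$w_initial)
  lex$w_other <- lex$w_other / sum(lex$w_other)
  lex
}

#' Synthetic-conversation generator configuration
#'
#' Defaults emulate the timing, pause, pitch and lexical structure of
#' spontaneous American English conversation as measured on manually
#' segmented intonation units: mean phrase length 4.1 words (shifted
#' geometric, giving phrase durations an exponential tail with a time
#' constant near 0.7 s), middle words 201 ms, final words 356 ms with final
#' lengthening spread over the last word's phones (middle phones near 74 ms,
#' closing phones near 118 ms), first words of 3+-word phrases 15% shorter,
#' and per-phrase pitch declining 15% with a reset peak at normalized time
#' 0.2.
#'
#' @param n_files,turns_per_file,speakers_per_file Corpus dimensions; turns
#'   alternate between the file's speakers.
#' @param phrases_per_turn_mean Mean phrases per turn (shifted Poisson,
#'   minimum 1).
#' @param words_per_phrase_mean Mean words per phrase; lengths are
#'   `1 + Geometric`, so the implied exponential tail of phrase durations
#'   has time constant `-middle_word_ms / log(1 - 1/mean) / 1000` seconds
#'   (0.72 s at the defaults).
#' @param middle_word_ms,middle_word_sd_ms,final_word_ms,final_word_sd_ms
#'   Lognormal word-duration moments (milliseconds).
#' @param first_word_shortening_frac Fractional shortening of the first word
#'   of phrases with at least 3 words.
#' @param middle_phone_ms,final_phone_ms Target phone durations driving the
#'   per-word phone count (clamped to 2-6 phones per word); final-word
#'   phones use the final target, putting the speech-rate slowdown on the
#'   whole last word.
#' @param pause_prob Probability of a silent pause at an internal phrase
#'   boundary; pause duration is `pause_min_s + Exp(pause_jitter_s)`.
#' @param pause_min_s,pause_jitter_s Boundary-pause duration parameters.
#' @param hesitation_prob,hesitation_min_s,hesitation_jitter_s Short
#'   within-phrase hesitation gaps (mostly below 300 ms), the noise floor
#'   for the pause rule.
#' @param finality_prob Probability that an internal phrase is a "final"
#'   unit (turn-final phrases always are).
#' @param finality_effect Multiplier on final-word lengthening for final
#'   units; values above 1 make final-unit boundaries more strongly marked.
#' @param pitch_base_range_hz Per-speaker baseline pitch drawn uniformly
#'   from this range.
#' @param decline_frac Fractional pitch decline across a phrase.
#' @param reset_peak_t Normalized time of the post-reset pitch peak.
#' @param pitch_dt_s,pitch_noise_frac Pitch sample spacing and multiplicative
#'   sample noise.
#' @param noise_frac Extra multiplicative timing jitter applied to every
#'   word duration (0 = the clean corpus).
#' @param unk_prob Probability that a word is an out-of-dictionary `<unk>`
#'   token carrying no phone timings.
#' @param inter_turn_gap_s Mean silent gap between consecutive turns.
#' @param lexicon Lexicon tibble as in [default_lexicon()].
#' @return A `proso_synth_config` list.
#' @export
synth_config <- function(n_files = 12L,
                         turns_per_file = 40L,
                         speakers_per_file = 2L,
                         phrases_per_turn_mean = 3,
                         words_per_phrase_mean = 4.1,
                         middle_word_ms = 201, middle_word_sd_ms = 7,
                         final_word_ms = 356, final_word_sd_ms = 28,
                         first_word_shortening_frac = 0.15,
                         middle_phone_ms = 74, final_phone_ms = 118,
                         pause_prob = 0.75,
                         pause_min_s = 0.35, pause_jitter_s = 0.25,
                         hesitation_prob = 0.08,
                         hesitation_min_s = 0.03, hesitation_jitter_s = 0.06,
                         finality_prob = 0.3,
                         finality_effect = 1.0,
                         pitch_base_range_hz = c(120, 220),
                         decline_frac = 0.15,
                         reset_peak_t = 0.2,
                         pitch_dt_s = 0.010,
                         pitch_noise_frac = 0.02,
                         noise_frac = 0,
                         unk_prob = 0,
                         inter_turn_gap_s = 1.0,
                         lexicon = default_lexicon()) {
  cfg <- as.list(environment())
  durs <- c(cfg$middle_word_ms, cfg$final_word_ms, cfg$middle_phone_ms,
            cfg$final_phone_ms)
  if (any(durs <= 0)) abort("all duration parameters must be positive")
  if (cfg$middle_phone_ms * 2 > cfg$middle_word_ms * 1.5 ||
      cfg$final_phone_ms * 2 > cfg$final_word_ms * 1.5) {
    abort("phone-duration targets exceed word durations; infeasible config")
  }
  if (!(cfg$decline_frac >= 0 && cfg$decline_frac < 1)) {
    abort("decline_frac must lie in [0, 1)")
  }
  if (cfg$words_per_phrase_mean <= 1) {
    abort("words_per_phrase_mean must exceed 1")
  }
  structure(cfg, class = "proso_synth_config")
}

# phone count targeting `target_s` mean phone duration, clamped to 2-6
n_phones_for <- function(dur_s, target_s) {
  pmin(6L, pmax(2L, as.integer(round(dur_s / target_s))))
}

# normalized pitch shape over u in [0,1]: reset rise to a peak at `peak`,
# then linear declination scaled so value at u = 0.9 is (1 - decline)
pitch_shape <- function(u, decline, peak) {
  low <- 1 - decline
  ifelse(u < peak,
         low + (u / peak) * decline,
         1 - decline * (u - peak) / (0.9 - peak))
}

synth_turn <- function(cfg, turn_start) {
  n_phr <- 1L + rpois(1, cfg$phrases_per_turn_mean - 1)
  n_words <- 1L + rgeom(n_phr, 1 / cfg$words_per_phrase_mean)
  finality <- ifelse(runif(n_phr) < cfg$finality_prob, "final", "non-final")
  finality[n_phr] <- "final"
  phrase_of <- rep(seq_len(n_phr), n_words)
  total <- sum(n_words)
  pos <- sequence(n_words)
  is_final_w <- pos == rep(n_words, n_words)
  # phrase-initial acceleration: every non-final first word of a multi-word
  # phrase is shortened and articulated faster
  is_first_w <- pos == 1L & rep(n_words, n_words) >= 2L
  final_mult <- ifelse(rep(finality, n_words) == "final", cfg$finality_effect, 1)

  dur <- rlnorm_ms(total, cfg$middle_word_ms / 1000, cfg$middle_word_sd_ms / 1000)
  fw <- which(is_final_w)
  dur[fw] <- rlnorm_ms(length(fw), cfg$final_word_ms / 1000,
                       cfg$final_word_sd_ms / 1000) * final_mult[fw]
  sw <- which(is_first_w & !is_final_w)
  dur[sw] <- rlnorm_ms(length(sw),
                       cfg$middle_word_ms * (1 - cfg$first_word_shortening_frac) / 1000,
                       cfg$middle_word_sd_ms / 1000)
  if (cfg$noise_frac > 0) {
    dur <- dur * exp(rnorm(total, 0, cfg$noise_frac))
  }

  # silent gaps after each word: boundary pauses / within-phrase hesitations
  gap <- numeric(total)
  phrase_end_w <- which(is_final_w & phrase_of < n_phr)
  pz <- phrase_end_w[runif(length(phrase_end_w)) < cfg$pause_prob]
  gap[pz] <- cfg$pause_min_s + rexp(length(pz), 1 / cfg$pause_jitter_s)
  within <- which(!is_final_w)
  hz <- within[runif(length(within)) < cfg$hesitation_prob]
  gap[hz] <- cfg$hesitation_min_s + rexp(length(hz), 1 / cfg$hesitation_jitter_s)

  word_start <- turn_start + c(0, cumsum(dur + gap))[seq_len(total)]
  word_end <- word_start + dur

  # labels: phrase-initial positions use the biased column
  lex <- cfg$lexicon
  label <- character(total)
  ini <- pos == 1L
  label[ini] <- sample(lex$word, sum(ini), replace = TRUE, prob = lex$w_initial)
  label[!ini] <- sample(lex$word, sum(!ini), replace = TRUE, prob = lex$w_other)
  unk <- runif(total) < cfg$unk_prob
  label[unk] <- "<unk>"

  # final lengthening lives on the whole last word's phones (scaled further
  # by the finality effect, so strongly marked boundaries articulate slower);
  # phrase-initial acceleration shortens the first word's phones by the same
  # fraction as the word itself
  target <- dplyr::case_when(
    is_final_w ~ cfg$final_phone_ms * final_mult,
    is_first_w ~ cfg$middle_phone_ms * (1 - cfg$first_word_shortening_frac),
    .default = cfg$middle_phone_ms
  ) / 1000
  n_ph <- n_phones_for(dur, target)
  n_ph[unk] <- 0L
  wrep <- rep(seq_len(total), pmax(n_ph, 1L))
  g <- rgamma(length(wrep), shape = 400)
  g_sum <- stats::ave(g, wrep, FUN = sum)
  ph_dur <- dur[wrep] * g / g_sum
  ph_end_rel <- stats::ave(ph_dur, wrep, FUN = cumsum)
  phones <- tibble(
    word_index = wrep,
    phone_label = ifelse(rep(n_ph, pmax(n_ph, 1L))[seq_along(wrep)] == 0,
                         NA_character_, "ph"),
    phone_start = word_start[wrep] + ph_end_rel - ph_dur,
    phone_end = word_start[wrep] + ph_end_rel
  )
  phones$phone_label[rep(unk, pmax(n_ph, 1L))] <- NA_character_
  phones$phone_start[is.na(phones$phone_label)] <- NA_real_
  phones$phone_end[is.na(phones$phone_label)] <- NA_real_

  words <- tibble(
    word_index = seq_len(total), word_label = label,
    word_start = word_start, word_end = word_end,
    phrase = phrase_of, position = pos
  )
  phrases <- words |>
    group_by(.data$phrase) |>
    summarise(start = min(.data$word_start), end = max(.data$word_end),
              n_words = n(), first_word_index = min(.data$word_index),
              last_word_index = max(.data$word_index), .groups = "drop") |>
    mutate(finality = finality)
  list(words = words, phones = phones, phrases = phrases,
       end = word_end[total])
}

#' Generate a synthetic conversation corpus with ground truth
#'
#' A pure function of `(config, seed)`: identical seeds give identical
#' corpora. Produces forced-alignment-style word/phone timings with
#' position-dependent durations, optional silent pauses at a fraction of the
#' true boundaries, short hesitation gaps, declining-and-resetting pitch per
#' phrase, position-biased word labels, and a ground-truth record of every
#' phrase with its finality label.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed for all of the generator's randomness.
#' @return A `proso_corpus` list: `alignment` (tibble, [alignment-format]),
#'   `reference` (ground-truth phrases: `file_id`, `speaker`, `turn_id`,
#'   `start`, `end`, `n_words`, `first_word_index`, `last_word_index`,
#'   `finality`), `boundaries` (true internal boundaries with the finality
#'   of the unit each one terminates), `pitch` (samples: `file_id`,
#'   `speaker`, `time`, `f0`), plus `config` and `seed`.
#' @export
synth_corpus <- function(config = synth_config(), seed = 1L) {
  if (!inherits(config, "proso_synth_config")) {
    abort("config must come from synth_config()")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  files <- purrr::map(seq_len(config$n_files), function(f) {
    file_id <- sprintf("f%02d", f)
    spk <- sprintf("%s_s%d", file_id, seq_len(config$speakers_per_file))
    base_hz <- runif(length(spk), config$pitch_base_range_hz[1],
                     config$pitch_base_range_hz[2])
    t <- 0
    al <- ref <- pit <- list()
    for (k in seq_len(config$turns_per_file)) {
      turn_id <- sprintf("t%03d", k)
      sp_i <- (k - 1L) %% length(spk) + 1L
      t <- t + rexp(1, 1 / config$inter_turn_gap_s)
      tr <- synth_turn(config, t)
      al[[k]] <- tr$words |>
        left_join(tr$phones, by = "word_index") |>
        mutate(file_id = file_id, turn_id = turn_id, speaker = spk[sp_i]) |>
        select(dplyr::all_of(alignment_cols))
      ref[[k]] <- tr$phrases |>
        mutate(file_id = file_id, turn_id = turn_id, speaker = spk[sp_i])
      pit[[k]] <- purrr::pmap_dfr(
        list(tr$phrases$start, tr$phrases$end),
        function(s, e) {
          tt <- seq(s, e, by = config$pitch_dt_s)
          u <- if (e > s) (tt - s) / (e - s) else rep(0, length(tt))
          f0 <- base_hz[sp_i] *
            pitch_shape(u, config$decline_frac, config$reset_peak_t) *
            exp(rnorm(length(tt), 0, config$pitch_noise_frac))
          tibble(time = tt, f0 = f0)
        }
      ) |>
        mutate(file_id = file_id, speaker = spk[sp_i]) |>
        select("file_id", "speaker", "time", "f0")
      t <- tr$end
    }
    list(alignment = bind_rows(al), reference = bind_rows(ref),
         pitch = bind_rows(pit))
  })

  alignment <- bind_rows(purrr::map(files, "alignment"))
  reference <- bind_rows(purrr::map(files, "reference")) |>
    select("file_id", "speaker", "turn_id", "start", "end", "n_words",
           "first_word_index", "last_word_index", "finality")
  # internal true boundaries: start of phrases 2..k of each turn, labelled
  # with the finality of the unit the boundary terminates
  boundaries <- reference |>
    group_by(.data$file_id, .data$turn_id) |>
    mutate(time = .data$start,
           word_index = .data$first_word_index,
           finality_of_terminated = lag(.data$finality)) |>
    filter(row_number() > 1) |>
    ungroup() |>
    select("file_id", "turn_id", "speaker", "word_index", "time",
           "finality_of_terminated")
  structure(
    list(alignment = alignment, reference = reference,
         boundaries = boundaries,
         pitch = bind_rows(purrr::map(files, "pitch")),
         config = config, seed = seed),
    class = "proso_corpus"
  )
}

#' @export
print.proso_corpus <- function(x, ...) {
  w <- align_words(x$alignment)
  cat("<synthetic conversation corpus>\n")
  cat(sprintf("  seed %d: %d files, %d turns, %d phrases, %d words\n",
              x$seed, length(unique(x$alignment$file_id)),
              nrow(distinct(w, .data$file_id, .data$turn_id)),
              nrow(x$reference), nrow(w)))
  invisible(x)
}

#' Write a synthetic corpus to plain-text files
#'
#' Emits `alignment.tsv`, `reference.tsv` (with finality labels) and
#' `pitch.tsv` into `dir`, plus `truth.json` holding the ground-truth
#' boundary list.
#'
#' @param corpus A `proso_corpus` from [synth_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_alignment_tsv(corpus$alignment, file.path(dir, "alignment.tsv"))
  corpus$reference |>
    select("file_id", "speaker", "start", "end", "finality") |>
    mutate(across(c("start", "end"), ~ round(.x, 3))) |>
    readr::write_tsv(file.path(dir, "reference.tsv"), progress = FALSE)
  corpus$pitch |>
    mutate(time = round(.data$time, 3), f0 = round(.data$f0, 2)) |>
    readr::write_tsv(file.path(dir, "pitch.tsv"), progress = FALSE)
  jsonlite::write_json(corpus$boundaries, file.path(dir, "truth.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
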