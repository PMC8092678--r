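# broom-style accessors for the package's result objects

#' @method tidy proso_eval
#' @export
tidy.proso_eval <- function(x, ...) x$metrics |> filter(.data$file_id != "(all)")

#' @method glance proso_eval
#' @export
glance.proso_eval <- function(x, ...) {
  x$metrics |> filter(.data$file_id == "(all)") |> select(-"file_id")
}

#' @method tidy proso_chisq
#' @export
tidy.proso_chisq <- function(x, ...) {
  obs <- x$observed
  exp <- x$expected
  rn <- rownames(obs) %||% as.character(seq_len(nrow(obs)))
  cn <- colnames(obs) %||% as.character(seq_len(ncol(obs)))
  tibble(
    row = rep(rn, times = ncol(obs)),
    col = rep(cn, each = nrow(obs)),
    observed = as.vector(obs),
    expected = as.vector(exp),
    contribution = as.vector((abs(obs - exp) - if (x$yates) 0.5 else 0)^2 / exp)
  )
}

#' @method glance proso_chisq
#' @export
glance.proso_chisq <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value, yates = x$yates)
}

#' @method tidy proso_finality
#' @export
tidy.proso_finality <- function(x, ...) x$recall

#' @method glance proso_finality
#' @export
glance.proso_finality <- function(x, ...) {
  tibble(
    recall_final = x$recall$recall[x$recall$finality == "final"],
    recall_non_final = x$recall$recall[x$recall$finality == "non-final"],
    chi2 = x$chisq$chi2, df = x$chisq$df, p_value = x$chisq$p_value
  )
}

#' @method tidy proso_pitch_summary
#' @export
tidy.proso_pitch_summary <- function(x, ...) x$curves

#' @method glance proso_pitch_summary
#' @export
glance.proso_pitch_summary <- function(x, ...) {
  out <- tibble(
    begin_mean = mean(x$by_file$begin_mean),
    end_mean = mean(x$by_file$end_mean),
    decline_frac = x$decline_frac_est,
    std_first = mean(x$by_file$std_first),
    std_end = mean(x$by_file$std_end),
    n_files = x$n_files, n_contours = x$n_contours
  )
  if (!is.null(x$tests)) {
    out$p_decline <- x$tests$p_value[1]
    out$p_end_variability <- x$tests$p_value[2]
  }
  out
}

#' @method tidy proso_phrasedist
#' @export
tidy.proso_phrasedist <- function(x, ...) x$durations

#' @method glance proso_phrasedist
#' @export
glance.proso_phrasedist <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble(tail_tau_s = x$fit$tau_s, tail_r2 = x$fit$r2,
                          tail_fit_ok = x$fit$ok))
}

#' @method tidy proso_posdur
#' @export
tidy.proso_posdur <- function(x, ...) {
  bind_rows(
    x$words |> mutate(level = "word", .before = 1),
    x$phones |> mutate(level = "phone", .before = 1)
  )
}

#' @method tidy proso_postable
#' @export
tidy.proso_postable <- function(x, ...) x$table

#' @method tidy proso_detection
#' @export
tidy.proso_detection <- function(x, ...) x$boundaries

#' @method glance proso_detection
#' @export
glance.proso_detection <- function(x, ...) {
  incl <- x$phrases |> filter(!.data$excluded)
  tibble(
    n_boundaries = nrow(x$boundaries),
    n_dsr_pass1 = sum(x$boundaries$source == "dsr_pass1"),
    n_dsr_pass2 = sum(x$boundaries$source == "dsr_pass2"),
    n_pause = sum(x$boundaries$source == "pause"),
    n_phrases = nrow(x$phrases),
    n_turns = nrow(distinct(x$phrases, .data$file_id, .data$turn_id)),
    mean_words_per_phrase = mean(incl$n_words),
    mean_phrase_duration_s = mean(incl$duration_s)
  )
}
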