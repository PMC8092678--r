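# ggplot2 views of the analysis results

#' Speech rate and boundaries of one turn
#'
#' @param detection A `proso_detection`.
#' @param file_id,turn_id Which turn to draw (defaults to the first turn
#'   with boundaries).
#' @return A ggplot: per-word-onset speech rate over time, with detected
#'   boundaries as vertical lines coloured by source.
#' @export
plot_speech_rate <- function(detection, file_id = NULL, turn_id = NULL) {
  r <- detection$rates
  if (is.null(file_id)) {
    b1 <- detection$boundaries[1, ]
    file_id <- b1$file_id
    turn_id <- b1$turn_id
  }
  fid <- file_id; tid <- turn_id
  r <- r |> filter(.data$file_id == fid, .data$turn_id == tid)
  b <- detection$boundaries |>
    filter(.data$file_id == fid, .data$turn_id == tid)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$onset, y = .data$rate)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$defined)) +
    ggplot2::geom_vline(data = b,
                        ggplot2::aes(xintercept = .data$time,
                                     colour = .data$source),
                        linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "speech rate (1/s)",
                  title = sprintf("%s / %s", fid, tid),
                  colour = "boundary source") +
    ggplot2::guides(shape = "none") +
    ggplot2::theme_minimal()
}

#' @method autoplot proso_detection
#' @export
autoplot.proso_detection <- function(object, ...) plot_speech_rate(object, ...)

#' Duration profiles by position from the phrase end
#'
#' @param object A `proso_posdur` from [duration_by_position()].
#' @param ... Unused.
#' @return A ggplot of mean word and phone durations (with s.e.m. bars)
#'   against position counted from the phrase end, last position first.
#' @method autoplot proso_posdur
#' @export
autoplot.proso_posdur <- function(object, ...) {
  d <- tidy.proso_posdur(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position_from_end,
                                  y = 1000 * .data$mean_s)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 1000 * (.data$mean_s - .data$sem_s),
      ymax = 1000 * (.data$mean_s + .data$sem_s)), width = 0.2) +
    ggplot2::scale_x_reverse() +
    ggplot2::facet_wrap(~ .data$level, scales = "free") +
    ggplot2::labs(x = "position from phrase end", y = "duration (ms)") +
    ggplot2::theme_minimal()
}

#' Phrase duration histogram with exponential tail
#'
#' @param object A `proso_phrasedist`.
#' @param ... Unused.
#' @return A ggplot of binned phrase-duration counts on a log scale, with
#'   the fitted exponential tail overlaid when available.
#' @method autoplot proso_phrasedist
#' @export
autoplot.proso_phrasedist <- function(object, ...) {
  d <- object$durations |> filter(.data$count > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid_s, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "phrase duration (s)", y = "count") +
    ggplot2::theme_minimal()
  if (isTRUE(object$fit$ok)) {
    tail_d <- d |> filter(.data$mid_s >= min(.data$mid_s))
    x0 <- d$mid_s[which.max(d$mid_s >= 1.0)]
    y0 <- d$count[which.max(d$mid_s >= 1.0)]
    p <- p + ggplot2::geom_function(
      fun = function(x) y0 * exp(-(x - x0) / object$fit$tau_s),
      linetype = 2, colour = "firebrick"
    ) +
      ggplot2::labs(subtitle = sprintf("tail time constant %.2f s (R2 %.3f)",
                                       object$fit$tau_s, object$fit$r2))
  }
  p
}

#' Normalized pitch contour summary
#'
#' @param object A `proso_pitch_summary`.
#' @param ... Unused.
#' @return A ggplot with the grand mean contour and the across-phrase
#'   standard deviation against normalized time.
#' @method autoplot proso_pitch_summary
#' @export
autoplot.proso_pitch_summary <- function(object, ...) {
  d <- object$curves |>
    tidyr::pivot_longer(c("mean", "std"), names_to = "statistic")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$statistic, scales = "free_y") +
    ggplot2::labs(x = "normalized time", y = "normalized pitch") +
    ggplot2::theme_minimal()
}

#' Pause-threshold precision sweep
#'
#' @param object A `proso_sweep` from [pause_threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean precision (with s.e.m. ribbon) against the
#'   pause threshold; the pauses-off condition appears as a dashed
#'   horizontal line.
#' @method autoplot proso_sweep
#' @export
autoplot.proso_sweep <- function(object, ...) {
  fin <- object |> filter(is.finite(.data$min_pause_s))
  inf <- object |> filter(is.infinite(.data$min_pause_s))
  p <- ggplot2::ggplot(fin, ggplot2::aes(x = 1000 * .data$min_pause_s,
                                         y = .data$precision_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$precision_mean - .data$precision_sem,
      ymax = .data$precision_mean + .data$precision_sem),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "minimal pause duration (ms)", y = "precision") +
    ggplot2::theme_minimal()
  if (nrow(inf) == 1) {
    p <- p + ggplot2::geom_hline(yintercept = inf$precision_mean,
                                 linetype = 2, colour = "grey40")
  }
  p
}

#' Positional word-frequency rank curves
#'
#' @param object A `proso_postable`.
#' @param top_m Ranks to display.
#' @param ... Unused.
#' @return A ggplot of word probability against rank, one line per phrase
#'   position, with group s.e.m. error bars.
#' @method autoplot proso_postable
#' @export
autoplot.proso_postable <- function(object, top_m = 5L, ...) {
  d <- object$groups |>
    filter(.data$rank <= top_m) |>
    mutate(position = factor(.data$position))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = 100 * .data$prob_mean,
                                  colour = .data$position)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = 100 * (.data$prob_mean - .data$prob_sem),
      ymax = 100 * (.data$prob_mean + .data$prob_sem))) +
    ggplot2::labs(x = "word rank within position", y = "probability (%)",
                  colour = "position") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
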