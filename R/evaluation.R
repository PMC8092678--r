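#' Word-onset evaluation slots
#'
#' The evaluation universe: one binary slot per onset of words 2..n of every
#' multi-word turn. The slot before a turn's first word is excluded (a turn
#' start is trivially a boundary), which also removes every slot that
#' follows a speaker change.
#'
#' @param alignment An alignment tibble.
#' @return Tibble of slots: `file_id`, `turn_id`, `speaker`, `word_index`,
#'   `onset`.
#' @export
boundary_slots <- function(alignment) {
  align_words(alignment) |>
    group_by(.data$file_id, .data$turn_id) |>
    filter(n() >= 2, row_number() > 1) |>
    ungroup() |>
    select("file_id", "turn_id", "speaker", "word_index", onset = "word_start")
}

# Map reference phrase-start times onto slots: greedy nearest-first matching
# within +/- tolerance, each slot and each reference boundary matched at most
# once, distance ties broken toward the earlier reference boundary. Phrase
# starts that match no slot lie outside the evaluation universe (they are
# turn starts, or fall where the detector cannot place a boundary) and are
# dropped; their count is returned for diagnostics.
match_reference <- function(slots, reference, tolerance_s) {
  if (tolerance_s < 0) abort("tolerance_s must be non-negative")
  ref_b <- reference |>
    select("file_id", "speaker", time = "start") |>
    arrange(.data$file_id, .data$speaker, .data$time)
  slots$ref <- FALSE
  outside <- 0L
  key_s <- paste(slots$file_id, slots$speaker)
  key_r <- paste(ref_b$file_id, ref_b$speaker)
  for (g in unique(key_s)) {
    s_i <- which(key_s == g)
    r_t <- ref_b$time[key_r == g]
    if (length(r_t) == 0) next
    cand <- tidyr::expand_grid(ri = seq_along(r_t), si = seq_along(s_i)) |>
      mutate(d = abs(r_t[.data$ri] - slots$onset[s_i][.data$si])) |>
      filter(.data$d <= tolerance_s) |>
      arrange(.data$d, .data$ri)
    used_r <- logical(length(r_t))
    used_s <- logical(length(s_i))
    for (j in seq_len(nrow(cand))) {
      ri <- cand$ri[j]; si <- cand$si[j]
      if (used_r[ri] || used_s[si]) next
      used_r[ri] <- TRUE
      used_s[si] <- TRUE
      slots$ref[s_i[si]] <- TRUE
    }
    outside <- outside + sum(!used_r)
  }
  list(slots = slots, n_ref_outside = outside)
}

#' Score automatic boundaries against a reference segmentation
#'
#' Confusion counts over word-onset slots: a slot is a true positive when
#' both the detector and the reference place a boundary there (reference
#' boundary times are matched to slots within `tolerance_s`, greedy
#' nearest-first, one slot per reference boundary), a false positive when
#' only the detector does, a false negative when only the reference does,
#' and a true negative otherwise.
#'
#' @param auto Boundary tibble (`file_id`, `turn_id`, `word_index`, ...) —
#'   e.g. `detect_boundaries()$boundaries` — or a `proso_detection`.
#' @param reference Reference phrases (`file_id`, `speaker`, `start`,
#'   `end`, ...), e.g. from [read_reference_tsv()] or a synthetic corpus.
#' @param alignment The alignment both segmentations refer to.
#' @param tolerance_s Matching window in seconds (aligner resolution is
#'   10 ms; the default allows 50 ms of slack).
#' @param multi_unit_only Score only turns where the reference itself holds
#'   at least two units, the protocol under which the method was designed
#'   (single-unit turns were excluded from its evaluation); set `FALSE` to
#'   score every multi-word turn.
#' @return A `proso_confusion`: tibble of per-file counts `tp`, `fp`, `fn`,
#'   `tn`, `n_slots` with the overall row marked `file_id = "(all)"`.
#' @export
align_boundaries <- function(auto, reference, alignment, tolerance_s = 0.05,
                             multi_unit_only = TRUE) {
  if (inherits(auto, "proso_detection")) auto <- auto$boundaries
  slots <- boundary_slots(alignment)
  if (multi_unit_only) {
    # a turn is multi-unit when >= 2 reference phrases start within its span
    spans <- align_words(alignment) |>
      group_by(.data$file_id, .data$turn_id, .data$speaker) |>
      summarise(t0 = min(.data$word_start), t1 = max(.data$word_end),
                .groups = "drop")
    n_units <- purrr::map_int(seq_len(nrow(spans)), function(i) {
      sum(reference$file_id == spans$file_id[i] &
            reference$speaker == spans$speaker[i] &
            reference$start >= spans$t0[i] - 1e-3 &
            reference$start < spans$t1[i])
    })
    keep <- spans[n_units >= 2, c("file_id", "turn_id")]
    slots <- slots |> semi_join(keep, by = c("file_id", "turn_id"))
  }
  m <- match_reference(slots, reference, tolerance_s)
  slots <- m$slots
  slots <- slots |>
    left_join(
      auto |> distinct(.data$file_id, .data$turn_id, .data$word_index) |>
        mutate(auto = TRUE),
      by = c("file_id", "turn_id", "word_index")
    ) |>
    mutate(auto = !is.na(.data$auto))
  per_file <- slots |>
    group_by(.data$file_id) |>
    summarise(
      tp = sum(.data$auto & .data$ref),
      fp = sum(.data$auto & !.data$ref),
      fn = sum(!.data$auto & .data$ref),
      tn = sum(!.data$auto & !.data$ref),
      n_slots = n(),
      .groups = "drop"
    )
  overall <- per_file |>
    summarise(file_id = "(all)", across(c("tp", "fp", "fn", "tn", "n_slots"), sum))
  out <- bind_rows(overall, per_file)
  attr(out, "n_ref_outside") <- m$n_ref_outside
  structure(out, class = c("proso_confusion", class(per_file)))
}

#' Agreement metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F-score `2pr/(p+r)` (zero
#' when `p + r = 0`), accuracy `(TP+TN)/(TP+FP+FN+TN)`, and Cohen's kappa on
#' the binary slot labels (observed agreement against chance agreement from
#' the marginals).
#'
#' @param counts A `proso_confusion`, or anything with numeric `tp`, `fp`,
#'   `fn`, `tn` columns (overall rows marked `file_id = "(all)"` are used),
#'   or a named vector/list with those fields.
#' @return A one-row tibble: `precision`, `recall`, `f_score`, `accuracy`,
#'   `kappa`, plus the four counts.
#' @export
compute_metrics <- function(counts) {
  if (is.data.frame(counts)) {
    row <- if ("file_id" %in% names(counts) && "(all)" %in% counts$file_id) {
      counts[counts$file_id == "(all)", ][1, ]
    } else {
      counts |> summarise(across(c("tp", "fp", "fn", "tn"), sum))
    }
    counts <- as.list(row)
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) abort("confusion counts must be non-negative")
  total <- tp + fp + fn + tn
  if (total == 0) abort("all confusion counts are zero; metrics undefined")
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else 0
  ac <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe < 1) (ac - pe) / (1 - pe) else 1
  tibble(precision = p, recall = r, f_score = f, accuracy = ac, kappa = kappa,
         tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Evaluate a detection end to end
#'
#' [align_boundaries()] followed by [compute_metrics()], overall and per
#' file.
#'
#' @inheritParams align_boundaries
#' @return A `proso_eval` with `$counts` and `$metrics` (first row overall).
#' @export
evaluate_boundaries <- function(auto, reference, alignment,
                                tolerance_s = 0.05, multi_unit_only = TRUE) {
  counts <- align_boundaries(auto, reference, alignment, tolerance_s,
                             multi_unit_only)
  metrics <- counts |>
    group_by(.data$file_id) |>
    group_split() |>
    purrr::map_dfr(~ mutate(compute_metrics(as.list(.x[1, ])),
                            file_id = .x$file_id[1], .before = 1))
  metrics <- metrics[order(metrics$file_id != "(all)"), ]
  structure(list(counts = counts, metrics = metrics,
                 tolerance_s = tolerance_s),
            class = "proso_eval")
}

#' @export
print.proso_eval <- function(x, ...) {
  m <- x$metrics[x$metrics$file_id == "(all)", ]
  cat("<boundary agreement>\n")
  cat(sprintf("  slots: %d | tp %d fp %d fn %d tn %d\n",
              m$tp + m$fp + m$fn + m$tn, m$tp, m$fp, m$fn, m$tn))
  cat(sprintf("  precision %.3f | recall %.3f | F %.3f | accuracy %.3f | kappa %.3f\n",
              m$precision, m$recall, m$f_score, m$accuracy, m$kappa))
  invisible(x)
}

#' Chi-square test of independence with expected counts
#'
#' Pearson's chi-square on a two-way contingency table, with the Yates
#' continuity correction available for 2x2 tables. Exposes the expected
#' counts (`row total x column total / grand total`) alongside the
#' statistic.
#'
#' @param observed Numeric matrix (or table) of non-negative counts with at
#'   least two rows and columns.
#' @param yates Apply the Yates correction (2x2 tables only).
#' @return A `proso_chisq`: list with `chi2`, `df`, `p_value`, `expected`,
#'   `observed`, `yates`.
#' @export
chi_square_independence <- function(observed, yates = FALSE) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(!is.finite(observed))) {
    abort("observed counts must be finite and non-negative")
  }
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    abort("need at least a 2x2 table")
  }
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    abort("zero marginal total; expected counts undefined")
  }
  if (yates && !(nrow(observed) == 2 && ncol(observed) == 2)) {
    warn("Yates correction applies to 2x2 tables only; ignored")
    yates <- FALSE
  }
  ht <- suppressWarnings(chisq.test(observed, correct = yates))
  structure(
    list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, expected = unclass(ht$expected),
         observed = observed, yates = yates),
    class = "proso_chisq"
  )
}

#' @export
print.proso_chisq <- function(x, ...) {
  cat(sprintf("chi-square(%d%s) = %.2f, p = %.3g\n", x$df,
              if (x$yates) ", Yates" else "", x$chi2, x$p_value))
  invisible(x)
}

#' Precision as a function of the minimal pause duration
#'
#' Re-runs the full detector for each pause threshold in `grid` and reports
#' the mean per-file precision against the reference, plus the pauses-off
#' condition (reported as `min_pause_s = Inf`).
#'
#' @inheritParams align_boundaries
#' @param grid Numeric vector of pause thresholds in seconds.
#' @param config Base [detector_config()]; only the pause settings vary.
#' @return A `proso_sweep` tibble: `min_pause_s`, `precision_mean`,
#'   `precision_sem`, `n_files`.
#' @export
pause_threshold_sweep <- function(alignment, reference,
                                  grid = seq(0.1, 1.9, by = 0.1),
                                  config = detector_config(),
                                  tolerance_s = 0.05, multi_unit_only = TRUE) {
  if (length(grid) == 0) abort("grid must be non-empty")
  one <- function(min_pause_s) {
    cfg <- config
    if (is.infinite(min_pause_s)) {
      cfg$use_pauses <- FALSE
    } else {
      cfg$min_pause_s <- min_pause_s
      cfg$use_pauses <- TRUE
    }
    det <- suppressWarnings(detect_boundaries(alignment, cfg))
    counts <- align_boundaries(det, reference, alignment, tolerance_s,
                               multi_unit_only)
    per_file <- counts |>
      filter(.data$file_id != "(all)") |>
      mutate(precision = ifelse(.data$tp + .data$fp > 0,
                                .data$tp / (.data$tp + .data$fp), NA_real_))
    tibble(min_pause_s = min_pause_s,
           precision_mean = mean(per_file$precision, na.rm = TRUE),
           precision_sem = sem(per_file$precision),
           n_files = sum(!is.na(per_file$precision)))
  }
  out <- purrr::map_dfr(c(sort(grid), Inf), one)
  structure(out, class = c("proso_sweep", class(out)))
}

#' Recall by finality of the terminated unit
#'
#' Splits the reference's internal boundaries by the finality label of the
#' unit each boundary terminates, reports recall for final vs non-final
#' units, and tests the detected/missed x final/non-final table with a
#' Yates-corrected chi-square. Units followed by a speaker change carry no
#' internal boundary and are excluded by construction.
#'
#' @inheritParams align_boundaries
#' @return A `proso_finality`: list with `recall` (tibble per finality
#'   class) and `chisq` (a `proso_chisq`).
#' @export
finality_recall <- function(auto, reference, alignment, tolerance_s = 0.05) {
  if (inherits(auto, "proso_detection")) auto <- auto$boundaries
  if (!"finality" %in% names(reference) ||
      all(reference$finality %in% c("unknown", NA))) {
    abort("reference carries no finality labels; finality recall undefined")
  }
  slots <- boundary_slots(alignment) |>
    left_join(
      auto |> distinct(.data$file_id, .data$turn_id, .data$word_index) |>
        mutate(auto = TRUE),
      by = c("file_id", "turn_id", "word_index")
    ) |>
    mutate(auto = !is.na(.data$auto))
  # internal boundary j terminates phrase j; label it with that finality
  ref_b <- reference |>
    group_by(.data$file_id, .data$speaker) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(finality_of_terminated = lag(.data$finality)) |>
    filter(row_number() > 1) |>
    ungroup() |>
    select("file_id", "speaker", time = "start", "finality_of_terminated")
  hits <- ref_b |>
    left_join(slots, by = c("file_id", "speaker"),
              relationship = "many-to-many") |>
    mutate(d = abs(.data$time - .data$onset)) |>
    filter(.data$d <= tolerance_s) |>
    group_by(.data$file_id, .data$speaker, .data$time) |>
    slice(which.min(.data$d)) |>
    ungroup() |>
    select("file_id", "speaker", "time", detected = "auto")
  scored <- ref_b |>
    left_join(hits, by = c("file_id", "speaker", "time")) |>
    filter(!is.na(.data$detected)) |>      # boundaries outside the slot universe drop out
    filter(.data$finality_of_terminated %in% c("final", "non-final"))
  recall <- scored |>
    group_by(finality = .data$finality_of_terminated) |>
    summarise(n_units = n(), recall = mean(.data$detected),
              detected = sum(.data$detected), .groups = "drop")
  if (nrow(recall) < 2) {
    abort(sprintf(
      "only one finality class present (%s, recall %.3f); chi-square undefined",
      recall$finality[1], recall$recall[1]))
  }
  tab <- as.matrix(recall[, c("detected", "n_units")])
  tab[, 2] <- tab[, 2] - tab[, 1]
  dimnames(tab) <- list(recall$finality, c("detected", "missed"))
  structure(list(recall = recall,
                 chisq = chi_square_independence(tab, yates = TRUE)),
            class = "proso_finality")
}

#' @export
print.proso_finality <- function(x, ...) {
  cat("<recall by finality of the terminated unit>\n")
  for (i in seq_len(nrow(x$recall))) {
    cat(sprintf("  %-9s %5.1f%%  (%d/%d)\n", x$recall$finality[i],
                100 * x$recall$recall[i], x$recall$detected[i],
                x$recall$n_units[i]))
  }
  print(x$chisq)
  invisible(x)
}
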