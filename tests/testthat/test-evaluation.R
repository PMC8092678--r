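test_that("identical boundary sets score perfectly", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 15), seed = 4)
  ev <- evaluate_boundaries(corp$boundaries, corp$reference, corp$alignment)
  m <- glance(ev)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f_score, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$kappa, 1)
})

test_that("an empty automatic set yields only misses", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 15), seed = 4)
  empty <- corp$boundaries[0, ]
  counts <- align_boundaries(empty, corp$reference, corp$alignment)
  all_row <- counts[counts$file_id == "(all)", ]
  expect_equal(all_row$tp, 0L)
  expect_equal(all_row$fp, 0L)
  expect_gt(all_row$fn, 0)
  # every scored slot is accounted for
  expect_equal(all_row$tp + all_row$fp + all_row$fn + all_row$tn,
               all_row$n_slots)
})

test_that("slot matching agrees with a nearest-first oracle under jitter", {
  set.seed(77)
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 30), seed = 9)
  slots <- boundary_slots(corp$alignment)
  # jitter true boundary times so some fall outside the 50 ms tolerance
  ref <- corp$reference
  jit <- runif(nrow(ref), -0.08, 0.08)
  ref$start <- ref$start + jit
  auto <- slots |> dplyr::slice_sample(prop = 0.3) |>
    dplyr::select(file_id, turn_id, speaker, word_index)
  counts <- align_boundaries(auto, ref, corp$alignment, tolerance_s = 0.05,
                             multi_unit_only = FALSE)
  # oracle: mark slots stream by stream
  marked <- logical(nrow(slots))
  for (g in unique(paste(slots$file_id, slots$speaker))) {
    si <- which(paste(slots$file_id, slots$speaker) == g)
    rt <- ref$start[paste(ref$file_id, ref$speaker) == g]
    marked[si] <- oracle_mark_slots(slots$onset[si], rt, 0.05)
  }
  is_auto <- paste(slots$file_id, slots$turn_id, slots$word_index) %in%
    paste(auto$file_id, auto$turn_id, auto$word_index)
  all_row <- counts[counts$file_id == "(all)", ]
  expect_equal(all_row$tp, sum(is_auto & marked))
  expect_equal(all_row$fp, sum(is_auto & !marked))
  expect_equal(all_row$fn, sum(!is_auto & marked))
  expect_equal(all_row$tn, sum(!is_auto & !marked))
})

test_that("scoring is invariant to the input row order", {
  corp <- synth_corpus(synth_config(n_files = 1, turns_per_file = 15), seed = 6)
  det <- suppressWarnings(detect_boundaries(corp$alignment))
  ev1 <- evaluate_boundaries(det$boundaries, corp$reference, corp$alignment)
  shuf <- function(df) df[sample(nrow(df)), ]
  set.seed(1)
  ev2 <- evaluate_boundaries(shuf(det$boundaries), shuf(corp$reference),
                             corp$alignment)
  expect_equal(glance(ev1), glance(ev2))
})

test_that("agreement metrics follow their defining formulas", {
  # totals of the published genre table: accuracy from the printed cells
  m <- compute_metrics(list(tp = 21144, fp = 15847, fn = 15974, tn = 130224))
  expect_equal(m$accuracy, 0.826, tolerance = 0.001)
  expect_equal(m$precision, 21144 / (21144 + 15847), tolerance = 1e-12)
  expect_equal(m$recall, 21144 / (21144 + 15974), tolerance = 1e-12)
  expect_equal(m$f_score,
               2 * m$precision * m$recall / (m$precision + m$recall))
  expect_error(compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "metrics undefined")
  expect_equal(compute_metrics(list(tp = 50, fp = 0, fn = 0, tn = 50))$kappa, 1)
})

test_that("kappa is near zero for independent labels", {
  set.seed(7)
  n <- 1e4
  auto <- runif(n) < 0.2
  ref <- runif(n) < 0.25
  m <- compute_metrics(list(
    tp = sum(auto & ref), fp = sum(auto & !ref),
    fn = sum(!auto & ref), tn = sum(!auto & !ref)
  ))
  expect_lt(abs(m$kappa), 0.03)
})

test_that("chi-square matches the textbook formula on random tables", {
  set.seed(42)
  for (k in 1:25) {
    tab <- matrix(rpois(9, 40) + 1, 3, 3)
    res <- chi_square_independence(tab)
    expect_equal(res$chi2, oracle_chisq(tab), tolerance = 1e-10)
    expect_equal(res$df, 4)
    # expected table preserves the observed margins
    expect_lt(max(abs(rowSums(res$expected) - rowSums(tab))), 1e-6)
    expect_lt(max(abs(colSums(res$expected) - colSums(tab))), 1e-6)
  }
  uni <- matrix(c(10, 10, 10, 10), 2, 2)
  expect_equal(chi_square_independence(uni)$chi2, 0)
  y <- matrix(c(30, 10, 12, 28), 2, 2)
  expect_equal(chi_square_independence(y, yates = TRUE)$chi2,
               oracle_chisq(y, yates = TRUE), tolerance = 1e-10)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2)),
               "zero marginal")
  expect_warning(chi_square_independence(matrix(1:9 + 10, 3, 3), yates = TRUE),
                 "2x2")
})

test_that("the pause sweep reaches the pauses-off precision at infinity", {
  corp <- synth_corpus(synth_config(n_files = 2, turns_per_file = 15), seed = 21)
  sw <- pause_threshold_sweep(corp$alignment, corp$reference, grid = c(0.3))
  expect_equal(nrow(sw), 2)
  # the infinite-threshold entry equals an explicit pauses-off run
  off <- suppressWarnings(detect_boundaries(
    corp$alignment, detector_config(use_pauses = FALSE)))
  counts <- align_boundaries(off, corp$reference, corp$alignment)
  per_file <- counts |>
    dplyr::filter(file_id != "(all)") |>
    dplyr::mutate(precision = tp / (tp + fp))
  inf_row <- sw[is.infinite(sw$min_pause_s), ]
  expect_equal(inf_row$precision_mean, mean(per_file$precision),
               tolerance = 1e-12)
  # a single grid value reproduces an independent full run at that threshold
  d03 <- suppressWarnings(detect_boundaries(
    corp$alignment, detector_config(min_pause_s = 0.3)))
  c03 <- align_boundaries(d03, corp$reference, corp$alignment) |>
    dplyr::filter(file_id != "(all)") |>
    dplyr::mutate(precision = tp / (tp + fp))
  expect_equal(sw$precision_mean[1], mean(c03$precision), tolerance = 1e-12)
})

test_that("precision peaks near the true boundary-pause duration", {
  cfgs <- synth_config(n_files = 2, turns_per_file = 30, pause_prob = 0.9,
                       pause_min_s = 0.35, pause_jitter_s = 0.01,
                       hesitation_prob = 0.2)
  corp <- synth_corpus(cfgs, seed = 13)
  sw <- pause_threshold_sweep(corp$alignment, corp$reference,
                              grid = c(0.10, 0.20, 0.30, 0.90))
  fin <- sw[is.finite(sw$min_pause_s), ]
  best <- fin$min_pause_s[which.max(fin$precision_mean)]
  expect_true(best %in% c(0.20, 0.30))  # just below the 0.35 s true pauses
  expect_gt(fin$precision_mean[fin$min_pause_s == 0.30],
            fin$precision_mean[fin$min_pause_s == 0.10])
})

test_that("finality recall separates strongly and weakly marked units", {
  cfgs <- synth_config(n_files = 3, turns_per_file = 30,
                       finality_effect = 1.35, pause_prob = 0.3)
  corp <- synth_corpus(cfgs, seed = 19)
  det <- suppressWarnings(detect_boundaries(corp$alignment))
  fr <- finality_recall(det, corp$reference, corp$alignment)
  g <- glance(fr)
  expect_gt(g$recall_final, g$recall_non_final)
  # the embedded 2x2 test agrees with a direct chi-square call
  tab <- cbind(fr$recall$detected, fr$recall$n_units - fr$recall$detected)
  expect_equal(fr$chisq$chi2, chi_square_independence(tab, yates = TRUE)$chi2)

  # a reference without labels, or with a single class, cannot be scored
  ref_u <- corp$reference |> dplyr::mutate(finality = "unknown")
  expect_error(finality_recall(det, ref_u, corp$alignment), "no finality")
  ref_f <- corp$reference |> dplyr::mutate(finality = "final")
  expect_error(finality_recall(det, ref_f, corp$alignment),
               "only one finality class")
})
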