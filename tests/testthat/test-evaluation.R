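ann <- function(id, prim = character(0), size = character(0),
                meta = character(0)) {
  tibble::tibble(id = id, primary_sites = list(prim),
                 primary_sizes = list(size), metastatic_sites = list(meta))
}

test_that("entity-level counts and metrics follow the set definitions", {
  pred <- ann("d", prim = c("A", "B", "C"))
  gold <- ann("d", prim = c("A", "B", "D"))
  r <- score_task(pred, gold, "primary_sites")
  expect_equal(r$tp, 2L); expect_equal(r$fp, 1L); expect_equal(r$fn, 1L)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)

  # identity
  r2 <- score_task(gold, gold, "primary_sites")
  expect_equal(c(r2$precision, r2$recall, r2$f1), c(1, 1, 1))

  # empty prediction vs non-empty gold
  r3 <- score_task(ann("d"), gold, "primary_sites")
  expect_equal(c(r3$precision, r3$recall, r3$f1), c(0, 0, 0))

  # both empty everywhere: vacuous perfection
  r4 <- score_task(ann("d"), ann("d"), "primary_sites")
  expect_equal(c(r4$precision, r4$recall, r4$f1), c(1, 1, 1))
})

test_that("id mismatches are rejected", {
  expect_error(score_task(ann("a"), ann("b"), "primary_sites"), "ids differ")
})

test_that("scoring is invariant to document order and duplicates collapse", {
  pred <- dplyr::bind_rows(ann("1", prim = "X"), ann("2", prim = c("Y", "Y")))
  gold <- dplyr::bind_rows(ann("1", prim = "X"), ann("2", prim = "Z"))
  r_fwd <- score_task(pred, gold, "primary_sites")
  r_rev <- score_task(pred[2:1, ], gold, "primary_sites")
  expect_equal(r_fwd, r_rev)
  expect_equal(r_fwd$fp, 1L)  # duplicate Y counts once
})

test_that("adding predictions moves precision and recall the right way", {
  gold <- ann("d", prim = c("A", "B"))
  base <- score_task(ann("d", prim = "A"), gold, "primary_sites")
  more_correct <- score_task(ann("d", prim = c("A", "B")), gold,
                             "primary_sites")
  more_wrong <- score_task(ann("d", prim = c("A", "Q")), gold,
                           "primary_sites")
  expect_gte(more_correct$recall, base$recall)
  expect_lte(more_wrong$precision, base$precision)
})

test_that("weighted overall combines task metrics with 0.2/0.3/0.5", {
  mk <- function(p, r, f, tp = 1L, fp = 1L, fn = 1L) {
    tibble::tibble(task = "t", tp = tp, fp = fp, fn = fn,
                   precision = p, recall = r, f1 = f)
  }
  res <- dplyr::bind_rows(mk(1, 1, 1), mk(0, 0, 0), mk(0, 0, 0))
  ov <- weighted_overall(res)
  expect_equal(ov$f1, 0.2)

  perfect <- dplyr::bind_rows(mk(1, 1, 1, tp = 5L, fp = 0L, fn = 0L),
                              mk(1, 1, 1, tp = 3L, fp = 0L, fn = 0L),
                              mk(1, 1, 1, tp = 8L, fp = 0L, fn = 0L))
  expect_equal(weighted_overall(perfect, mode = "metric")$f1, 1)
  expect_equal(weighted_overall(perfect, mode = "count")$f1, 1)

  half <- dplyr::bind_rows(mk(0.5, 0.5, 0.5), mk(0.5, 0.5, 0.5),
                           mk(0.5, 0.5, 0.5))
  expect_equal(weighted_overall(half)$f1, 0.5)

  expect_error(weighted_overall(res, weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("F1 harmonic identity holds on every emitted result row", {
  pred <- dplyr::bind_rows(ann("1", prim = "A", meta = c("M", "N")),
                           ann("2", size = "5CM", meta = "M"))
  gold <- dplyr::bind_rows(ann("1", prim = "A", meta = "M"),
                           ann("2", size = "4CM", meta = c("M", "K")))
  ev <- evaluate_predictions(pred, gold)
  per <- tidy(ev)
  for (i in seq_len(nrow(per))) {
    p <- per$precision[i]; r <- per$recall[i]
    expect_equal(per$f1[i], if (p + r > 0) 2 * p * r / (p + r) else 0)
    if (per$tp[i] + per$fp[i] > 0) {
      expect_equal(p, per$tp[i] / (per$tp[i] + per$fp[i]))
    }
  }
  expect_s3_class(glance(ev), "tbl_df")
})

test_that("robustness curve is reproducible and degenerate at full size", {
  corp <- generate_corpus(generator_config(n_docs = 30, seed = 3))
  pred <- corp$gold  # perfect predictions suffice for the mechanics
  pred$primary_sites[[1]] <- character(0)  # introduce one error
  curve <- robustness_curve(pred, corp$gold, sizes = c(10, 30), repeats = 5,
                            seed = 11)
  expect_s3_class(curve, "onco_robustness")
  full <- curve[curve$size == 30, ]
  expect_true(all(full$sd == 0))  # every draw is the whole corpus

  curve2 <- robustness_curve(pred, corp$gold, sizes = c(10, 30), repeats = 5,
                             seed = 11)
  expect_equal(curve, curve2)

  one <- robustness_curve(pred, corp$gold, sizes = 10, repeats = 1, seed = 2)
  expect_true(all(one$sd == 0))

  expect_error(robustness_curve(pred, corp$gold, sizes = 31), "exceeds")

  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
})

test_that("macro averaging differs from micro when documents are unbalanced", {
  pred <- dplyr::bind_rows(ann("1", prim = "A"),
                           ann("2", prim = c("B", "C", "D", "E")))
  gold <- dplyr::bind_rows(ann("1", prim = "A"),
                           ann("2", prim = "B"))
  micro <- score_task(pred, gold, "primary_sites", average = "micro")
  macro <- score_task(pred, gold, "primary_sites", average = "macro")
  expect_equal(micro$precision, 2 / 5)
  expect_equal(macro$precision, mean(c(1, 1 / 4)))
})
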