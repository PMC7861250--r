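TASK_FIELDS <- c("primary_sites", "primary_sizes", "metastatic_sites")

f1_of <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

eval_row <- function(tp, fp, fn, vacuous = FALSE) {
  if (vacuous) {
    # both prediction and gold empty everywhere: nothing to miss, nothing wrong
    return(tibble(tp = 0L, fp = 0L, fn = 0L,
                  precision = 1, recall = 1, f1 = 1))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         precision = p, recall = r, f1 = f1_of(p, r))
}

#' Entity-level score for one extraction task
#'
#' Per document, with exact matching of normalized strings under set
#' semantics: TP = |pred ∩ gold|, FP = |pred \ gold|, FN = |gold \ pred|.
#' Counts pool over documents (micro average, the convention for entity-level
#' P/R/F1; `average = "macro"` instead averages per-document metrics) and
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R). Boundary
#' conventions: an empty denominator gives 0; when both prediction and gold
#' are empty for every document all three metrics are 1 (vacuous perfection).
#' True negatives are never computed — extraction has no closed universe of
#' negatives and the formulas never use them.
#'
#' @param pred predictions (tibble or JSONL path, see [as_annotations()]).
#' @param gold gold annotations, same shape and the same document ids.
#' @param task which entity list to score.
#' @param average `"micro"` (default) or `"macro"`.
#' @return one-row tibble: `task`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
#' @examples
#' pred <- tibble::tibble(id = "d", primary_sites = list(c("A", "B", "C")),
#'                        primary_sizes = list(character(0)),
#'                        metastatic_sites = list(character(0)))
#' gold <- pred; gold$primary_sites <- list(c("A", "B", "D"))
#' score_task(pred, gold, "primary_sites") # P = R = F1 = 2/3
score_task <- function(pred, gold,
                       task = c("primary_sites", "primary_sizes",
                                "metastatic_sites"),
                       average = c("micro", "macro")) {
  task <- match.arg(task)
  average <- match.arg(average)
  pred <- as_annotations(pred)
  gold <- as_annotations(gold)
  check_ids(pred$id, gold$id)
  gold <- gold[match(pred$id, gold$id), , drop = FALSE]
  per_doc <- purrr::map2(pred[[task]], gold[[task]], function(p, g) {
    p <- unique(p); g <- unique(g)
    c(tp = length(intersect(p, g)), fp = length(setdiff(p, g)),
      fn = length(setdiff(g, p)))
  })
  counts <- Reduce(`+`, per_doc, accumulate = FALSE)
  vacuous <- counts[["tp"]] + counts[["fp"]] + counts[["fn"]] == 0L
  if (average == "micro") {
    res <- eval_row(counts[["tp"]], counts[["fp"]], counts[["fn"]], vacuous)
  } else {
    rows <- bind_rows(lapply(per_doc, function(ct)
      eval_row(ct[["tp"]], ct[["fp"]], ct[["fn"]],
               vacuous = sum(ct) == 0L)))
    res <- tibble(tp = counts[["tp"]], fp = counts[["fp"]],
                  fn = counts[["fn"]],
                  precision = mean(rows$precision), recall = mean(rows$recall),
                  f1 = mean(rows$f1))
    if (vacuous) res[, c("precision", "recall", "f1")] <- 1
  }
  mutate(res, task = task, .before = 1)
}

check_ids <- function(pred_ids, gold_ids) {
  extra <- setdiff(pred_ids, gold_ids)
  missing <- setdiff(gold_ids, pred_ids)
  if (length(extra) || length(missing)) {
    abort(paste0(
      "document ids differ between prediction and gold",
      if (length(extra)) paste0("; only in pred: ",
                                paste(utils::head(extra, 5), collapse = ", ")),
      if (length(missing)) paste0("; only in gold: ",
                                  paste(utils::head(missing, 5),
                                        collapse = ", "))))
  }
}

#' Task weights for the overall score
#'
#' The overall score weighs primary site 0.2, lesion size 0.3 and metastatic
#' site 0.5; weights must sum to 1.
#'
#' @param w_primary,w_size,w_meta task weights.
#' @return named numeric vector of length 3.
#' @export
weight_config <- function(w_primary = 0.2, w_size = 0.3, w_meta = 0.5) {
  w <- c(primary = w_primary, size = w_size, meta = w_meta)
  if (abs(sum(w) - 1) > 1e-8) abort("task weights must sum to 1")
  w
}

#' Weighted overall score across the three tasks
#'
#' Combines per-task results (ordered primary site, size, metastatic site)
#' into one overall row. Under `mode = "metric"` (default) each of
#' precision/recall/F1 is the weight-dot-product of the per-task values;
#' under `mode = "count"` the TP/FP/FN counts are weight-scaled, summed, and
#' the metric formulas re-applied. The two modes genuinely differ and the
#' aggregation used by any particular benchmark may be either; both are
#' provided.
#'
#' @param results three-row tibble from [score_task()], rows ordered
#'   (primary_sites, primary_sizes, metastatic_sites).
#' @param weights from [weight_config()].
#' @param mode `"metric"` or `"count"`.
#' @return one-row tibble with `task = "overall_weighted"`.
#' @export
weighted_overall <- function(results, weights = weight_config(),
                             mode = c("metric", "count")) {
  mode <- match.arg(mode)
  if (abs(sum(weights) - 1) > 1e-8) abort("task weights must sum to 1")
  stopifnot(nrow(results) == 3L)
  if (mode == "metric") {
    res <- tibble(
      task = "overall_weighted", tp = NA_integer_, fp = NA_integer_,
      fn = NA_integer_,
      precision = sum(weights * results$precision),
      recall = sum(weights * results$recall),
      f1 = sum(weights * results$f1))
  } else {
    tp <- sum(weights * results$tp); fp <- sum(weights * results$fp)
    fn <- sum(weights * results$fn)
    row <- eval_row(0, 0, 0, vacuous = TRUE)
    if (tp + fp + fn > 0) {
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      row <- tibble(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                    precision = p, recall = r, f1 = f1_of(p, r))
    } else {
      row <- mutate(row, tp = NA_integer_, fp = NA_integer_, fn = NA_integer_)
    }
    res <- mutate(row, task = "overall_weighted", .before = 1)
  }
  res
}

#' Score predictions against gold on all three tasks
#'
#' Convenience wrapper: per-task entity-level scores plus the weighted
#' overall row, as an `onco_eval` object with [tidy()][generics::tidy] /
#' [glance()][generics::glance] methods.
#'
#' @inheritParams score_task
#' @inheritParams weighted_overall
#' @return an `onco_eval` object (a tibble of four result rows plus
#'   attributes).
#' @export
evaluate_predictions <- function(pred, gold, weights = weight_config(),
                                 mode = c("metric", "count"),
                                 average = c("micro", "macro")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  per_task <- bind_rows(lapply(TASK_FIELDS, function(t)
    score_task(pred, gold, t, average = average)))
  overall <- weighted_overall(per_task, weights, mode)
  out <- bind_rows(per_task, overall)
  structure(out, class = c("onco_eval", class(tibble())),
            weights = weights, mode = mode, average = average)
}

#' @export
print.onco_eval <- function(x, ...) {
  cat("Entity-level evaluation (", attr(x, "average"), " average, ",
      attr(x, "mode"), "-mode weighting)\n", sep = "")
  df <- as.data.frame(x)
  df$precision <- sprintf("%.4f", df$precision)
  df$recall <- sprintf("%.4f", df$recall)
  df$f1 <- sprintf("%.4f", df$f1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_predictions
#' @param x an `onco_eval` object.
#' @param ... unused.
#' @method tidy onco_eval
#' @export
tidy.onco_eval <- function(x, ...) {
  as_tibble(x[x$task != "overall_weighted", , drop = FALSE])
}

#' @rdname evaluate_predictions
#' @method glance onco_eval
#' @export
glance.onco_eval <- function(x, ...) {
  ov <- x[x$task == "overall_weighted", , drop = FALSE]
  tibble(precision = ov$precision, recall = ov$recall, f1 = ov$f1,
         mode = attr(x, "mode"), average = attr(x, "average"))
}

#' Subsampling robustness experiment
#'
#' Stability of the weighted overall score under corpus subsampling: for each
#' subsample size, draws `repeats` uniform random document subsets (without
#' replacement, seeded and reproducible), scores the weighted overall on
#' each, and reports mean and standard deviation of precision, recall and F1.
#' At the full corpus size every draw is the whole corpus, so the standard
#' deviation is exactly 0.
#'
#' @inheritParams evaluate_predictions
#' @param sizes integer vector of subsample sizes (each ≤ number of
#'   documents).
#' @param repeats draws per size.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return tibble of class `onco_robustness`: `size`, `metric`, `mean`, `sd`.
#' @export
robustness_curve <- function(pred, gold, sizes = seq(20, 200, by = 20),
                             repeats = 50, seed = 1,
                             weights = weight_config(),
                             mode = c("metric", "count")) {
  mode <- match.arg(mode)
  pred <- as_annotations(pred)
  gold <- as_annotations(gold)
  check_ids(pred$id, gold$id)
  stopifnot(repeats >= 1)
  n <- nrow(pred)
  if (any(sizes > n)) {
    abort(paste0("subsample size exceeds corpus size (", n, " documents)"))
  }
  rows <- withr::with_seed(seed, {
    purrr::map(sizes, function(sz) {
      draws <- purrr::map(seq_len(repeats), function(rep) {
        ids <- sample(pred$id, sz, replace = FALSE)
        sub_pred <- pred[match(ids, pred$id), , drop = FALSE]
        sub_gold <- gold[match(ids, gold$id), , drop = FALSE]
        glance(evaluate_predictions(sub_pred, sub_gold, weights, mode))
      })
      draws <- bind_rows(draws)
      tibble(size = sz,
             metric = c("precision", "recall", "f1"),
             mean = c(mean(draws$precision), mean(draws$recall),
                      mean(draws$f1)),
             sd = if (repeats == 1L) c(0, 0, 0) else
               c(stats::sd(draws$precision), stats::sd(draws$recall),
                 stats::sd(draws$f1)))
    })
  })
  structure(bind_rows(rows),
            class = c("onco_robustness", class(tibble())))
}

#' Plot a robustness curve
#'
#' Mean weighted precision/recall/F1 against subsample size, with a ±1 sd
#' ribbon.
#'
#' @param object an `onco_robustness` tibble from [robustness_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot onco_robustness
#' @export
autoplot.onco_robustness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$mean,
                                       colour = .data$metric,
                                       fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "number of test documents",
                  y = "weighted overall score", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
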