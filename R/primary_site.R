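# does `text` contain any of `keys` (width-folded, ASCII case-insensitive)?
contains_any <- function(text, keys) {
  if (!length(keys)) return(FALSE)
  any(str_detect(fold_width(text), fixed(fold_width(keys), ignore_case = TRUE)))
}

#' Sentences that mention a malignancy indicator
#'
#' Keyword filter for the primary-site stage: a sentence survives iff it
#' contains at least one malignancy indicator (癌, 恶性, 瘤, MT, CA, ...) as a
#' substring of its width-folded text; the Latin abbreviations MT and CA match
#' case-insensitively. Order is preserved.
#'
#' @param docs documents tibble or JSONL path.
#' @param lexicon an `onco_lexicon`.
#' @return sentence tibble (as [split_sentences()]) restricted to indicator
#'   sentences.
#' @export
filter_malignancy_sentences <- function(docs, lexicon = load_lexicon()) {
  sents <- split_sentences(docs)
  keep <- vapply(sents$sentence, contains_any, logical(1),
                 keys = lexicon$malignancy, USE.NAMES = FALSE)
  sents[keep, , drop = FALSE]
}

#' Anatomy mentions in a sentence
#'
#' Segments the sentence with the anatomy dictionary (longest match) and emits
#' one mention per token that is an anatomy term, or whose descriptor-stripped
#' form is one, in sentence order. Spans are 0-based half-open code point
#' offsets into the sentence.
#'
#' @param sentence sentence string.
#' @param lexicon an `onco_lexicon`.
#' @param sentence_index ordinal recorded on the mentions.
#' @return mention tibble: `surface`, `normalized`, `etype`, `sentence_index`,
#'   `start`, `end`.
#' @export
#' @examples
#' match_anatomy_mentions("肺癌可能。", load_lexicon())
match_anatomy_mentions <- function(sentence, lexicon = load_lexicon(),
                                   sentence_index = 1L) {
  toks <- segment(sentence, lexicon)
  if (!nrow(toks)) return(empty_mentions())
  anat <- fold_width(lexicon$anatomy)
  stripped <- strip_descriptive_words(fold_width(toks$token), lexicon)
  hit <- toks$is_term | (fold_width(toks$token) %in% anat) | (stripped %in% anat)
  toks <- toks[hit, , drop = FALSE]
  if (!nrow(toks)) return(empty_mentions())
  tibble(surface = toks$token,
         normalized = normalize_mention(toks$token, lexicon),
         etype = "PRIMARY_SITE",
         sentence_index = as.integer(sentence_index),
         start = toks$start, end = toks$end)
}

empty_mentions <- function() {
  tibble(surface = character(0), normalized = character(0),
         etype = character(0), sentence_index = integer(0),
         start = integer(0), end = integer(0))
}

#' Refine an approximate primary site to a specific one
#'
#' A malignancy phrase like 肺癌 yields the approximate site 肺, but the tumor
#' originates in some part of the lung. The refiner scans the document's
#' sentences in order for an anatomy mention that [is_part_of()] the
#' approximate site (左肺上叶 for 肺) and returns the first such mention;
#' with none found the approximate mention is returned unchanged. By default
#' sentences containing a metastasis keyword are skipped so metastatic sites
#' cannot masquerade as the primary.
#'
#' @param approximate one-row mention tibble (a PRIMARY_SITE mention).
#' @param text the full document text.
#' @param lexicon an `onco_lexicon`.
#' @param skip_metastasis skip metastasis-keyword sentences while scanning.
#' @return one-row mention tibble.
#' @export
refine_primary_site <- function(approximate, text, lexicon = load_lexicon(),
                                skip_metastasis = TRUE) {
  stopifnot(nrow(approximate) == 1L)
  sents <- sentences_of(text)
  for (i in seq_len(nrow(sents))) {
    if (skip_metastasis &&
        contains_any(sents$sentence[i], lexicon$metastasis)) next
    men <- match_anatomy_mentions(sents$sentence[i], lexicon,
                                  sents$sentence_index[i])
    for (j in seq_len(nrow(men))) {
      if (is_part_of(men$surface[j], approximate$surface[1])) {
        return(men[j, , drop = FALSE])
      }
    }
  }
  approximate
}

#' Extract primary tumor sites
#'
#' The primary site is the first anatomic site mentioned in the report that is
#' associated with a malignancy description and not with metastasis. Pipeline:
#' keep malignancy-indicator sentences, drop those also containing a
#' metastasis keyword, match anatomy mentions, take the first mention in
#' document order, then refine it to a more specific site if one occurs
#' elsewhere in the document. Most reports carry a single primary; with
#' `multi_primary = TRUE` (an extension beyond the default single-site
#' behavior) the first mention of every surviving indicator sentence is
#' returned.
#'
#' @param docs documents tibble or JSONL path.
#' @param lexicon an `onco_lexicon`.
#' @param multi_primary return one site per indicator sentence instead of the
#'   document-first site only.
#' @param refine_skips_metastasis passed to [refine_primary_site()].
#' @return mention tibble with an `id` column; deduplicated on the normalized
#'   form per document (usually 1 row per document, 0 when nothing survives).
#' @export
extract_primary_sites <- function(docs, lexicon = load_lexicon(),
                                  multi_primary = FALSE,
                                  refine_skips_metastasis = TRUE) {
  docs <- as_documents(docs)
  out <- purrr::map2(docs$id, docs$text, function(id, text) {
    sents <- sentences_of(text)
    if (!nrow(sents)) return(NULL)
    mal <- vapply(sents$sentence, contains_any, logical(1),
                  keys = lexicon$malignancy, USE.NAMES = FALSE)
    met <- vapply(sents$sentence, contains_any, logical(1),
                  keys = lexicon$metastasis, USE.NAMES = FALSE)
    surv <- sents[mal & !met, , drop = FALSE]
    if (!nrow(surv)) return(NULL)
    picked <- list()
    for (i in seq_len(nrow(surv))) {
      men <- match_anatomy_mentions(surv$sentence[i], lexicon,
                                    surv$sentence_index[i])
      if (nrow(men)) picked[[length(picked) + 1L]] <- men[1, , drop = FALSE]
      if (!multi_primary && length(picked)) break
    }
    if (!length(picked)) return(NULL)
    refined <- purrr::map(picked, refine_primary_site, text = text,
                          lexicon = lexicon,
                          skip_metastasis = refine_skips_metastasis)
    res <- bind_rows(refined)
    res$etype <- "PRIMARY_SITE"
    res$id <- id
    res[!duplicated(res$normalized), , drop = FALSE]
  })
  res <- bind_rows(out)
  if (!nrow(res)) return(mutate(empty_mentions(), id = character(0)))
  select(res, "id", dplyr::everything())
}
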