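LOCATIVE_CHARS <- c("内", "部", "旁")

#' Sentences that mention a metastasis keyword
#'
#' Key-sentence acquisition: metastatic sites co-occur with keywords such as
#' 转移, 考虑转移 and 多发转移 in the same sentence. Under the default
#' `"substring"` policy plain substring matching is used, so a double negative
#' (转移不除外, "metastasis not excluded") counts as a positive mention — the
#' desired reading. The `"drop-negated"` policy additionally drops sentences
#' where the keyword sits under a simple negation (未见/未发现/无 ... 转移).
#'
#' @param docs documents tibble or JSONL path.
#' @param lexicon an `onco_lexicon`.
#' @param negation_policy `"substring"` (default) or `"drop-negated"`.
#' @return sentence tibble restricted to key sentences, order preserved.
#' @export
filter_metastasis_sentences <- function(docs, lexicon = load_lexicon(),
                                        negation_policy = c("substring",
                                                            "drop-negated")) {
  negation_policy <- match.arg(negation_policy)
  sents <- split_sentences(docs)
  keep <- vapply(sents$sentence, contains_any, logical(1),
                 keys = lexicon$metastasis, USE.NAMES = FALSE)
  if (negation_policy == "drop-negated") {
    negated <- str_detect(fold_width(sents$sentence),
                          "(未见|未发现|无)[^,，;；]*转移") &
      !str_detect(fold_width(sents$sentence), "转移不除外")
    keep <- keep & !negated
  }
  sents[keep, , drop = FALSE]
}

#' Complete coordinated entities sharing an elided suffix
#'
#' In phrases like 肺门及前纵隔淋巴结 the head noun 淋巴结 is written once but
#' belongs to both conjuncts; naive splitting on the conjunction would lose
#' it. The phrase is split on the conjunction tokens (、 及 与), the shared
#' suffix is identified as the longest anatomy term that is a proper suffix of
#' the last conjunct (falling back to its trailing dictionary token), and that
#' suffix is appended to every conjunct not already ending with it. When the
#' last conjunct has no proper anatomy suffix (肝、骨 — two complete organ
#' names, nothing elided) the conjuncts are returned as they stand. A phrase
#' without conjunction tokens comes back unchanged as a singleton.
#'
#' @param phrase descriptor-stripped anatomic phrase.
#' @param lexicon an `onco_lexicon`.
#' @return character vector of completed entities, in phrase order.
#' @export
#' @examples
#' complete_conjoined_entities("肺门及前纵隔淋巴结", load_lexicon())
complete_conjoined_entities <- function(phrase, lexicon = load_lexicon()) {
  stopifnot(is.character(phrase), length(phrase) == 1L, nzchar(phrase))
  conj <- lexicon$conjunction
  conj_class <- paste0("[", paste(vapply(conj, function(t)
    str_replace_all(t, "([\\[\\]\\\\^-])", "\\\\\\1"), character(1)),
    collapse = ""), "]")
  parts <- strsplit(phrase, conj_class, perl = FALSE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) <= 1L) return(phrase)
  cn <- parts[[length(parts)]]
  suffix <- shared_suffix(cn, lexicon)
  if (is.na(suffix)) return(parts)
  vapply(parts, function(p) {
    if (endsWith(p, suffix)) p else paste0(p, suffix)
  }, character(1), USE.NAMES = FALSE)
}

# longest anatomy term that is a PROPER suffix of x; fallback: trailing
# dictionary token of x when x segments into more than one token; NA when
# nothing is elided (x is itself a single complete term)
shared_suffix <- function(x, lexicon) {
  anat <- lexicon$anatomy
  cand <- anat[nchar(anat) < nchar(x) &
                 vapply(anat, function(a) endsWith(x, a), logical(1))]
  if (length(cand)) return(cand[which.max(nchar(cand))])
  toks <- segment(x, lexicon)
  if (nrow(toks) > 1L) {
    tail_tok <- toks$token[nrow(toks)]
    if (nchar(tail_tok) < nchar(x)) return(tail_tok)
  }
  NA_character_
}

#' Extract metastatic tumor sites
#'
#' For every metastasis-keyword sentence, locates maximal anatomy-bearing
#' phrases: contiguous token runs of anatomy terms, descriptor terms,
#' conjunction tokens and the locative characters 内/部/旁, trimmed so each
#' run ends at its last anatomy term (any other character, including
#' punctuation other than 、, terminates a run). Each run is
#' descriptor-stripped, coordination-completed, and emitted as one mention per
#' completed entity; deduplication across the document folds laterality
#' variants (左肺 and 左侧肺 count once).
#'
#' Compound phrases without a conjunction (右肺门纵隔多发肿大淋巴结) are
#' deliberately emitted un-split as one entity; splitting them would require
#' knowledge the surface text does not carry.
#'
#' @param docs documents tibble or JSONL path.
#' @param lexicon an `onco_lexicon`.
#' @param negation_policy see [filter_metastasis_sentences()].
#' @return mention tibble with an `id` column, `etype` = `"META_SITE"`;
#'   `surface` is the run substring, `normalized` the completed entity.
#' @export
extract_metastatic_sites <- function(docs, lexicon = load_lexicon(),
                                     negation_policy = c("substring",
                                                         "drop-negated")) {
  negation_policy <- match.arg(negation_policy)
  docs <- as_documents(docs)
  dict <- unique(c(lexicon$anatomy, lexicon$descriptor, lexicon$conjunction,
                   LOCATIVE_CHARS))
  anat <- fold_width(lexicon$anatomy)
  out <- purrr::map2(docs$id, docs$text, function(id, text) {
    key <- filter_metastasis_sentences(tibble(id = id, text = text), lexicon,
                                       negation_policy)
    if (!nrow(key)) return(NULL)
    men <- list()
    for (i in seq_len(nrow(key))) {
      sent <- key$sentence[i]
      toks <- segment(sent, lexicon, terms = dict)
      allowed <- toks$is_term
      is_anat <- fold_width(toks$token) %in% anat
      runs <- split(seq_len(nrow(toks)),
                    cumsum(c(TRUE, diff(allowed) != 0))[seq_len(nrow(toks))])
      for (r in runs) {
        if (!allowed[r[1]]) next
        sub <- r
        # trim to end at the last anatomy token
        last_anat <- max(c(0L, sub[is_anat[sub]]))
        if (last_anat == 0L) next
        sub <- sub[sub <= last_anat]
        # trim leading conjunction/locative tokens
        while (length(sub) &&
               (toks$token[sub[1]] %in% lexicon$conjunction ||
                toks$token[sub[1]] %in% LOCATIVE_CHARS)) {
          sub <- sub[-1]
        }
        if (!length(sub) || !any(is_anat[sub])) next
        run_start <- toks$start[sub[1]]; run_end <- toks$end[sub[length(sub)]]
        surface <- span_sub(sent, run_start, run_end)
        phrase <- strip_descriptive_words(fold_width(surface), lexicon)
        if (!nzchar(phrase)) next
        entities <- complete_conjoined_entities(phrase, lexicon)
        for (ent in entities) {
          men[[length(men) + 1L]] <- tibble(
            surface = surface, normalized = ent, etype = "META_SITE",
            sentence_index = key$sentence_index[i],
            start = run_start, end = run_end)
        }
      }
    }
    if (!length(men)) return(NULL)
    res <- bind_rows(men)
    res$id <- id
    res[!duplicated(canonical_site(res$normalized)), , drop = FALSE]
  })
  res <- bind_rows(out)
  if (!nrow(res)) return(mutate(empty_mentions(), id = character(0)))
  select(res, "id", dplyr::everything())
}
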