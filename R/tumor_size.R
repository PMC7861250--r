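# Measurement-expression grammar. Size mentions in Chinese radiology text are
# highly regular: 1-3 dimensions, each an integer or decimal with an optional
# CM/MM unit in any case, joined by ×, X, x or * with optional spaces, and an
# optional preceding qualifier 不足 (less than) or 约 (about). Matching runs
# on width-folded text so full-width digits/letters/separators participate.
size_pattern <- function() {
  num <- "\\d+(?:\\.\\d+)?"
  unit <- "(?:[Cc][Mm]|[Mm][Mm])"
  sep <- "[×xX*]"
  paste0("(?:(不足|约)\\s*)?",
         "(", num, ")\\s*(", unit, ")?",
         "(?:\\s*(", sep, ")\\s*(", num, ")\\s*(", unit, ")?",
         "(?:\\s*(", sep, ")\\s*(", num, ")\\s*(", unit, ")?)?",
         ")?")
}

# all grammar matches in one string, with parsed dimensions. Leftmost-longest
# non-overlapping semantics over VALID size expressions: a bare number with no
# second dimension and no unit (e.g. a date) is not a match and does not
# consume characters, so a valid expression starting inside it is still found.
parse_size_matches <- function(text) {
  folded <- fold_width(text)
  anchored <- paste0("^", size_pattern())
  n <- str_length(folded)
  if (n == 0L || !str_detect(folded, "\\d")) return(empty_size_mentions())
  # a match can only start at a digit or a qualifier's first character
  chars <- strsplit(folded, "")[[1]]
  starts <- which(chars %in% c(as.character(0:9), "不", "约"))
  out <- list()
  i <- 1L
  for (s in starts) {
    if (s < i) next
    g <- str_match(str_sub(folded, s), anchored)[1, ]
    if (is.na(g[1]) || !nzchar(g[1])) next
    vals <- g[c(3, 6, 9)]; units <- g[c(4, 7, 10)]
    present <- !is.na(vals)
    ndim <- sum(present)
    if (ndim == 0L) next
    if (ndim < 2L && !any(!is.na(units[present]))) next
    e <- s + str_length(g[1]) - 1L
    dims <- tibble(
      value_raw = vals[present],
      value = as.numeric(vals[present]),
      unit = ifelse(is.na(units[present]), "unspecified",
                    tolower(units[present]))
    )
    out[[length(out) + 1L]] <- tibble(
      raw = str_sub(text, s, e),
      qualifier = if (is.na(g[2])) NA_character_ else g[2],
      separator = if (is.na(g[5])) NA_character_ else g[5],
      dims = list(dims),
      start = as.integer(s - 1L), end = as.integer(e)
    )
    i <- e + 1L
  }
  if (!length(out)) return(empty_size_mentions())
  bind_rows(out)
}

empty_size_mentions <- function() {
  tibble(raw = character(0), qualifier = character(0),
         separator = character(0), dims = list(),
         start = integer(0), end = integer(0))
}

#' Sentences containing a size expression
#'
#' First step of size extraction: a sentence is a candidate iff the
#' measurement grammar matches at least one valid size expression in it
#' (digits alone, e.g. dates, do not qualify). Order preserved.
#'
#' @param docs documents tibble or JSONL path.
#' @return sentence tibble restricted to size-bearing sentences.
#' @export
detect_size_sentences <- function(docs) {
  sents <- split_sentences(docs)
  keep <- vapply(sents$sentence,
                 function(s) nrow(parse_size_matches(s)) > 0L,
                 logical(1), USE.NAMES = FALSE)
  sents[keep, , drop = FALSE]
}

#' Keep size sentences related to the primary tumor
#'
#' A size sentence is considered primary-related when it contains any
#' laterality variant of a primary site (左肺门 matches a sentence writing
#' 左侧肺门) or is itself the sentence holding a primary-site mention.
#' Surviving sentences that also contain a density indicator (高密度影,
#' 低密度影, 不规则团块, ...) rank first, since those phrases correlate
#' strongly with lesion size statements. With no primary sites the result is
#' empty: size extraction is defined relative to a primary site.
#'
#' @param sentences sentence tibble (with `id`, `sentence_index`, `sentence`).
#' @param primary_sites mention tibble from [extract_primary_sites()] (or a
#'   character vector of site strings applied to every document).
#' @param lexicon an `onco_lexicon`.
#' @param expand_variants apply laterality-variant expansion when matching
#'   sites into sentences.
#' @return sentence tibble, density-indicator sentences first.
#' @export
filter_primary_related <- function(sentences, primary_sites,
                                   lexicon = load_lexicon(),
                                   expand_variants = TRUE) {
  empty <- sentences[0, , drop = FALSE]
  if (is.character(primary_sites)) {
    primary_sites <- tibble(id = NA_character_, surface = primary_sites,
                            normalized = primary_sites,
                            sentence_index = NA_integer_)
  }
  if (!nrow(primary_sites) || !nrow(sentences)) return(empty)
  keep <- logical(nrow(sentences))
  for (i in seq_len(nrow(sentences))) {
    sid <- sentences$id[i]
    prim <- primary_sites[is.na(primary_sites$id) | primary_sites$id == sid, ,
                          drop = FALSE]
    if (!nrow(prim)) next
    forms <- unique(unlist(lapply(
      unique(c(prim$surface, prim$normalized)),
      function(s) if (expand_variants) expand_site_variants(s) else s
    )))
    same_sentence <- any(!is.na(prim$sentence_index) &
                           prim$sentence_index == sentences$sentence_index[i])
    keep[i] <- same_sentence || contains_any(sentences$sentence[i], forms)
  }
  surv <- sentences[keep, , drop = FALSE]
  if (!nrow(surv)) return(empty)
  dens <- vapply(surv$sentence, contains_any, logical(1),
                 keys = lexicon$density, USE.NAMES = FALSE)
  bind_rows(surv[dens, , drop = FALSE], surv[!dens, , drop = FALSE])
}

#' Extract size mentions from one sentence
#'
#' Returns every non-overlapping, leftmost-longest match of the measurement
#' grammar, ordered by span, with dimensions (value + unit), separator and
#' qualifier parsed out. `raw` is the verbatim sentence substring at the span.
#'
#' @param sentence sentence string.
#' @param sentence_index ordinal recorded on the mentions.
#' @return size-mention tibble: `raw`, `qualifier`, `separator`, `dims`
#'   (list-column of tibbles `value_raw`, `value`, `unit`), `normalized`,
#'   `sentence_index`, `start`, `end`.
#' @export
#' @examples
#' extract_size_mentions("大小约1.3CM × 1.7CM")
extract_size_mentions <- function(sentence, sentence_index = 1L) {
  m <- parse_size_matches(sentence)
  m$normalized <- vapply(m$dims, normalize_size, character(1))
  m$sentence_index <- as.integer(sentence_index)
  select(m, "raw", "qualifier", "separator", "dims", "normalized",
         "sentence_index", "start", "end")
}

#' Canonical form of a size expression
#'
#' Renders parsed dimensions as `v1UNITxv2UNIT...`: lowercase x separator,
#' uppercase units, values exactly as written in the text (2.0 stays 2.0).
#' Under the default `propagate` policy a trailing unit fills unit-less
#' dimensions to its left (5x4x3CM becomes 5CMx4CMx3CM); with `as-parsed`
#' units are rendered only where written.
#'
#' @param dims a dims tibble (`value_raw`, `value`, `unit`) or a one-row
#'   size-mention tibble carrying a `dims` list-column.
#' @param policy `"propagate"` (default) or `"as-parsed"`.
#' @return single canonical string.
#' @export
#' @examples
#' m <- extract_size_mentions("5x4x3CM")
#' normalize_size(m$dims[[1]]) # "5CMx4CMx3CM"
normalize_size <- function(dims, policy = c("propagate", "as-parsed")) {
  policy <- match.arg(policy)
  if (is.data.frame(dims) && "dims" %in% names(dims)) {
    stopifnot(nrow(dims) == 1L)
    dims <- dims$dims[[1]]
  }
  units <- dims$unit
  if (policy == "propagate") {
    n <- length(units)
    if (n > 1L) {
      for (i in seq(n - 1L, 1L)) {
        if (units[i] == "unspecified") units[i] <- units[i + 1L]
      }
    }
  }
  parts <- paste0(dims$value_raw,
                  ifelse(units == "unspecified", "", toupper(units)))
  paste(parts, collapse = "x")
}

#' Extract primary tumor sizes from documents
#'
#' Three-step composition: detect size-bearing sentences, keep those related
#' to the primary tumor site, then extract size mentions from the survivors.
#' Results come back in document order, deduplicated on the normalized form
#' per document. With no primary site the result is empty.
#'
#' @param docs documents tibble or JSONL path.
#' @param primary_sites mention tibble; computed via [extract_primary_sites()]
#'   when omitted.
#' @param lexicon an `onco_lexicon`.
#' @param policy unit policy for [normalize_size()].
#' @param expand_variants see [filter_primary_related()].
#' @return size-mention tibble with an `id` column.
#' @export
extract_primary_sizes <- function(docs, primary_sites = NULL,
                                  lexicon = load_lexicon(),
                                  policy = "propagate",
                                  expand_variants = TRUE) {
  docs <- as_documents(docs)
  if (is.null(primary_sites)) {
    primary_sites <- extract_primary_sites(docs, lexicon)
  }
  out <- purrr::map2(docs$id, docs$text, function(id, text) {
    sents <- sentences_of(text)
    if (!nrow(sents)) return(NULL)
    sents$id <- id
    cand <- sents[vapply(sents$sentence,
                         function(s) nrow(parse_size_matches(s)) > 0L,
                         logical(1), USE.NAMES = FALSE), , drop = FALSE]
    rel <- filter_primary_related(cand, primary_sites, lexicon,
                                  expand_variants = expand_variants)
    if (!nrow(rel)) return(NULL)
    men <- purrr::map2(rel$sentence, rel$sentence_index,
                       extract_size_mentions)
    men <- bind_rows(men)
    if (!nrow(men)) return(NULL)
    men$normalized <- vapply(men$dims, normalize_size, character(1),
                             policy = policy)
    men <- arrange(men, .data$sentence_index, .data$start)
    men <- men[!duplicated(men$normalized), , drop = FALSE]
    men$id <- id
    men
  })
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- extract_size_mentions("")[0, , drop = FALSE]
    res$id <- character(0)
  }
  select(res, "id", dplyr::everything())
}
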