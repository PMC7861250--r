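SENTENCE_DELIMS <- c("。", "；", ";", "！", "？", "\n") # 。；;！？\n

#' Split documents into sentences
#'
#' Sentences are delimited by 。 ； ; ！ ？ and newline; the delimiter attaches
#' to the preceding sentence and empty fragments are dropped. Commas (both ,
#' and ，) do NOT split: size expressions and their anatomic context routinely
#' share a comma-joined clause and must stay in one sentence. Spans are
#' 0-based half-open offsets in Unicode code points into the original text,
#' and concatenating `sentence` values in order reconstructs the text exactly.
#'
#' @param docs documents tibble (`id`, `text`) or a JSONL path
#'   (see [as_documents()]).
#' @return tibble with columns `id`, `sentence_index` (1-based), `sentence`,
#'   `start`, `end`.
#' @export
#' @examples
#' docs <- tibble::tibble(id = "d1", text = "左肺占位。纵隔淋巴结转移。")
#' split_sentences(docs)
split_sentences <- function(docs) {
  docs <- as_documents(docs)
  out <- purrr::map2(docs$id, docs$text, function(id, text) {
    s <- sentences_of(text)
    if (!nrow(s)) return(NULL)
    s$id <- id
    s
  })
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(id = character(0), sentence_index = integer(0),
                  sentence = character(0), start = integer(0), end = integer(0)))
  }
  select(res, "id", "sentence_index", "sentence", "start", "end")
}

# single-text sentence decomposition; delimiter kept with preceding sentence
sentences_of <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble(sentence_index = integer(0), sentence = character(0),
                  start = integer(0), end = integer(0)))
  }
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  is_delim <- chars %in% SENTENCE_DELIMS
  n <- length(chars)
  starts <- integer(0); ends <- integer(0)
  seg_start <- 1L
  for (i in seq_len(n)) {
    if (is_delim[i]) {
      starts <- c(starts, seg_start); ends <- c(ends, i)
      seg_start <- i + 1L
    }
  }
  if (seg_start <= n) { starts <- c(starts, seg_start); ends <- c(ends, n) }
  texts <- substring(paste(chars, collapse = ""), starts, ends)
  # drop fragments that are nothing but delimiters/whitespace
  keep <- nzchar(gsub(paste0("[", paste(c("。", "；", ";", "！",
                                          "？", "\\s"), collapse = ""), "]"),
                      "", texts))
  texts <- texts[keep]; starts <- starts[keep]; ends <- ends[keep]
  tibble(sentence_index = seq_along(texts), sentence = texts,
         start = starts - 1L, end = ends)
}

#' Dictionary longest-match segmentation
#'
#' Tokenizes a sentence so that every lexicon term occurring in it is emitted
#' as one unbroken token, with longest-match priority when terms nest (左肺门
#' wins over 肺门). Characters not covered by any dictionary term are merged
#' into filler tokens, so the token concatenation always equals the input.
#' Matching is done on the width-folded text but tokens are the original
#' surface. Any tokenizer honoring the same guarantee can be substituted
#' upstream; this greedy matcher keeps the package dependency-free.
#'
#' @param sentence single sentence string.
#' @param lexicon an `onco_lexicon`.
#' @param terms optional explicit dictionary (character vector); defaults to
#'   the lexicon's anatomy terms.
#' @return tibble with columns `token`, `start`, `end` (0-based half-open code
#'   point span), `is_term`.
#' @export
segment <- function(sentence, lexicon = load_lexicon(), terms = lexicon$anatomy) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  folded <- fold_width(sentence)
  n <- str_length(folded)
  if (n == 0L) {
    return(tibble(token = character(0), start = integer(0), end = integer(0),
                  is_term = logical(0)))
  }
  terms <- unique(fold_width(terms))
  by_len <- split(terms, str_length(terms))
  lens <- sort(as.integer(names(by_len)), decreasing = TRUE)
  term_env <- new.env(parent = emptyenv(), size = length(terms) * 2L)
  for (t in terms) assign(t, TRUE, envir = term_env)
  tok_start <- integer(0); tok_end <- integer(0); tok_term <- logical(0)
  i <- 1L
  rest_start <- NA_integer_
  flush_rest <- function(upto) {
    if (!is.na(rest_start)) {
      tok_start <<- c(tok_start, rest_start); tok_end <<- c(tok_end, upto)
      tok_term <<- c(tok_term, FALSE); rest_start <<- NA_integer_
    }
  }
  while (i <= n) {
    matched <- 0L
    for (L in lens) {
      if (i + L - 1L > n) next
      cand <- str_sub(folded, i, i + L - 1L)
      if (exists(cand, envir = term_env, inherits = FALSE)) { matched <- L; break }
    }
    if (matched > 0L) {
      flush_rest(i - 1L)
      tok_start <- c(tok_start, i); tok_end <- c(tok_end, i + matched - 1L)
      tok_term <- c(tok_term, TRUE)
      i <- i + matched
    } else {
      if (is.na(rest_start)) rest_start <- i
      i <- i + 1L
    }
  }
  flush_rest(n)
  ord <- order(tok_start)
  tibble(token = str_sub(sentence, tok_start[ord], tok_end[ord]),
         start = tok_start[ord] - 1L, end = tok_end[ord],
         is_term = tok_term[ord])
}

#' Strip descriptive wording from an anatomic phrase
#'
#' Removes every occurrence of each descriptor term (多发肿大, 肿大, 小, ...)
#' from a phrase, longest descriptor first, leaving the anatomic core:
#' 纵隔内多发肿大淋巴结 becomes 纵隔内淋巴结. Removal repeats until a fixed
#' point so the operation is idempotent even when deletions juxtapose new
#' descriptor occurrences.
#'
#' @param phrase character vector of phrases.
#' @param lexicon an `onco_lexicon` providing `descriptor` terms.
#' @return character vector of stripped phrases.
#' @export
#' @examples
#' lex <- load_lexicon()
#' strip_descriptive_words("纵隔内多发肿大淋巴结", lex) # 纵隔内淋巴结
strip_descriptive_words <- function(phrase, lexicon = load_lexicon()) {
  descs <- lexicon$descriptor[order(-str_length(lexicon$descriptor))]
  vapply(phrase, function(p) {
    repeat {
      q <- p
      for (d in descs) q <- str_replace_all(q, fixed(d), "")
      if (identical(q, p)) return(p)
      p <- q
    }
  }, character(1), USE.NAMES = FALSE)
}

# normalized form of a mention surface: width-folded; descriptor-stripped
# unless the surface itself is a dictionary anatomy term (protects terms such
# as 小脑 whose characters overlap descriptor vocabulary)
normalize_mention <- function(surface, lexicon) {
  folded <- fold_width(surface)
  anat <- fold_width(lexicon$anatomy)
  ifelse(folded %in% anat, folded, strip_descriptive_words(folded, lexicon))
}
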