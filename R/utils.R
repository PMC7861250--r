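#' Fold full-width ASCII to half-width
#'
#' Clinical reports freely mix full-width and half-width forms of digits,
#' Latin letters and punctuation (１．３ＣＭ vs 1.3CM). All pattern matching
#' in this package runs on the folded form; the fold is one code point to one
#' code point, so character offsets into the folded string are valid offsets
#' into the original. Letter case is preserved.
#'
#' @param x character vector.
#' @return character vector of the same length, with code points U+FF01..U+FF5E
#'   mapped to U+0021..U+007E and the ideographic space U+3000 to a plain space.
#' @export
#' @examples
#' fold_width("１．３ＣＭ") # "1.3CM"
fold_width <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    cp <- utf8ToInt(s)
    full <- cp >= 0xFF01L & cp <= 0xFF5EL
    cp[full] <- cp[full] - 0xFEE0L
    cp[cp == 0x3000L] <- 0x20L
    intToUtf8(cp)
  }, character(1), USE.NAMES = FALSE)
}

# substring by code points, 0-based half-open span
span_sub <- function(text, start, end) str_sub(text, start + 1L, end)

#' Read a JSON-lines file into a tibble
#'
#' One JSON object per line. Used for both documents (`id`, `text`) and
#' annotation records (`id` plus entity-list fields). List-valued fields
#' become list-columns of character vectors.
#'
#' @param path file path.
#' @param required character vector of field names every record must carry.
#' @return a tibble with one row per line.
#' @export
read_jsonl <- function(path, required = c("id", "text")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) abort(paste0("malformed JSON on line ", i, ": ",
                                       conditionMessage(e)))
    )
    missing <- setdiff(required, names(rec))
    if (length(missing)) {
      abort(paste0("line ", i, " lacks required field(s): ",
                   paste(missing, collapse = ", ")))
    }
    recs[[i]] <- rec
  }
  if (!length(recs)) {
    out <- tibble(id = character(0))
    for (f in setdiff(required, "id")) {
      out[[f]] <- if (f == "text") character(0) else list()
    }
    return(out)
  }
  fields <- unique(unlist(lapply(recs, names)))
  out <- tibble(.rows = length(recs))
  for (f in fields) {
    vals <- lapply(recs, function(r) r[[f]])
    scalar <- all(vapply(vals, function(v) is.null(v) ||
                           (is.atomic(v) && length(v) == 1L), logical(1)))
    if (scalar && !is.null(vals[[1]]) && !is.list(vals[[1]])) {
      out[[f]] <- vapply(vals, function(v) {
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    } else {
      out[[f]] <- lapply(vals, function(v) as.character(unlist(v)))
    }
  }
  out
}

#' Write a tibble as JSON-lines
#'
#' List-columns serialize as JSON arrays (empty lists as `[]`), scalar columns
#' as bare values. Output is UTF-8, one record per row, deterministic.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    rec <- lapply(x, function(col) {
      v <- if (is.list(col)) col[[i]] else col[[i]]
      if (is.list(col)) I(as.character(unlist(v))) else v
    })
    names(rec) <- names(x)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Coerce documents input to the canonical tibble
#'
#' Accepts a tibble/data frame with `id` and `text` columns or a path to a
#' JSON-lines file of `{"id": ..., "text": ...}` records. Text is kept exactly
#' as read; no normalization is applied to the stored original.
#'
#' @param docs data frame or file path.
#' @return tibble with character columns `id`, `text`.
#' @export
as_documents <- function(docs) {
  if (is.character(docs) && length(docs) == 1L) docs <- read_jsonl(docs)
  if (!is.data.frame(docs) || !all(c("id", "text") %in% names(docs))) {
    abort("documents must be a data frame with columns `id` and `text`, or a JSONL path")
  }
  if (anyDuplicated(docs$id)) abort("duplicate document ids")
  tibble(id = as.character(docs$id), text = as.character(docs$text))
}
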