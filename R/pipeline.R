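#' Run the full extraction pipeline
#'
#' Applies the three extraction stages in order — primary tumor sites, primary
#' tumor sizes (relative to those sites), metastatic sites — and returns one
#' row per input document with the three entity lists as list-columns of
#' normalized strings. The pipeline is deterministic: identical input and
#' flags give identical output.
#'
#' @param docs documents tibble (`id`, `text`) or JSONL path.
#' @param lexicon an `onco_lexicon`.
#' @param multi_primary see [extract_primary_sites()].
#' @param negation_policy see [filter_metastasis_sentences()].
#' @param unit_policy see [normalize_size()].
#' @param expand_variants see [filter_primary_related()].
#' @return tibble `id`, `primary_sites`, `primary_sizes`, `metastatic_sites`
#'   (list-columns of character vectors; empty vectors where nothing was
#'   extracted).
#' @export
#' @examples
#' docs <- tibble::tibble(
#'   id = "d1",
#'   text = "左肺上叶见肿块,考虑肺癌。左肺上叶病灶大小约1.3CM × 1.7CM。纵隔淋巴结转移。")
#' extract_entities(docs)
extract_entities <- function(docs, lexicon = load_lexicon(),
                             multi_primary = FALSE,
                             negation_policy = "substring",
                             unit_policy = "propagate",
                             expand_variants = TRUE) {
  docs <- as_documents(docs)
  prim <- extract_primary_sites(docs, lexicon, multi_primary = multi_primary)
  sizes <- extract_primary_sizes(docs, primary_sites = prim, lexicon = lexicon,
                                 policy = unit_policy,
                                 expand_variants = expand_variants)
  meta <- extract_metastatic_sites(docs, lexicon,
                                   negation_policy = negation_policy)
  pull_for <- function(tbl, id) {
    as.character(tbl$normalized[tbl$id == id])
  }
  tibble(
    id = docs$id,
    primary_sites = lapply(docs$id, pull_for, tbl = prim),
    primary_sizes = lapply(docs$id, pull_for, tbl = sizes),
    metastatic_sites = lapply(docs$id, pull_for, tbl = meta)
  )
}

#' Coerce a prediction/gold object to the canonical annotation tibble
#'
#' Accepts a tibble with `id` and the three entity list-columns, or a path to
#' a JSON-lines file of records
#' `{"id": ..., "primary_sites": [...], "primary_sizes": [...],
#' "metastatic_sites": [...]}`.
#'
#' @param x tibble or file path.
#' @return tibble with `id` and three list-columns of character vectors.
#' @export
as_annotations <- function(x) {
  fields <- c("primary_sites", "primary_sizes", "metastatic_sites")
  if (is.character(x) && length(x) == 1L) {
    x <- read_jsonl(x, required = c("id", fields))
  }
  if (!is.data.frame(x) || !all(c("id", fields) %in% names(x))) {
    abort(paste0("annotations need columns id, ",
                 paste(fields, collapse = ", ")))
  }
  out <- tibble(id = as.character(x$id))
  for (f in fields) {
    col <- x[[f]]
    if (!is.list(col)) col <- as.list(col)
    out[[f]] <- lapply(col, function(v) as.character(unlist(v)))
  }
  out
}
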