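#' Load a term lexicon from TSV
#'
#' The lexicon drives every extraction stage: the anatomy dictionary used for
#' word segmentation and mention matching, the malignancy indicators that flag
#' primary-tumor sentences (癌, 恶性, 瘤, MT, CA), the density indicators that
#' rank size-bearing sentences (高密度影 and friends), the metastasis keywords
#' (转移 and variants), the descriptor terms stripped from anatomic phrases
#' (多发肿大, 小), and the conjunction tokens (、 及 与) on which coordinated
#' phrases are split.
#'
#' The file format is two tab-separated columns, `term<TAB>category`, UTF-8,
#' with `#`-prefixed comment lines allowed. Valid categories are `anatomy`,
#' `malignancy`, `density`, `metastasis`, `descriptor` and `conjunction`.
#' Duplicate rows collapse silently; every category must be non-empty after
#' loading.
#'
#' @param path path to a lexicon TSV. Defaults to the lexicon shipped with the
#'   package (~150 anatomy terms covering lung, breast, lymph-node,
#'   mediastinum, liver and bone vocabulary; replace it wholesale for other
#'   tumor domains — coverage is a data concern, not code).
#' @return an object of class `onco_lexicon`: a list of character vectors
#'   `anatomy`, `malignancy`, `density`, `metastasis`, `descriptor`,
#'   `conjunction`.
#' @export
#' @examples
#' lex <- load_lexicon()
#' "肺" %in% lex$anatomy
load_lexicon <- function(path = default_lexicon_path()) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  categories <- c("anatomy", "malignancy", "density", "metastasis",
                  "descriptor", "conjunction")
  lex <- stats::setNames(rep(list(character(0)), length(categories)), categories)
  for (i in idx) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[[1]]) || !nzchar(parts[[2]])) {
      abort(paste0("malformed lexicon row on line ", i,
                   " (expected term<TAB>category): ", lines[[i]]))
    }
    term <- trimws(parts[[1]])
    cat <- trimws(parts[[2]])
    if (!cat %in% categories) {
      abort(paste0("unknown lexicon category '", cat, "' on line ", i))
    }
    if (str_detect(term, "[。；;！？\n]")) {
      abort(paste0("lexicon term contains a sentence delimiter on line ", i))
    }
    lex[[cat]] <- c(lex[[cat]], term)
  }
  lex <- lapply(lex, function(v) unique(v))
  empty <- categories[vapply(lex, length, integer(1)) == 0L]
  if (length(empty)) {
    abort(paste0("lexicon is missing required category(ies): ",
                 paste(empty, collapse = ", ")))
  }
  structure(lex, class = "onco_lexicon")
}

#' @export
print.onco_lexicon <- function(x, ...) {
  cat("<onco_lexicon>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %d terms\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Path to the shipped default lexicon
#' @return file path of the packaged lexicon TSV.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "default_lexicon.tsv", package = "onconer",
              mustWork = TRUE)
}

#' Laterality variants of a site name
#'
#' Chinese reports interchangeably write 左肺门 and 左侧肺门 (left hilum) for
#' the same site. The only rewriting applied is insertion/deletion of 侧 after
#' a leading 左 or 右; sites without a laterality prefix are returned alone.
#'
#' @param site non-empty site string.
#' @return character vector: the site plus its 侧-variants (no duplicates).
#' @export
#' @examples
#' expand_site_variants("左肺门") # 左肺门 左侧肺门
expand_site_variants <- function(site) {
  stopifnot(is.character(site), length(site) == 1L, nzchar(site))
  out <- site
  if (str_detect(site, "^[左右]侧.")) {         # 左侧X / 右侧X
    out <- c(out, paste0(str_sub(site, 1, 1), str_sub(site, 3)))
  } else if (str_detect(site, "^[左右][^侧]")) { # 左X / 右X
    out <- c(out, paste0(str_sub(site, 1, 1), "侧", str_sub(site, 2)))
  }
  unique(out)
}

# canonical form: width-folded, 左侧X/右侧X collapsed to 左X/右X
canonical_site <- function(site) {
  site <- fold_width(site)
  ifelse(str_detect(site, "^[左右]侧."),
         paste0(str_sub(site, 1, 1), str_sub(site, 3)),
         site)
}

#' Is one site a proper anatomical part of another?
#'
#' String containment test used to refine an approximate primary site (肺) to
#' a specific one (左肺上叶): `specific` is a part of `approximate` when the
#' approximate name — or a laterality-stripped form of it — occurs inside the
#' specific name. Laterality spelling variants of the same site (左肺门 vs
#' 左侧肺门) are not parts of each other, and a part must have a strictly
#' longer name than the whole, so refinement can only move toward more
#' specific sites.
#'
#' @param specific candidate finer site string.
#' @param approximate candidate coarser site string.
#' @return single logical.
#' @export
#' @examples
#' is_part_of("左肺上叶", "肺") # TRUE
#' is_part_of("肺", "肺")       # FALSE
is_part_of <- function(specific, approximate) {
  stopifnot(nzchar(specific), nzchar(approximate))
  if (specific == approximate) return(FALSE)
  if (canonical_site(specific) == canonical_site(approximate)) return(FALSE)
  if (str_length(specific) <= str_length(approximate)) return(FALSE)
  forms <- unique(c(expand_site_variants(approximate),
                    canonical_site(approximate),
                    strip_laterality(approximate)))
  any(str_detect(specific, fixed(forms)))
}

# drop a leading 左/右/左侧/右侧 prefix
strip_laterality <- function(site) {
  str_replace_all(site, "^[左右]侧?", "")
}
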