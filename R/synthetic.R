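#' Configuration for the synthetic report generator
#'
#' The generator emulates the structure of annotated Chinese diagnostic
#' imaging corpora: multi-sentence reports with about one primary tumor site
#' per report, a size mention in ~60% of reports, and on average ~2.5
#' metastatic site entities per report, written with malignancy indicators,
#' measurement expressions and metastasis keywords. Adversarial probabilities
#' inject the documented hard cases — coordination-free compound phrases,
#' double-negated metastasis statements and out-of-dictionary anatomy — and
#' tag the affected documents so tests can partition in-grammar from
#' out-of-grammar text. All adversarial probabilities default to 0: the
#' default corpus is fully in-grammar.
#'
#' @param n_docs number of documents.
#' @param seed integer seed; generation is deterministic given
#'   (config, seed, lexicon).
#' @param sentences_per_doc inclusive range of sentences per report.
#' @param p_size_mention probability a report carries a size mention.
#' @param meta_sites_per_doc inclusive range of metastatic gold entities.
#' @param p_conjunction_list probability a metastasis clause is a coordinated
#'   list with an elided shared head.
#' @param p_refinement probability the primary site is written as an
#'   approximate organ plus a later specific sentence (exercising
#'   refinement).
#' @param p_double_negation probability of a 转移不除外-style clause (tag
#'   `double_negation`).
#' @param p_compound_no_conjunction probability of a compound multi-site
#'   phrase with no conjunction (tag `compound`; the gold lists the true
#'   split sites, which the extractor is expected to miss).
#' @param p_unknown_anatomy probability of a metastatic site absent from the
#'   lexicon (tag `unknown_anatomy`).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_docs = 200, seed = 42,
                             sentences_per_doc = c(5, 25),
                             p_size_mention = 0.6,
                             meta_sites_per_doc = c(0, 5),
                             p_conjunction_list = 0.3,
                             p_refinement = 0.3,
                             p_double_negation = 0,
                             p_compound_no_conjunction = 0,
                             p_unknown_anatomy = 0) {
  probs <- c(p_size_mention, p_conjunction_list, p_refinement,
             p_double_negation, p_compound_no_conjunction, p_unknown_anatomy)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  stopifnot(length(sentences_per_doc) == 2L,
            sentences_per_doc[1] <= sentences_per_doc[2],
            length(meta_sites_per_doc) == 2L,
            meta_sites_per_doc[1] <= meta_sites_per_doc[2],
            n_docs >= 0)
  structure(list(n_docs = n_docs, seed = seed,
                 sentences_per_doc = as.integer(sentences_per_doc),
                 p_size_mention = p_size_mention,
                 meta_sites_per_doc = as.integer(meta_sites_per_doc),
                 p_conjunction_list = p_conjunction_list,
                 p_refinement = p_refinement,
                 p_double_negation = p_double_negation,
                 p_compound_no_conjunction = p_compound_no_conjunction,
                 p_unknown_anatomy = p_unknown_anatomy),
            class = "generator_config")
}

load_templates <- function(path = system.file("extdata",
                                              "report_templates.tsv",
                                              package = "onconer",
                                              mustWork = TRUE)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(slot = vapply(parts, `[[`, character(1), 1),
         template = vapply(parts, `[[`, character(1), 2))
}

fill_template <- function(template, values) {
  for (nm in names(values)) {
    template <- str_replace_all(template, fixed(paste0("{", nm, "}")),
                                values[[nm]])
  }
  template
}

# vocabulary pools used by the generator; all in the default lexicon except
# the deliberately unknown sites
gen_pools <- function() {
  list(
    specific_primary = c("左肺上叶", "左肺下叶", "右肺上叶", "右肺中叶",
                         "右肺下叶", "左乳", "右乳", "肝左叶", "肝右叶",
                         "左肺门", "右肺门"),
    organ_pairs = list(
      c("肺", "左肺上叶"), c("肺", "右肺下叶"), c("肺", "右肺中叶"),
      c("肺", "左肺下叶"), c("肝", "肝左叶"), c("肝", "肝右叶")),
    malignancy = c("癌", "恶性肿瘤", "MT", "CA"),
    density = c("高密度影", "低密度影", "不规则团块", "软组织密度灶"),
    meta_organ = c("肝", "骨", "脑", "脾", "胸膜", "左肾", "右肾",
                   "双侧肾上腺", "腹膜后", "颅内", "左肺", "右肺"),
    lymph_region = c("纵隔", "盆腔", "腹腔"),
    lymph_prefix = c("肺门", "前纵隔", "腋窝", "锁骨上", "颈部", "肝门",
                     "脾门"),
    descriptors = c("多发肿大", "多发", "散在", "数枚"),
    compound_pairs = list(c("右肺门", "纵隔"), c("左肺门", "前纵隔")),
    unknown_sites = c("胰尾", "腘窝", "骶髂关节", "斜坡")
  )
}

# one random size expression: dims as written plus the expected normalized form
gen_size_string <- function() {
  ndim <- sample(1:3, 1)
  value_raw <- vapply(seq_len(ndim), function(i) {
    if (stats::runif(1) < 0.5) as.character(sample(1:9, 1))
    else sprintf("%.1f", stats::runif(1, 0.5, 9.9))
  }, character(1))
  units <- vapply(seq_len(ndim), function(i) {
    if (i == ndim) sample(c("CM", "cm", "MM"), 1)
    else if (stats::runif(1) < 0.3) sample(c("CM", "MM"), 1)
    else ""
  }, character(1))
  seps <- if (ndim > 1) sample(c("×", "x", "X", "*"), ndim - 1,
                               replace = TRUE) else character(0)
  raw <- value_raw[1]
  if (nzchar(units[1])) raw <- paste0(raw, units[1])
  for (i in seq_len(ndim - 1)) {
    raw <- paste0(raw, seps[i], value_raw[i + 1], units[i + 1])
  }
  dims <- tibble(value_raw = value_raw,
                 value = as.numeric(value_raw),
                 unit = ifelse(nzchar(units), tolower(units), "unspecified"))
  list(raw = raw, normalized = normalize_size(dims))
}

#' Generate a synthetic annotated corpus
#'
#' Assembles each report from templates (a packaged, user-replaceable TSV): a
#' primary clause (specific site + malignancy indicator, or an approximate
#' organ clause plus a later specific sentence exercising refinement), an
#' optional size clause carrying a density indicator and a grammar-sampled
#' measurement next to a laterality variant of the primary site, metastasis
#' clauses (descriptor-padded sites, coordinated lists with elided heads, and
#' the configured adversarial shapes), and neutral filler sentences. The gold
#' annotation records exactly the entities the extraction rules are meant to
#' return — for adversarial documents, the true entities the rules are known
#' to miss.
#'
#' @param config a [generator_config()].
#' @param lexicon an `onco_lexicon` (the shipped default pools assume the
#'   default lexicon).
#' @return list with class `onco_corpus`: `documents` (tibble `id`, `text`),
#'   `gold` (tibble `id` + three entity list-columns), `tags` (tibble `id`,
#'   `tags` list-column of character vectors).
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(n_docs = 3, seed = 1))
#' corp$documents$text[1]
generate_corpus <- function(config = generator_config(),
                            lexicon = load_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_docs == 0L) {
    return(structure(list(
      documents = tibble(id = character(0), text = character(0)),
      gold = tibble(id = character(0), primary_sites = list(),
                    primary_sizes = list(), metastatic_sites = list()),
      tags = tibble(id = character(0), tags = list())),
      class = "onco_corpus"))
  }
  tpl <- load_templates()
  pools <- gen_pools()
  sample_range <- function(rng) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  pick_tpl <- function(slot) {
    cand <- tpl$template[tpl$slot == slot]
    cand[[sample.int(length(cand), 1)]]
  }
  withr::with_seed(config$seed, {
    docs <- vector("list", config$n_docs)
    golds <- vector("list", config$n_docs)
    tags <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      doc_tags <- character(0)
      sentences <- character(0)
      ## --- primary clause -------------------------------------------------
      mal <- sample(pools$malignancy, 1)
      if (stats::runif(1) < config$p_refinement) {
        pair <- pools$organ_pairs[[sample.int(length(pools$organ_pairs), 1)]]
        primary <- pair[2]
        sentences <- c(sentences,
                       fill_template(pick_tpl("primary_approx"),
                                     list(organ = pair[1], mal = mal)),
                       fill_template(pick_tpl("primary_specific"),
                                     list(specific = primary)))
      } else {
        primary <- sample(pools$specific_primary, 1)
        sentences <- c(sentences,
                       fill_template(pick_tpl("primary_direct"),
                                     list(site = primary, mal = mal)))
      }
      gold_primary <- primary
      ## --- size clause ----------------------------------------------------
      gold_sizes <- character(0)
      if (stats::runif(1) < config$p_size_mention) {
        sz <- gen_size_string()
        variants <- expand_site_variants(primary)
        site_form <- variants[[sample.int(length(variants), 1)]]
        sentences <- c(sentences,
                       fill_template(pick_tpl("size"),
                                     list(site = site_form,
                                          density = sample(pools$density, 1),
                                          size = sz$raw)))
        gold_sizes <- sz$normalized
      }
      ## --- metastasis clauses ---------------------------------------------
      k <- sample_range(config$meta_sites_per_doc)
      gold_meta <- character(0)
      organ_pool <- setdiff(pools$meta_organ, primary)
      region_pool <- pools$lymph_region
      prefix_pool <- pools$lymph_prefix
      add_meta_sentence <- function(phrase, negated = FALSE) {
        slot <- if (negated) "meta_negation" else "meta_sentence"
        sentences <<- c(sentences,
                        fill_template(pick_tpl(slot), list(phrase = phrase)))
      }
      if (k >= 2 && stats::runif(1) < config$p_conjunction_list &&
          length(prefix_pool) >= 2) {
        pr <- sample(prefix_pool, 2)
        prefix_pool <- setdiff(prefix_pool, pr)
        conj <- sample(c("及", "、"), 1)  # 及 or 、
        phrase <- paste0(pr[1], conj, pr[2],
                         sample(c("", "多发肿大"), 1),
                         "淋巴结")   # [desc?]淋巴结
        add_meta_sentence(phrase)
        gold_meta <- c(gold_meta, paste0(pr, "淋巴结"))
        k <- k - 2L
      }
      dn_pending <- stats::runif(1) < config$p_double_negation
      while (k > 0L) {
        if (stats::runif(1) < 0.35 && length(region_pool)) {
          region <- sample(region_pool, 1)
          region_pool <- setdiff(region_pool, region)
          desc <- sample(c("多发肿大", "小",
                           "数枚"), 1)
          phrase <- paste0(region, "内", desc, "淋巴结")
          add_meta_sentence(phrase)
          gold_meta <- c(gold_meta, paste0(region, "内淋巴结"))
        } else if (length(organ_pool)) {
          site <- sample(organ_pool, 1)
          organ_pool <- setdiff(organ_pool, site)
          if (dn_pending) {
            phrase <- paste0(site, "多发可疑小结节")
            add_meta_sentence(phrase, negated = TRUE)
            doc_tags <- c(doc_tags, "double_negation")
            dn_pending <- FALSE
          } else {
            desc <- sample(pools$descriptors, 1)
            phrase <- paste0(site, desc, "结节")
            add_meta_sentence(phrase)
          }
          gold_meta <- c(gold_meta, site)
        } else break
        k <- k - 1L
      }
      if (stats::runif(1) < config$p_compound_no_conjunction) {
        cp <- pools$compound_pairs[[sample.int(length(pools$compound_pairs),
                                               1)]]
        phrase <- paste0(cp[1], cp[2], "多发肿大",
                         "淋巴结")
        add_meta_sentence(phrase)
        gold_meta <- c(gold_meta, paste0(cp, "淋巴结"))
        doc_tags <- c(doc_tags, "compound")
      }
      if (stats::runif(1) < config$p_unknown_anatomy) {
        usite <- sample(pools$unknown_sites, 1)
        add_meta_sentence(paste0(usite, "结节"))
        gold_meta <- c(gold_meta, usite)
        doc_tags <- c(doc_tags, "unknown_anatomy")
      }
      ## --- fillers ---------------------------------------------------------
      target_n <- sample_range(config$sentences_per_doc)
      n_fill <- max(0L, target_n - length(sentences))
      fillers <- tpl$template[tpl$slot == "filler"]
      if (n_fill > 0L) {
        sentences <- c(sentences,
                       sample(fillers, n_fill, replace = TRUE))
      }
      docs[[d]] <- tibble(id = sprintf("doc%04d", d),
                          text = paste(sentences, collapse = ""))
      golds[[d]] <- tibble(id = sprintf("doc%04d", d),
                           primary_sites = list(gold_primary),
                           primary_sizes = list(gold_sizes),
                           metastatic_sites = list(unique(gold_meta)))
      tags[[d]] <- tibble(id = sprintf("doc%04d", d),
                          tags = list(unique(doc_tags)))
    }
    structure(list(documents = bind_rows(docs), gold = bind_rows(golds),
                   tags = bind_rows(tags)),
              class = "onco_corpus")
  })
}

#' @export
print.onco_corpus <- function(x, ...) {
  cat("<onco_corpus> ", nrow(x$documents), " documents\n", sep = "")
  if (nrow(x$gold)) {
    cat(sprintf("  mean gold entities/doc: primary %.2f, size %.2f, meta %.2f\n",
                mean(lengths(x$gold$primary_sites)),
                mean(lengths(x$gold$primary_sizes)),
                mean(lengths(x$gold$metastatic_sites))))
  }
  invisible(x)
}

#' Write a synthetic corpus to JSONL files
#'
#' @param corpus an `onco_corpus`.
#' @param dir output directory (created if needed); writes `docs.jsonl`,
#'   `gold.jsonl`, `tags.jsonl`.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "onco_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_jsonl(corpus$documents, file.path(dir, "docs.jsonl"))
  write_jsonl(corpus$gold, file.path(dir, "gold.jsonl"))
  write_jsonl(corpus$tags, file.path(dir, "tags.jsonl"))
  invisible(dir)
}
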