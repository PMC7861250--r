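test_that("the size grammar matches all canonical measurement formats", {
  cases <- list(
    list(s = "5x4x3CM", norm = "5CMx4CMx3CM",
         units = c("unspecified", "unspecified", "cm")),
    list(s = "2.0X2CM", norm = "2.0CMx2CM",
         units = c("unspecified", "cm")),
    list(s = "5CM*5MM", norm = "5CMx5MM", units = c("cm", "mm")),
    list(s = "不足 5CM", norm = "5CM", units = "cm")
  )
  for (cs in cases) {
    m <- extract_size_mentions(cs$s)
    expect_equal(nrow(m), 1L, info = cs$s)
    expect_equal(m$normalized, cs$norm, info = cs$s)
    expect_equal(m$dims[[1]]$unit, cs$units, info = cs$s)
  }
  expect_equal(extract_size_mentions("不足 5CM")$qualifier, "不足")
})

test_that("bare numbers and dates are not size expressions", {
  expect_equal(nrow(extract_size_mentions("2018年3月复查")), 0L)
  expect_equal(nrow(extract_size_mentions("共3枚")), 0L)
  expect_equal(nrow(detect_size_sentences(doc1("2019年12月行手术。"))), 0L)
  expect_equal(nrow(detect_size_sentences(doc1("无数字文本。"))), 0L)
})

test_that("the worked sentence is detected and parsed exactly", {
  sent <- "左肺上叶示一不规则软组织密度灶,大小约1.3CM × 1.7CM,边缘分叶,可见强化。"
  det <- detect_size_sentences(doc1(sent))
  expect_equal(nrow(det), 1L)
  m <- extract_size_mentions(sent)
  expect_equal(nrow(m), 1L)
  expect_equal(m$normalized, "1.3CMx1.7CM")
  expect_equal(m$qualifier, "约")
  expect_equal(m$dims[[1]]$value, c(1.3, 1.7))
  expect_equal(m$dims[[1]]$unit, c("cm", "cm"))
  # raw equals the sentence substring at the span
  expect_equal(stringr::str_sub(sent, m$start + 1L, m$end), m$raw)
})

test_that("primary-relatedness filter uses site variants and ranks density first", {
  sents <- split_sentences(doc1(paste0(
    "左侧肺门见高密度影,大小约2CM×1CM。",
    "肝内低密度灶,大小约3CM。",
    "左肺门病灶较前稍大。")))
  sents$id <- "d1"
  prim <- tibble::tibble(id = "d1", surface = "左肺门",
                         normalized = "左肺门", sentence_index = NA_integer_)
  kept <- filter_primary_related(sents, prim, default_lex)
  expect_equal(sort(kept$sentence_index), c(1L, 3L))
  expect_equal(kept$sentence_index[1], 1L)  # density sentence ranks first

  expect_equal(nrow(filter_primary_related(sents,
                                           prim[0, , drop = FALSE],
                                           default_lex)), 0L)
})

test_that("unit normalization propagates the trailing unit by default", {
  m <- extract_size_mentions("5x4x3CM")
  expect_equal(normalize_size(m$dims[[1]], policy = "propagate"),
               "5CMx4CMx3CM")
  expect_equal(normalize_size(m$dims[[1]], policy = "as-parsed"), "5x4x3CM")
  expect_equal(normalize_size(extract_size_mentions("5CM")$dims[[1]]), "5CM")
})

test_that("parse -> normalize -> re-parse is a fixed point", {
  for (s in c("5x4x3CM", "2.0X2CM", "5CM*5MM", "不足 5CM",
              "大小约1.3CM × 1.7CM")) {
    norm <- extract_size_mentions(s)$normalized
    again <- extract_size_mentions(norm)
    expect_equal(again$normalized, norm, info = s)
  }
})

test_that("full size pipeline composes the three steps", {
  text <- paste0("左肺上叶见肿块,考虑肺癌。",
                 "左肺上叶示一不规则软组织密度灶,大小约1.3CM × 1.7CM,边缘分叶,可见强化。",
                 "肝内小结节,大小约2CM×1CM,考虑转移。")
  sz <- extract_primary_sizes(doc1(text), lexicon = default_lex)
  expect_equal(sz$normalized, "1.3CMx1.7CM")

  # size syntax only in a sentence naming no primary variant -> nothing
  text2 <- "左肺上叶见肿块,考虑肺癌。肝内低密度灶,大小约2CM×1CM,考虑转移。"
  expect_equal(nrow(extract_primary_sizes(doc1(text2), lexicon = default_lex)),
               0L)
  # no size syntax at all
  expect_equal(nrow(extract_primary_sizes(doc1("左肺癌可能。"),
                                          lexicon = default_lex)), 0L)
})

test_that("matcher agrees with a brute-force scanner on generated strings", {
  strings <- random_size_strings(1000, seed = 97)
  for (s in strings) {
    got <- extract_size_mentions(s)
    want <- brute_force_size_spans(s)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$end, want$end, info = s)
    }
  }
})
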