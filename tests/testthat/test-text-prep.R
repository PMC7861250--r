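test_that("sentence splitting keeps delimiters and reconstructs the text", {
  s <- split_sentences(doc1("左肺占位。纵隔淋巴结转移。"))
  expect_equal(nrow(s), 2L)
  expect_equal(s$sentence, c("左肺占位。", "纵隔淋巴结转移。"))
  expect_equal(paste(s$sentence, collapse = ""), "左肺占位。纵隔淋巴结转移。")

  one <- split_sentences(doc1("无分隔符的文本"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 0L)
  expect_equal(one$end, stringr::str_length("无分隔符的文本"))

  expect_equal(nrow(split_sentences(doc1(""))), 0L)
})

test_that("commas do not split; all five delimiters and newline do", {
  s <- split_sentences(doc1("病灶,大小约5CM,边缘清。第二句；第三句;第四句！第五句？第六句\n第七句"))
  expect_equal(nrow(s), 7L)
  expect_true(startsWith(s$sentence[1], "病灶,"))
})

test_that("split spans round-trip on randomly delimited text (fuzz)", {
  withr::with_seed(21, {
    clauses <- c("左肺上叶见肿块", "大小约5CM", "考虑转移", "请结合临床",
                 "纵隔淋巴结肿大", "余未见异常")
    delims <- c("。", "；", ";", "！", "？", "\n")
    for (rep in 1:25) {
      n <- sample(1:6, 1)
      text <- paste0(paste0(sample(clauses, n, replace = TRUE),
                            sample(delims, n, replace = TRUE)),
                     collapse = "")
      s <- split_sentences(doc1(text))
      expect_equal(paste(s$sentence, collapse = ""), text)
      # spans non-overlapping, strictly increasing, and exact
      expect_true(all(diff(s$start) > 0))
      expect_true(all(s$start < s$end))
      for (i in seq_len(nrow(s))) {
        expect_equal(stringr::str_sub(text, s$start[i] + 1L, s$end[i]),
                     s$sentence[i])
      }
    }
  })
})

test_that("segmentation keeps dictionary terms unbroken with longest match", {
  toks <- segment("左肺上叶示一不规则软组织密度灶", default_lex)
  expect_true("左肺上叶" %in% toks$token)
  expect_equal(paste(toks$token, collapse = ""),
               "左肺上叶示一不规则软组织密度灶")

  # nested terms: 肺 is inside 左肺门; the longer term must win
  toks2 <- segment("左肺门影增大", default_lex)
  expect_true("左肺门" %in% toks2$token)
  expect_false("肺门" %in% toks2$token[toks2$is_term])
})

test_that("longest-match agrees with brute force over all nested lexicon hits", {
  sent <- "右肺门及前纵隔示左肺上叶旁肿块"
  toks <- segment(sent, default_lex)
  expect_equal(paste(toks$token, collapse = ""), sent)
  # brute force: every anatomy term occurring in the sentence that is not a
  # strict substring of a longer occurring term must appear as one token
  occ <- default_lex$anatomy[vapply(default_lex$anatomy, function(t)
    grepl(t, sent, fixed = TRUE), logical(1))]
  maximal <- occ[vapply(occ, function(t)
    !any(occ != t & vapply(occ, function(o)
      grepl(t, o, fixed = TRUE) && o != t &&
        grepl(o, sent, fixed = TRUE), logical(1))), logical(1))]
  for (t in maximal) expect_true(t %in% toks$token, info = t)
})

test_that("segment output concatenation equals input on generated sentences", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      text <- paste(sample(c(default_lex$anatomy[1:30], "示", ",", "影",
                             "増大", "5CM"), sample(3:8, 1), replace = TRUE),
                    collapse = "")
      toks <- segment(text, default_lex)
      expect_equal(paste(toks$token, collapse = ""), text)
    }
  })
})

test_that("descriptor stripping removes descriptive wording, idempotently", {
  expect_equal(strip_descriptive_words("纵隔内多发肿大淋巴结", default_lex),
               "纵隔内淋巴结")
  expect_equal(strip_descriptive_words("纵隔内小淋巴结", default_lex),
               "纵隔内淋巴结")
  expect_equal(strip_descriptive_words("纵隔淋巴结", default_lex),
               "纵隔淋巴结")
  phrases <- c("纵隔内多发肿大淋巴结", "肝多发散在结节", "左肺门数枚小淋巴结")
  once <- strip_descriptive_words(phrases, default_lex)
  expect_equal(strip_descriptive_words(once, default_lex), once)
})

test_that("width folding maps full-width ASCII and preserves case", {
  expect_equal(fold_width("１.３ＣＭ×１.７ｃｍ"), "1.3CM×1.7cm")
  expect_equal(fold_width("癌ＭＴ"), "癌MT")
  expect_equal(fold_width(""), "")
})
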