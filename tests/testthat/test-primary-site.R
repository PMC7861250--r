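test_that("malignancy filter keeps exactly the indicator sentences", {
  d <- doc1("左肺上叶见肿块,考虑肺癌。双侧胸廓对称。病灶性质待定,MT不除外。")
  kept <- filter_malignancy_sentences(d, default_lex)
  expect_equal(kept$sentence_index, c(1L, 3L))

  # MT / CA match case-insensitively, also in full width
  expect_equal(nrow(filter_malignancy_sentences(doc1("考虑mt可能。"),
                                                default_lex)), 1L)
  expect_equal(nrow(filter_malignancy_sentences(doc1("考虑ＣＡ可能。"),
                                                default_lex)), 1L)
  expect_equal(nrow(filter_malignancy_sentences(doc1("未见明显异常。"),
                                                default_lex)), 0L)
})

test_that("anatomy mentions are matched inside larger words", {
  m <- match_anatomy_mentions("肺癌可能。", default_lex)
  expect_equal(m$surface[1], "肺")

  m2 <- match_anatomy_mentions("右乳炎性乳癌术后。", default_lex)
  expect_equal(m2$surface[1], "右乳")

  expect_equal(nrow(match_anatomy_mentions("未见明显异常。", default_lex)), 0L)

  # surface always equals the sentence substring at the span
  sent <- "左肺上叶及纵隔内多发肿大淋巴结影。"
  m3 <- match_anatomy_mentions(sent, default_lex)
  for (i in seq_len(nrow(m3))) {
    expect_equal(stringr::str_sub(sent, m3$start[i] + 1L, m3$end[i]),
                 m3$surface[i])
  }
})

test_that("approximate sites are refined to finer parts found elsewhere", {
  text <- "肺癌术后改变。左肺上叶见不规则肿块影。"
  approx <- match_anatomy_mentions("肺癌术后改变。", default_lex)[1, ]
  refined <- refine_primary_site(approx, text, default_lex)
  expect_equal(refined$surface, "左肺上叶")

  # identity fallback when nothing finer exists
  same <- refine_primary_site(approx, "肺癌术后改变。余未见异常。",
                              default_lex)
  expect_equal(same$surface, "肺")

  # unrelated finer sites are not picked up
  approx_ru <- match_anatomy_mentions("乳癌术后。", default_lex)[1, ]
  expect_equal(refine_primary_site(approx_ru,
                                   "乳癌术后。左肺上叶见结节。",
                                   default_lex)$surface, "乳")
})

test_that("refinement skips metastasis sentences by default", {
  text <- "肺癌可能。左肺下叶结节,考虑转移。左肺上叶见肿块影。"
  approx <- match_anatomy_mentions("肺癌可能。", default_lex)[1, ]
  expect_equal(refine_primary_site(approx, text, default_lex)$surface,
               "左肺上叶")
  expect_equal(refine_primary_site(approx, text, default_lex,
                                   skip_metastasis = FALSE)$surface,
               "左肺下叶")
})

test_that("primary extraction takes the first malignancy-related site", {
  d <- doc1("右乳见肿块,考虑乳癌。肝内低密度灶。")
  p <- extract_primary_sites(d, default_lex)
  expect_equal(p$normalized, "右乳")

  expect_equal(nrow(extract_primary_sites(doc1("双肺纹理清晰。"),
                                          default_lex)), 0L)

  # a sentence with both an indicator and a metastasis keyword is excluded
  d2 <- doc1("肝内见低密度灶,考虑恶性肿瘤转移。余未见异常。")
  expect_equal(nrow(extract_primary_sites(d2, default_lex)), 0L)
})

test_that("two-primary reports yield only the first site by default", {
  text <- paste0("右乳炎性乳癌术后;",
                 "右肺中叶磨玻璃结节伴轻度糖代谢增高,考虑为原发性MT可能。")
  p <- extract_primary_sites(doc1(text), default_lex)
  expect_equal(p$normalized, "右乳")

  # the multi-primary extension recovers the second site too
  p2 <- extract_primary_sites(doc1(text), default_lex, multi_primary = TRUE)
  expect_setequal(p2$normalized, c("右乳", "右肺中叶"))
})

test_that("enlarging the anatomy lexicon never loses candidate mentions", {
  sent <- "胸下段食管管壁增厚,符合食管癌表现。"
  small <- default_lex
  n_small <- nrow(match_anatomy_mentions(sent, small))
  big <- small
  big$anatomy <- c(big$anatomy, "胸下段食管")
  m_big <- match_anatomy_mentions(sent, big)
  expect_gte(nrow(m_big), n_small)
  expect_true("胸下段食管" %in% m_big$surface)
})
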