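# shared fixtures: one lexicon load per test run
default_lex <- load_lexicon()

doc1 <- function(text, id = "d1") tibble::tibble(id = id, text = text)

# independent brute-force matcher for the size grammar: scans every substring,
# keeps anchored full matches that qualify as size expressions (>= 2 dims or a
# unit), and assembles the leftmost-longest non-overlapping cover
brute_force_size_spans <- function(text) {
  folded <- fold_width(text)
  pat <- paste0("^", onconer:::size_pattern(), "$")
  n <- stringr::str_length(folded)
  spans <- list()
  i <- 1L
  while (i <= n) {
    best_end <- 0L
    for (j in seq(i, n)) {
      piece <- stringr::str_sub(folded, i, j)
      g <- stringr::str_match(piece, pat)[1, ]
      if (is.na(g[1])) next
      vals <- g[c(3, 6, 9)]; units <- g[c(4, 7, 10)]
      ndim <- sum(!is.na(vals))
      if (ndim == 0L) next
      if (ndim >= 2L || any(!is.na(units[!is.na(vals)]))) best_end <- j
    }
    if (best_end > 0L) {
      spans[[length(spans) + 1L]] <- c(start = i - 1L, end = best_end)
      i <- best_end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(spans)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  tibble::as_tibble(do.call(rbind, spans))
}

# random strings mixing valid measurements with distractor text
random_size_strings <- function(n, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      pieces <- vapply(seq_len(sample(1:4, 1)), function(j) {
        kind <- sample(c("size", "number", "noise", "date"), 1,
                       prob = c(0.4, 0.2, 0.3, 0.1))
        switch(kind,
          size = {
            nd <- sample(1:3, 1)
            vals <- vapply(seq_len(nd), function(k)
              if (runif(1) < 0.5) as.character(sample(1:9, 1))
              else sprintf("%.1f", runif(1, 0.3, 9.9)), character(1))
            units <- vapply(seq_len(nd), function(k)
              if (k == nd || runif(1) < 0.4)
                sample(c("CM", "cm", "MM", "mm", ""), 1)
              else "", character(1))
            seps <- sample(c("×", "x", "X", "*"), max(0, nd - 1),
                           replace = TRUE)
            out <- paste0(vals[1], units[1])
            for (k in seq_len(nd - 1)) {
              out <- paste0(out, seps[k], vals[k + 1], units[k + 1])
            }
            paste0(sample(c("", "约", "不足 "), 1), out)
          },
          number = as.character(sample(1:3000, 1)),
          noise = paste(sample(c("病灶", "边缘", "可见",
                                 "大小", ",", "。", " "),
                               sample(1:3, 1), replace = TRUE), collapse = ""),
          date = paste0(sample(2000:2025, 1), "年",
                        sample(1:12, 1), "月"))
      }, character(1))
      paste(pieces, collapse = "")
    }, character(1))
  })
}
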