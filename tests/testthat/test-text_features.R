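sust_terms <- c("sustaining", "sustainment", "sustainability", "beyond funding")

test_that("tokenizer lowercases, keeps internal hyphens, and finds sentences", {
  ts <- tokenize("Sustaining care. Beyond funding!")
  expect_identical(ts$tokens, c("sustaining", "care", "beyond", "funding"))
  expect_identical(ts$sentence_ends, c(2L, 4L))

  expect_identical(tokenize("state-funded plan")$tokens,
                   c("state-funded", "plan"))

  expect_error(tokenize(""), "empty")
  expect_error(tokenize("   "), "empty")

  # punctuation not followed by whitespace does not end a sentence (e.g. 3.5)
  ts2 <- tokenize("spent 3.5 million. more text")
  expect_identical(length(ts2$sentence_ends), 2L)
})

test_that("category counting is exact-token, ordered, and greedy longest-match", {
  expect_identical(count_category(tokenize("sustaining services beyond funding ends"),
                                  sust_terms), 2L)
  expect_identical(count_category(character(0), sust_terms), 0L)
  # phrase terms need adjacency in order
  expect_identical(count_category(tokenize("funding beyond sustainability"),
                                  sust_terms), 1L)
  # no stemming: inflections not in the lexicon do not match
  expect_identical(count_category(tokenize("sustain sustained sustains"),
                                  sust_terms), 0L)
  # greedy longest-match does not double-count inside a matched phrase
  expect_identical(count_category(c("beyond", "funding"),
                                  c("funding", "beyond funding")), 1L)
})

test_that("category counts match a brute-force enumeration oracle", {
  terms <- c("alpha", "beta gamma", "gamma", "delta epsilon zeta")
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta")
  withr::with_seed(7, {
    for (rep in 1:25) {
      tokens <- sample(vocab, sample(5:200, 1), replace = TRUE)
      expect_identical(count_category(tokens, terms),
                       oracle_count_terms(tokens, terms),
                       info = paste("rep", rep))
    }
  })
})

test_that("stylistic counts follow the packaged function-word list", {
  sp <- style_profile(tokenize("the state will expand services"))
  expect_identical(sp$function_word_count, 2L)   # the, will
  expect_identical(sp$future_tense_count, 1L)    # will expand
  expect_identical(sp$long_word_count, 1L)       # services (expand = 6 letters)
  expect_equal(sp$words_per_sentence, 5)

  # passive future counts: auxiliary continuation is allowed
  expect_identical(style_profile(tokenize("programs will be sustained"))$future_tense_count, 1L)
  # "going to" bigram
  expect_identical(style_profile(tokenize("we are going to expand"))$future_tense_count, 1L)
  # "will" followed by an article is not a future verb phrase
  expect_identical(style_profile(tokenize("where there is a will the way"))$future_tense_count, 0L)

  sp0 <- style_profile(tokenize("10 20 30"))
  expect_identical(sp0$function_word_count, 0L)
  expect_identical(sp0$future_tense_count, 0L)
  expect_identical(sp0$long_word_count, 0L)
})

test_that("feature vectors are length-normalized and duplication-invariant", {
  lex <- structure(list(sustainability = sust_terms), class = "keyword_lexicon")
  doc <- "sustaining plans aim at sustainability goals over ten years"  # 10 tokens? count
  ts <- tokenize(doc)
  expect_identical(length(ts$tokens), 9L)
  fv <- extract_features(doc, lex)
  expect_equal(fv$freq_sustainability, 2 / 9)

  # no lexicon hits
  fv0 <- extract_features("nothing matching here", lex)
  expect_equal(fv0$freq_sustainability, 0)

  # frequencies invariant under document duplication
  dd <- paste(doc, doc, sep = ". ")
  fv2 <- extract_features(dd, lex)
  for (col in grep("freq", names(fv), value = TRUE)) {
    expect_equal(fv2[[col]], fv[[col]], info = col)
  }

  # all frequencies in [0,1]
  freqs <- unlist(fv[grep("freq", names(fv))])
  expect_true(all(freqs >= 0 & freqs <= 1))
})

test_that("lexicon loading validates structure", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("category,term", "sustainability,sustaining",
               "sustainability,beyond funding", "rescue,naloxone"), f)
  lex <- load_lexicon(f)
  expect_named(lex, c("sustainability", "rescue"))
  expect_identical(lex$sustainability, c("sustaining", "beyond funding"))

  writeLines(c("category,term", "a,x", "a,x"), f)
  expect_error(load_lexicon(f), "duplicate")
  writeLines("category,term", f)
  expect_error(load_lexicon(f), "non-empty")
  writeLines(c("wrong,cols", "a,b"), f)
  expect_error(load_lexicon(f))

  # packaged default loads and covers the expected categories
  lex <- default_lexicon()
  expect_true(all(c("sustainability", "implementation", "evaluation",
                    "financial_strategies") %in% names(lex)))
  expect_true(all(sust_terms %in% lex$sustainability))
})

test_that("corpora load from directories and JSON-lines files", {
  d <- withr::local_tempdir()
  writeLines("First doc about sustaining care.", file.path(d, "a.txt"))
  writeLines("Second doc.", file.path(d, "b.txt"))
  corp <- read_corpus(d)
  expect_identical(corp$doc_id, c("a", "b"))

  jf <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"x","text":"one doc"}',
               '{"doc_id":"y","text":"two docs"}'), jf)
  corp2 <- read_corpus(jf)
  expect_identical(corp2$doc_id, c("x", "y"))
  expect_identical(corp2$text[1], "one doc")

  feats <- corpus_features(corp)
  expect_identical(nrow(feats), 2L)
  # deterministic column order: lexicon categories then style features
  expect_identical(tail(names(feats), 4),
                   c("function_word_freq", "future_tense_freq",
                     "long_word_freq", "words_per_sentence"))
})
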