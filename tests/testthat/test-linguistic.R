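# tokenizer, tagger, lexicons, one-hot encodings, vocabulary, frequencies

test_that("tokenizer lowercases and splits off punctuation", {
  expect_identical(tokenize("I am sad."), c("i", "am", "sad", "."))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("don't cry!"), c("don't", "cry", "!"))
  # token counts match an independent regex scan on random cleaned strings
  set.seed(9)
  for (i in 1:40) {
    x <- clean_text(paste(sample(c(random_words(6), ".", ",", "!"),
                                 sample(1:20, 1), replace = TRUE), collapse = " "))
    n_oracle <- length(gregexpr("[a-z']+|[[:punct:]]", tolower(x), perl = TRUE)[[1]])
    if (x == "") n_oracle <- 0L
    expect_length(tokenize(x), n_oracle)
  }
})

test_that("the part-of-speech inventory is 48 unique tags", {
  expect_length(ASHN_POS_TAGS, 48L)
  expect_identical(anyDuplicated(ASHN_POS_TAGS), 0L)
})

test_that("the rule tagger produces valid tags with a noun fallback", {
  expect_identical(pos_tag(c("the", "cat", "sat")), c("DT", "NN", "VBD"))
  expect_identical(pos_tag(character(0)), character(0))
  expect_identical(pos_tag("qzxvwt"), "NN")   # unseen word falls back to noun
  set.seed(4)
  for (i in 1:20) {
    toks <- tokenize(clean_text(paste(random_words(sample(1:15, 1)), collapse = " ")))
    tags <- pos_tag(toks)
    expect_length(tags, length(toks))
    expect_true(all(tags %in% ASHN_POS_TAGS))
  }
  # pluggable external tagger is validated
  expect_identical(pos_tag(c("a", "b"), tagger = function(t) rep("NN", length(t))),
                   c("NN", "NN"))
  expect_error(pos_tag("a", tagger = function(t) "BOGUS"), "invalid tag")
})

test_that("one-hot encodings round-trip and are exactly one-hot", {
  # exhaustive over all 48 tags and all 3 sentiment labels
  m <- encode_pos_onehot(ASHN_POS_TAGS)
  expect_identical(dim(m), c(48L, 48L))
  expect_true(all(rowSums(m) == 1))
  expect_identical(decode_pos_onehot(m), ASHN_POS_TAGS)
  s <- encode_sentiment_onehot(ASHN_SENTIMENTS)
  expect_identical(dim(s), c(3L, 3L))
  expect_true(all(rowSums(s) == 1))
  expect_identical(decode_sentiment_onehot(s), ASHN_SENTIMENTS)
  expect_identical(unname(encode_sentiment_onehot("negative")[1, ]), c(0, 0, 1))
  expect_error(encode_pos_onehot("NOPE"), "unknown")
  expect_identical(nrow(encode_pos_onehot(character(0))), 0L)
})

test_that("sentiment labelling uses the lexicon with a neutral default", {
  expect_identical(label_sentiment("hopeless"), "negative")
  expect_identical(label_sentiment("medication"), "positive")
  expect_identical(label_sentiment("zzxqv"), "neutral")
  expect_identical(label_sentiment(c("Hopeless", "BABY")), c("negative", "neutral"))
  expect_identical(label_sentiment(character(0)), character(0))
})

test_that("score-based external lexicons map to labels by strict majority", {
  td <- withr::local_tempdir()
  f <- file.path(td, "lex.tsv")
  writeLines(c("happy\t0.8\t0.1", "awful\t0.1\t0.9", "table\t0\t0",
               "mixed\t0.5\t0.5"), f)
  lex <- read_sentiment_lexicon(f)
  expect_identical(unname(lex[c("happy", "awful", "table", "mixed")]),
                   c("positive", "negative", "neutral", "neutral"))
  f2 <- file.path(td, "lex2.tsv")
  writeLines(c("good\tpositive", "bad\tnegative"), f2)
  expect_identical(unname(read_sentiment_lexicon(f2)["bad"]), "negative")
})

test_that("the symptom lexicon holds 9 categories and 76 unique keywords", {
  lex <- builtin_symptom_lexicon()
  expect_length(lex, 9L)
  expect_identical(sum(lengths(lex)), 76L)
  expect_true(all(vapply(lex, function(k) anyDuplicated(k) == 0L, logical(1))))
  # replaceable via JSON, with the structural contract enforced
  td <- withr::local_tempdir()
  f <- file.path(td, "sym.json")
  writeLines(as.character(jsonlite::toJSON(unclass(lex))), f)
  expect_length(read_symptom_lexicon(f), 9L)
  bad <- unclass(lex)
  bad[[1]] <- bad[[1]][-1]
  expect_error(validate_symptom_lexicon(bad), "76 keywords")
  expect_error(validate_symptom_lexicon(bad[-1]), "9 categories")
})

test_that("vocabulary retains words occurring strictly more than min_count", {
  corpus <- c(rep(list(rep("kept", 6L)), 1), rep(list(rep("edge", 5L)), 1),
              list(c("rare", "words")))
  v <- build_vocabulary(corpus, min_count = 5L)
  expect_true("kept" %in% names(v))
  expect_false("edge" %in% names(v))
  expect_identical(unname(v[c("UNK", "PAD")]), c(0L, 1L))
  expect_identical(encode_tokens(c("kept", "edge", "rare"), v)[2:3], c(0L, 0L))
  # monotone: raising the threshold never adds words
  set.seed(5)
  corpus <- replicate(30, random_words(sample(5:20, 1)), simplify = FALSE)
  v3 <- build_vocabulary(corpus, 3L)
  v6 <- build_vocabulary(corpus, 6L)
  expect_true(all(names(v6) %in% names(v3)))
  # empty after thresholding
  v_empty <- build_vocabulary(list("once"), 5L)
  expect_identical(names(v_empty), c("UNK", "PAD"))
})

test_that("frequency tables match a brute-force counter", {
  posts <- list(make_post("sad sad baby"))
  ft <- frequency_table(posts)
  expect_identical(ft$word, c("sad", "baby"))
  expect_identical(ft$count, c(2L, 1L))
  expect_identical(ft$polarity[1], "negative")
  expect_identical(nrow(frequency_table(list())), 0L)
  set.seed(6)
  posts <- lapply(1:12, function(i) {
    make_post(paste(random_words(sample(3:10, 1)), collapse = " "), id = paste0("p", i))
  })
  ft <- frequency_table(posts, top_k = 100L)
  oracle <- table(unlist(lapply(posts, `[[`, "tokens")))
  oracle <- oracle[!names(oracle) %in% c(".", ",", "!")]
  for (i in seq_len(nrow(ft))) {
    expect_identical(ft$count[i], as.integer(oracle[[ft$word[i]]]))
  }
  # counts are sorted and ties broken lexicographically
  expect_true(all(diff(ft$count) <= 0))
  # permutation invariance
  ft2 <- frequency_table(rev(posts), top_k = 100L)
  expect_identical(ft, ft2)
  expect_error(frequency_table(posts, top_k = 0L), "top_k")
})

test_that("title-field frequency tables clean and tokenize on the fly", {
  posts <- list(list(title = "Sad DAY!", tokens = c("ignored")),
                list(title = NA_character_, tokens = c("ignored")))
  ft <- frequency_table(posts, field = "title")
  expect_identical(sort(ft$word), c("day", "sad"))
})
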