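test_that("tokenization strips punctuation but keeps internal apostrophes", {
  expect_equal(tokenize("The cat, sat."), c("The", "cat", "sat"))
  expect_equal(tokenize("it's a man's hat —"),
               c("it's", "a", "man's", "hat"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("   \n\t "), character(0))
  expect_equal(tokenize("well-known fact"), c("well", "known", "fact"))
  expect_equal(tokenize("in 1984 yes"), c("in", "1984", "yes"))
})

test_that("tokenize is idempotent on its own output", {
  texts <- c("The cat, sat.", "it's a man's hat —",
             "um... so (pause) there's a - a house!")
  for (txt in texts) {
    once <- tokenize(txt)
    expect_equal(tokenize(paste(once, collapse = " ")), once)
  }
})

test_that("annotation flags stop words and reports OOV surfaces", {
  tab <- toy_table()
  stoplist <- c("a", "the", "is", "at")
  t1 <- annotate_tokens(c("the", "cat"), stoplist, tab, warn_oov = FALSE)
  expect_equal(t1$tokens$is_stop, c(TRUE, FALSE))
  expect_equal(t1$tokens$in_vocab, c(TRUE, TRUE))
  expect_equal(t1$oov_report, character(0))

  expect_warning(
    t2 <- annotate_tokens(c("zyzzyva", "cat"), stoplist, tab),
    "zyzzyva")
  expect_equal(t2$oov_report, "zyzzyva")
  expect_equal(t2$tokens$in_vocab, c(FALSE, TRUE))

  t3 <- annotate_tokens(character(0), stoplist, tab)
  expect_equal(nrow(t3$tokens), 0)
  expect_equal(t3$oov_report, character(0))
})

test_that("annotation preserves token order and count", {
  tab <- toy_table()
  toks <- c("dog", "the", "cat", "dog", "qqq")
  t <- annotate_tokens(toks, "the", tab, warn_oov = FALSE)
  expect_equal(t$tokens$surface, toks)
})

test_that("word count includes stop words and OOV words", {
  tab <- toy_table()
  t <- annotate_tokens(c("the", "cat", "sat"), c("a", "the", "is", "at"),
                       tab, warn_oov = FALSE)
  expect_equal(word_count(t), 3)
  expect_equal(word_count(t, include_stops = FALSE), 2)
  expect_equal(word_count(t, include_oov = FALSE), 2)  # "sat" is OOV here
  empty <- annotate_tokens(character(0), "the", tab)
  expect_equal(word_count(empty), 0)
  # invariant to the stoplist contents
  t2 <- annotate_tokens(c("the", "cat", "sat"), character(0), tab,
                        warn_oov = FALSE)
  expect_equal(word_count(t2), word_count(t))
})

test_that("CHAT files reduce to participant speech without markup", {
  cha <- withr::local_tempfile(fileext = ".cha")
  writeLines(c(
    "@Begin",
    "@Participants:\tPAR Participant, INV Investigator",
    "*INV:\tcan you describe the picture ?",
    "*PAR:\tthere is a <big> [/] big house and um a tree .",
    "%mor:\tdet|the n|house",
    "*PAR:\tthe man (i)s walking +...",
    "@End"), cha)
  txt <- read_chat(cha)
  toks <- tokenize(txt)
  expect_false(any(grepl("\\[|%|\\*|@", toks)))
  expect_true(all(c("house", "tree", "walking") %in% toks))
  expect_false("investigator" %in% tolower(toks))
  expect_false(any(toks == "INV"))
})
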