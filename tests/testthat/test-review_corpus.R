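test_that("polarity mismatch follows the rating/sentiment concordance rule", {
  # expected values enumerated by hand over all (rating, polarity) pairs
  grid <- expand.grid(rating = 1:5, polarity = c("positive", "negative"),
                      stringsAsFactors = FALSE)
  expected <- c(
    # positive: mismatched at 1-2 stars only
    TRUE, TRUE, FALSE, FALSE, FALSE,
    # negative: mismatched at 4-5 stars only
    FALSE, FALSE, FALSE, TRUE, TRUE
  )
  expect_equal(polarity_mismatch(grid$rating, grid$polarity), expected)
  expect_error(polarity_mismatch(5, NA_character_),
               class = "useis_validation_error")
})

test_that("duplicates of the same app/author/text are removed, one per extra copy", {
  corpus <- make_corpus(
    rating = c(5, 5, 4, 2, 1, 3),
    polarity = c("positive", "positive", "positive",
                 "negative", "negative", "negative"),
    text = c("love this app", "love this app", "pretty good",
             "meh not great", "crashes a lot", "average really"),
    author_id = c("u1", "u1", "u2", "u3", "u4", "u5")
  )
  # brute-force pairwise duplicate count on the 6-record fixture
  key <- paste(corpus$app_id, corpus$author_id, tolower(corpus$text))
  n_dup <- 0
  for (i in 1:5) for (j in (i + 1):6) if (key[i] == key[j]) n_dup <- n_dup + 1
  expect_equal(n_dup, 1)

  res <- apply_filters(corpus)
  expect_equal(nrow(res$corpus), 5)
  expect_equal(res$report$removed$duplicate, 1)
  expect_equal(res$report$retained, 5)
})

test_that("a clean corpus passes through untouched", {
  corpus <- make_corpus(rating = c(5, 4, 1), polarity = c("positive", "positive", "negative"))
  res <- apply_filters(corpus)
  expect_equal(as.data.frame(res$corpus), as.data.frame(corpus))
  expect_true(all(unlist(res$report$removed) == 0))
})

test_that("discordant rating/polarity reviews are removed as mismatches", {
  corpus <- make_corpus(rating = c(5, 5), polarity = c("negative", "positive"))
  res <- apply_filters(corpus)
  expect_equal(res$report$removed$polarity_mismatch, 1)
  expect_equal(res$corpus$polarity, "positive")
})

test_that("each removal has one reason and counts conserve the input size", {
  for (seed in 1:4) {
    spec <- corpus_spec(
      "US", 400, default_scenario()$topics,
      contamination = list(duplicate = 0.05, blank = 0.03, garbled = 0.03,
                           ad = 0.02, bot = 0.04, polarity_mismatch = 0.05),
      seed = seed
    )
    corpus <- simulate_reviews(spec)
    res <- apply_filters(corpus, bot_predicate = flag_bot_authors)
    expect_equal(res$report$retained + sum(unlist(res$report$removed)),
                 nrow(corpus))
    # idempotence: a second pass removes nothing
    res2 <- apply_filters(res$corpus, bot_predicate = flag_bot_authors)
    expect_true(all(unlist(res2$report$removed) == 0))
    expect_equal(nrow(res2$corpus), nrow(res$corpus))
  }
})

test_that("garbled, non-target-language, blank and ad reviews are attributed correctly", {
  corpus <- make_corpus(
    rating = rep(5, 5),
    text = c("   ", "!!! ???", "完全中文评论",
             "use promo code 99 today", "genuinely helpful app"),
    author_id = paste0("u", 1:5)
  )
  res <- apply_filters(corpus)
  expect_equal(res$report$removed$blank, 1)
  expect_equal(res$report$removed$garbled, 1)
  expect_equal(res$report$removed$non_target_language, 1) # CJK text in US market
  expect_equal(res$report$removed$advertisement, 1)
  expect_equal(res$corpus$text, "genuinely helpful app")
})

test_that("topic proportions are counts over the market and sum to one", {
  corpus <- make_corpus(
    rating = rep(5, 10),
    topic = c(rep("A", 5), rep("B", 3), rep("C", 2)),
    author_id = paste0("u", 1:10)
  )
  props <- topic_proportions(corpus, "US")
  expect_equal(setNames(props$proportion, props$topic),
               c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(sum(props$proportion), 1)

  single <- topic_proportions(make_corpus(rating = 5, topic = "Z"), "US")
  expect_equal(single$proportion, 1)

  h <- hierarchy_frame("Sat", data.frame(
    indicator = c("A", "B", "C"), criterion = c("one", "two", "two")
  ))
  crit <- criterion_proportions(props, h)
  expect_equal(crit$proportion[crit$criterion == "two"], 0.5)
})

test_that("proportions sum to one for simulated corpora", {
  for (seed in 1:5) {
    corpus <- simulate_reviews(corpus_spec("US", 500, default_scenario()$topics,
                                           seed = seed))
    props <- topic_proportions(corpus, "US")
    expect_equal(sum(props$proportion), 1, tolerance = 1e-9)
  }
})

test_that("positive share is positives over labeled reviews", {
  corpus <- make_corpus(
    rating = c(rep(5, 8), 1, 1),
    polarity = c(rep("positive", 8), "negative", "negative"),
    author_id = paste0("u", 1:10)
  )
  expect_equal(positive_share(corpus, "A"), 0.8)
  expect_equal(positive_share(make_corpus(5, "positive"), "A"), 1)
  expect_equal(positive_share(make_corpus(1, "negative"), "A"), 0)
  expect_error(positive_share(corpus, "missing"), class = "useis_empty_input_error")
  unlabeled <- make_corpus(5, NA_character_)
  expect_error(positive_share(unlabeled, "A"), class = "useis_empty_input_error")
})

test_that("positive share concentrates in the exact binomial interval", {
  p <- 0.7
  n <- 1000
  topics <- tibble::tibble(topic = "A", proportion = 1, positive_share = p)
  for (seed in 1:20) {
    corpus <- simulate_reviews(corpus_spec("US", n, topics, seed = seed))
    lo <- qbinom(0.005, n, p) / n
    hi <- qbinom(0.995, n, p) / n
    share <- positive_share(corpus, "A")
    expect_gte(share, lo)
    expect_lte(share, hi)
  }
})

test_that("corpus validation surfaces bad inputs", {
  expect_error(review_corpus(data.frame(review_id = character(0))),
               class = "useis_validation_error")
  base <- make_corpus(5)
  expect_error(review_corpus(base[0, ]), class = "useis_empty_input_error")
  bad_market <- base; bad_market$market <- "UK"
  expect_error(review_corpus(bad_market), class = "useis_validation_error")
  bad_rating <- base; bad_rating$rating <- 7L
  expect_error(review_corpus(bad_rating), class = "useis_validation_error")
  no_topic <- make_corpus(c(5, 4), topic = c("A", NA))
  expect_error(topic_proportions(no_topic, "US"), class = "useis_validation_error")
  expect_error(topic_proportions(base, "CN"), class = "useis_empty_input_error")
})

test_that("review corpora round-trip through CSV and JSON-lines", {
  corpus <- simulate_reviews(corpus_spec("US", 50, default_scenario()$topics,
                                         seed = 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(corpus, csv, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  back <- read_reviews(csv)
  expect_equal(back$review_id, corpus$review_id)
  expect_equal(as.integer(back$rating), corpus$rating)
  expect_equal(back$topic, corpus$topic)

  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(
    vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(as.list(corpus[i, ]), auto_unbox = TRUE)
    }, character(1)),
    jsonl
  )
  back2 <- read_reviews(jsonl)
  expect_equal(back2$text, corpus$text)
  expect_equal(nrow(back2), nrow(corpus))
})
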